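cluster	namespace	term
1	biological_process	GO:0046940
1	biological_process	GO:0009141
1	biological_process	GO:0009123
1	biological_process	GO:0009144
1	biological_process	GO:0009199
1	biological_process	GO:0009142
1	biological_process	GO:0009201
1	biological_process	GO:0009058
1	biological_process	GO:0006979
1	biological_process	GO:1901576
1	biological_process	GO:0000461
1	molecular_function	GO:0030570
1	molecular_function	GO:0016837
1	molecular_function	GO:0008379
2	biological_process	GO:0050896
2	biological_process	GO:0042221
2	molecular_function	GO:0004364
2	molecular_function	GO:0016765
2	molecular_function	GO:1900750
2	molecular_function	GO:0043295
2	molecular_function	GO:0072341
2	molecular_function	GO:1901681
2	molecular_function	GO:0042277
2	molecular_function	GO:0033218
2	molecular_function	GO:0015036
2	molecular_function	GO:0016667
2	molecular_function	GO:0016740
2	molecular_function	GO:0005515
2	molecular_function	GO:0015035
3	biological_process	GO:0006086
3	biological_process	GO:0006085
3	biological_process	GO:0035384
3	biological_process	GO:0034033
3	biological_process	GO:0006084
3	biological_process	GO:0033866
3	biological_process	GO:0071616
3	biological_process	GO:0034030
3	biological_process	GO:0044088
3	biological_process	GO:0032889
3	biological_process	GO:1901652
3	biological_process	GO:0071375
3	biological_process	GO:0032869
3	biological_process	GO:1901653
3	biological_process	GO:0032868
3	biological_process	GO:0043434
3	biological_process	GO:0044282
3	biological_process	GO:0006793
3	biological_process	GO:0006796
3	biological_process	GO:0016310
3	biological_process	GO:1901616
3	biological_process	GO:0046174
3	biological_process	GO:0046164
3	molecular_function	GO:0016624
3	molecular_function	GO:0051287
3	molecular_function	GO:0004634
3	molecular_function	GO:0042132
3	molecular_function	GO:0016860
3	cellular_component	GO:1990204
3	cellular_component	GO:0070469
3	cellular_component	GO:0031975
3	cellular_component	GO:0031967
3	cellular_component	GO:0005746
3	cellular_component	GO:0005747
3	cellular_component	GO:0019866
3	cellular_component	GO:0098803
3	cellular_component	GO:0005743
3	cellular_component	GO:0005740
3	cellular_component	GO:0031966
3	cellular_component	GO:0045271
3	cellular_component	GO:0030964
4	biological_process	GO:0051179
4	biological_process	GO:0098655
4	biological_process	GO:1902600
4	biological_process	GO:0006812
4	biological_process	GO:0098660
4	biological_process	GO:0034220
4	biological_process	GO:0098662
4	biological_process	GO:0006811
4	biological_process	GO:0055085
4	biological_process	GO:0006810
4	biological_process	GO:0051234
4	molecular_function	GO:0046961
4	molecular_function	GO:0044769
4	molecular_function	GO:0042625
4	molecular_function	GO:0009678
4	molecular_function	GO:0019829
4	molecular_function	GO:0015078
4	molecular_function	GO:0042626
4	molecular_function	GO:0015399
4	molecular_function	GO:0016887
4	molecular_function	GO:0022853
4	molecular_function	GO:0022890
4	molecular_function	GO:0008324
4	molecular_function	GO:0022804
4	molecular_function	GO:0015318
4	molecular_function	GO:0015075
4	molecular_function	GO:0022857
4	molecular_function	GO:0005215
4	molecular_function	GO:0008553
4	cellular_component	GO:0016469
4	cellular_component	GO:0033176
4	cellular_component	GO:0033179
4	cellular_component	GO:0033177
4	cellular_component	GO:0033180
4	cellular_component	GO:0005773
4	cellular_component	GO:0005774
4	cellular_component	GO:0098588
4	cellular_component	GO:0031090
5	biological_process	GO:0010499
5	biological_process	GO:0043632
5	biological_process	GO:0030163
5	biological_process	GO:0043161
5	biological_process	GO:0010498
5	biological_process	GO:0044265
5	biological_process	GO:0006511
5	biological_process	GO:0044257
5	biological_process	GO:0051603
5	biological_process	GO:0019941
5	biological_process	GO:2000144
5	biological_process	GO:0045899
5	biological_process	GO:0060260
5	biological_process	GO:0045898
5	biological_process	GO:0060261
5	biological_process	GO:0043933
5	biological_process	GO:0006807
5	biological_process	GO:0044238
5	biological_process	GO:0071704
5	biological_process	GO:0006508
5	biological_process	GO:0044267
5	biological_process	GO:0019538
5	biological_process	GO:1901565
5	biological_process	GO:0009057
5	biological_process	GO:0044248
5	molecular_function	GO:0004298
5	molecular_function	GO:0070003
5	molecular_function	GO:0004175
5	molecular_function	GO:0008233
5	molecular_function	GO:0036402
5	cellular_component	GO:0000502
5	cellular_component	GO:1905368
5	cellular_component	GO:0031597
5	cellular_component	GO:0005838
5	cellular_component	GO:0019773
5	cellular_component	GO:0022624
5	cellular_component	GO:0008541
5	cellular_component	GO:0005839
5	cellular_component	GO:0008540
5	cellular_component	GO:1905369
5	cellular_component	GO:0140535
6	biological_process	GO:0070887
6	biological_process	GO:0009060
6	molecular_function	GO:0008135
6	molecular_function	GO:0090079
6	molecular_function	GO:0045182
6	molecular_function	GO:0030060
6	molecular_function	GO:0016615
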