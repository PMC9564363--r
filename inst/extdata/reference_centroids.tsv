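cluster	ABS-cx	BS-cx	BBS-cx	ABS-cv	BS-cv	BBS-cv	size	withinss
1	0.7581557	-0.29911	-2.06396	0.191851	0.266578	-1.21004	12	36.9506
2	-0.1136721	-6.2065	-4.59749	0.250547	-0.32258	0.729957	4	42.15465
3	-0.7552579	0.793721	0.46037	-0.56888	0.069973	-6.89288	11	38.7308
4	1.0195613	-2.84078	-3.94615	0.464451	0.864264	-7.14603	3	42.71795
5	0.4441395	-1.41837	-0.12500	0.422867	0.09185	-1.34692	16	65.03039
6	-0.3790747	-0.02729	0.300643	-0.92325	-0.24844	-0.05900	20	137.90456
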