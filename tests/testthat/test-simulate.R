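test_that("simulation config enforces its invariants", {
  expect_error(simulation_config(cluster_sizes = c(10, 10)),
               "sum to n_proteins")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  expect_error(simulation_config(baseline_annotation_prob = 0.5,
                                 enriched_annotation_prob = 0.5),
               "exceed")
  expect_error(simulation_config(score_high_range = c(600, 1000)),
               "at or above")
  expect_error(simulation_config(score_low_range = c(100, 700)),
               "below")
  expect_error(simulation_config(planted_clique_sizes = c(5, 1)), ">= 2")
  expect_error(simulation_config(dag_depth = 1), "dag_depth")
})

test_that("identical config yields byte-identical artifacts", {
  cfg <- simulation_config(seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_study(cfg, outdir = d1)
  simulate_study(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 label = paste("checksum of", f))
  }
})

test_that("abundance generator plants exact group sizes and profiles", {
  sim <- generate_abundance_table(simulation_config(seed = 8))
  expect_equal(as.integer(table(sim$labels$cluster)),
               c(12, 4, 11, 3, 16, 20))
  expect_equal(nrow(sim$table), 66)
  expect_true(all(as.matrix(sim$table[, pap_conditions()]) > 0))

  # normalization is the exact inverse of the generator transform
  prof <- normalize_abundance(sim$table)
  expect_equal(as.matrix(prof[, pap_conditions()]),
               as.matrix(sim$profiles[, pap_conditions()]),
               tolerance = 1e-9)

  # near-zero noise with one flat cluster: profiles collapse to zero
  flat <- generate_abundance_table(simulation_config(
    n_proteins = 5, cluster_sizes = 5,
    centroid_matrix = matrix(0, 1, 6), noise_sd = 1e-9, seed = 1))
  expect_equal(max(abs(as.matrix(
    normalize_abundance(flat$table)[, pap_conditions()]))), 0,
    tolerance = 1e-6)
})

test_that("k-means recovers planted clusters at high separation", {
  cfg <- simulation_config(noise_sd = 0.1, seed = 14)
  sim <- generate_abundance_table(cfg)
  fit <- kmeans_profiles(normalize_abundance(sim$table), k = 6, seed = 14)
  expect_equal(
    mclust::adjustedRandIndex(fit$assignments$cluster, sim$labels$cluster),
    1
  )
})

test_that("PPI generator plants cliques exactly as configured", {
  # no background, one clique of size 4: the filtered graph is K4
  cfg <- simulation_config(n_proteins = 3, cluster_sizes = 3,
                           centroid_matrix = matrix(0, 1, 6),
                           planted_clique_sizes = 4,
                           background_edge_prob = 0, n_background_nodes = 0,
                           seed = 2)
  net <- generate_ppi_network(cfg, list(`1` = c("a", "b", "c")))
  hi <- filter_high_confidence(net$edges, 700)
  expect_equal(nrow(hi), 6)
  expect_setequal(unique(c(hi$protein1, hi$protein2)),
                  c("HUB_1", "a", "b", "c"))

  # all planted scores pass the filter, all background scores fail
  cfg2 <- simulation_config(seed = 4)
  sim2 <- generate_ppi_network(cfg2, split(sprintf("P%03d", 1:66),
                                           rep(1:6, c(12, 4, 11, 3, 16, 20))))
  hi2 <- filter_high_confidence(sim2$edges, 700)
  expect_equal(nrow(hi2), nrow(sim2$planted_edges))

  # hub in two otherwise-disjoint triangles: downstream MCC(hub) = 4
  cfg3 <- simulation_config(n_proteins = 4, cluster_sizes = 4,
                            centroid_matrix = matrix(0, 1, 6),
                            planted_clique_sizes = c(3, 3),
                            background_edge_prob = 0, n_background_nodes = 0,
                            seed = 3)
  net3 <- generate_ppi_network(cfg3, list(`1` = sprintf("s%d", 1:4)))
  sc <- mcc_score(filter_high_confidence(net3$edges, 700))
  expect_equal(sc$mcc[sc$node == "HUB_1"], 4)

  expect_error(generate_ppi_network(cfg3, list(`1` = c("a", "a"))),
               "duplicate")
})

test_that("GO generator builds valid namespaced DAGs with planted signal", {
  cfg <- simulation_config(seed = 5)
  universe <- sprintf("g%02d", 1:40)
  sim <- generate_go_resources(cfg, list(s1 = universe[1:10]),
                               universe = universe)
  expect_length(sim$dag$roots, 3)
  expect_setequal(names(sim$dag$roots), go_namespaces())
  # every term carries exactly one namespace (single row per id)
  expect_equal(anyDuplicated(sim$dag$terms$id), 0)
  expect_equal(nrow(sim$planted), 3)

  # degenerate probabilities: planted term annotates exactly its gene set
  cfg0 <- simulation_config(baseline_annotation_prob = 0,
                            enriched_annotation_prob = 1, seed = 6)
  sim0 <- generate_go_resources(cfg0, list(s1 = universe[1:10]),
                                universe = universe)
  for (i in seq_len(nrow(sim0$planted))) {
    genes <- sim0$annotations$gene[
      sim0$annotations$term == sim0$planted$term[i]]
    expect_setequal(genes, universe[1:10])
  }
  expect_true(all(sim0$annotations$term %in% sim0$planted$term))
})
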