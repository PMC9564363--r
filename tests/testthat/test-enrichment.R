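chain_dag <- function() {
  go_dag(
    terms = tibble::tibble(
      id = c("GO:0000001", "GO:0000002", "GO:0000003"),
      name = c("root", "mid", "leaf"),
      namespace = "biological_process"
    ),
    parents = tibble::tibble(id = c("GO:0000002", "GO:0000003"),
                             parent = c("GO:0000001", "GO:0000002"))
  )
}

test_that("true-path propagation closes over is_a ancestors", {
  dag <- chain_dag()
  ann <- propagate_annotations(
    dag, tibble::tibble(gene = "g", term = "GO:0000003"))
  expect_setequal(ann$propagated$term,
                  c("GO:0000001", "GO:0000002", "GO:0000003"))

  at_root <- propagate_annotations(
    dag, tibble::tibble(gene = "g", term = "GO:0000001"))
  expect_equal(nrow(at_root$propagated), 1)

  # diamond: shared grandparent counted once
  dia <- propagate_annotations(
    diamond_dag(), tibble::tibble(gene = "g", term = "GO:0000004"))
  expect_equal(nrow(dia$propagated), 4)
  expect_equal(anyDuplicated(paste(dia$propagated$gene,
                                   dia$propagated$term)), 0)

  expect_error(
    propagate_annotations(dag, tibble::tibble(gene = "g", term = "GO:0009999")),
    "absent from DAG"
  )
})

# helper: go_annotations object with prescribed per-term direct gene lists
make_corpus <- function(dag, direct_list) {
  ann <- purrr::imap_dfr(direct_list, function(genes, term) {
    tibble::tibble(gene = genes, term = term)
  })
  propagate_annotations(dag, ann)
}

test_that("hypergeometric p-values hit their closed forms", {
  dag <- chain_dag()
  # universe of 10 genes, term GO:0000003 annotates 4 of them
  corpus <- make_corpus(dag, list(
    "GO:0000003" = sprintf("g%02d", 1:4),
    "GO:0000001" = sprintf("g%02d", 5:10)
  ))
  study <- sprintf("g%02d", c(1:4, 10))   # n = 5, k = 4 for the leaf
  res <- enrich(study, corpus, "biological_process")
  leaf <- res[res$term == "GO:0000003", ]
  expect_equal(leaf$p_raw, 6 / 252, tolerance = 1e-12)
  expect_false("GO:0000001" %in% res$term)   # root excluded

  # K = N: certain event
  allterm <- make_corpus(dag, list("GO:0000002" = sprintf("g%02d", 1:6)))
  res <- enrich(sprintf("g%02d", 1:3), allterm, "biological_process")
  expect_equal(res$p_raw[res$term == "GO:0000002"], 1)

  # k = n = K: 1 / C(N, K)
  corpus <- make_corpus(dag, list(
    "GO:0000003" = c("a", "b"),
    "GO:0000001" = c("c", "d", "e")
  ))
  res <- enrich(c("a", "b"), corpus, "biological_process")
  expect_equal(res$p_raw[res$term == "GO:0000003"], 1 / choose(5, 2),
               tolerance = 1e-12)

  expect_error(enrich(character(0), corpus, "biological_process"), "empty")
  expect_error(enrich("zz", corpus, "biological_process"),
               "outside background")
})

test_that("p-values equal exhaustive draw enumeration for all N <= 12", {
  for (N in c(5, 8, 12)) {
    for (n in c(2, floor(N / 2))) {
      for (K in c(1, 3, N - 1)) {
        for (k in seq_len(min(n, K))) {
          expect_equal(
            phyper(k - 1, K, N - K, n, lower.tail = FALSE),
            enum_hyper(k, K, N, n),
            tolerance = 1e-12,
            label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k)
          )
        }
      }
    }
  }
})

test_that("enrichment p decreases strictly as the study count grows", {
  N <- 30; K <- 10; n <- 8
  p <- vapply(1:8, function(k) phyper(k - 1, K, N - K, n, lower.tail = FALSE),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("Bonferroni adjustment acts per family", {
  res <- tibble::tibble(
    term = c("GO:0000010", "GO:0000011"),
    namespace = "biological_process",
    k = 2, n = 5, K = 3, N = 20,
    p_raw = c(0.01, 0.5)
  )
  adj <- adjust_bonferroni(res, alpha = 0.05)
  expect_equal(adj$p_adj, c(0.02, 1))
  expect_equal(adj$significant, c(TRUE, FALSE))

  single <- adjust_bonferroni(res[1, ], alpha = 0.05)
  expect_equal(single$p_adj, single$p_raw)

  ten <- adjust_bonferroni(dplyr::bind_rows(res[1, ], res[rep(2, 9), ]))
  expect_equal(ten$p_adj[1], 0.1)          # 0.01 * m with m = 10
  expect_false(ten$significant[1])

  everything <- adjust_bonferroni(res, alpha = 1)
  expect_true(all(everything$significant))  # degenerate threshold
})

test_that("a strongly planted term survives Bonferroni", {
  cfg <- simulation_config(seed = 17, baseline_annotation_prob = 0.05,
                           enriched_annotation_prob = 0.9)
  universe <- sprintf("g%03d", 1:300)
  study <- universe[1:30]
  sim <- generate_go_resources(cfg, list(study = study), universe = universe)
  annset <- propagate_annotations(sim$dag, sim$annotations)
  for (ns in go_namespaces()) {
    planted <- sim$planted$term[sim$planted$namespace == ns]
    res <- enrich(intersect(study, annset$universe[[ns]]), annset, ns) |>
      adjust_bonferroni(0.05)
    expect_true(res$significant[res$term == planted],
                label = paste("planted term significant in", ns))
  }
})
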