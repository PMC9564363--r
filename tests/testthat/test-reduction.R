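# corpus over branchy_dag(): root, x is_a root, {a, b} is_a x, c is_a root.
# 16 genes; direct annotations chosen so propagated counts are
# root 16, x 4, a 2, b 2, c 4.
branchy_corpus <- function() {
  dag <- branchy_dag()
  genes <- sprintf("g%02d", 1:16)
  ann <- dplyr::bind_rows(
    tibble::tibble(gene = genes[1:2], term = "GO:0000012"),    # a
    tibble::tibble(gene = genes[3:4], term = "GO:0000013"),    # b
    tibble::tibble(gene = genes[5:8], term = "GO:0000014"),    # c
    tibble::tibble(gene = genes[9:16], term = "GO:0000010")    # root direct
  )
  list(dag = dag, annset = propagate_annotations(dag, ann))
}

test_that("information content matches hand-computed -ln(count/total)", {
  cc <- branchy_corpus()
  ic <- information_content(cc$dag, cc$annset)
  ic_of <- setNames(ic$ic, ic$term)
  expect_equal(ic_of[["GO:0000010"]], 0)                 # root: p = 1
  expect_equal(ic_of[["GO:0000011"]], -log(4 / 16))      # x
  expect_equal(ic_of[["GO:0000012"]], -log(2 / 16))      # a
  expect_equal(ic_of[["GO:0000014"]], -log(4 / 16))      # c

  # a term annotating half the corpus has IC = ln 2
  dag <- diamond_dag()
  ann <- propagate_annotations(dag, tibble::tibble(
    gene = sprintf("g%d", 1:4),
    term = c("GO:0000004", "GO:0000004", "GO:0000001", "GO:0000001")
  ))
  ic2 <- information_content(dag, ann)
  expect_equal(ic2$ic[ic2$term == "GO:0000004"], log(2), tolerance = 1e-12)
})

test_that("Lin similarity follows the MICA formula", {
  cc <- branchy_corpus()
  ic <- information_content(cc$dag, cc$annset)

  # identical terms with positive IC
  expect_equal(lin_similarity("GO:0000012", "GO:0000012", cc$dag, ic), 1)
  # siblings under x: 2*IC(x) / (IC(a) + IC(b)) = 2 ln4 / (2 ln8)
  expect_equal(lin_similarity("GO:0000012", "GO:0000013", cc$dag, ic),
               log(4) / log(8), tolerance = 1e-12)
  # disjoint branches: only common ancestor is the root (IC 0)
  expect_equal(lin_similarity("GO:0000012", "GO:0000014", cc$dag, ic), 0)

  # chain root -> a -> b with p = (1, 0.5, 0.25): sim = 2 ln2 / (ln2 + ln4)
  dag <- go_dag(
    tibble::tibble(id = c("GO:0000021", "GO:0000022", "GO:0000023"),
                   name = c("root", "a", "b"),
                   namespace = "cellular_component"),
    tibble::tibble(id = c("GO:0000022", "GO:0000023"),
                   parent = c("GO:0000021", "GO:0000022"))
  )
  ann <- propagate_annotations(dag, tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"),
    term = c("GO:0000021", "GO:0000021", "GO:0000022", "GO:0000023")
  ))
  ic3 <- information_content(dag, ann)
  expect_equal(lin_similarity("GO:0000022", "GO:0000023", dag, ic3),
               2 / 3, tolerance = 1e-12)

  # cross-namespace comparison is refused
  expect_error(lin_similarity("GO:0000012", "GO:0000021", cc$dag, ic),
               "not in DAG|cross-namespace")
})

test_that("semantic reduction merges by the stated discard hierarchy", {
  cc <- branchy_corpus()
  ic <- information_content(cc$dag, cc$annset)

  # a and b: sim = ln4/ln8 = 0.667 > 0.5 -> one of them merges; the one
  # with the larger p_adj is discarded
  res <- tibble::tibble(term = c("GO:0000012", "GO:0000013"),
                        p_adj = c(0.001, 0.01))
  red <- reduce_terms(res, cc$dag, ic, cutoff = 0.5)
  expect_equal(red$representatives$term, "GO:0000012")
  expect_equal(red$merged$term, "GO:0000013")
  expect_equal(red$merged$representative, "GO:0000012")

  # equal p_adj: discard falls back to larger frequency, then larger id;
  # a and b have equal frequency (2/16 each) -> larger id GO:0000013 goes
  tie <- tibble::tibble(term = c("GO:0000012", "GO:0000013"),
                        p_adj = c(0.001, 0.001))
  red_tie <- reduce_terms(tie, cc$dag, ic, cutoff = 0.5)
  expect_equal(red_tie$representatives$term, "GO:0000012")

  # all pairwise sims below cutoff: identity
  apart <- tibble::tibble(term = c("GO:0000012", "GO:0000014"),
                          p_adj = c(0.001, 0.01))
  red_id <- reduce_terms(apart, cc$dag, ic, cutoff = 0.5)
  expect_equal(nrow(red_id$merged), 0)
  expect_setequal(red_id$representatives$term, apart$term)

  # cutoff 1 merges nothing for distinct generic terms
  red_one <- reduce_terms(res, cc$dag, ic, cutoff = 1)
  expect_equal(nrow(red_one$merged), 0)
})

test_that("greedy reduction replays the rules on a three-term family", {
  # x, a, b: sim(a,b) = ln4/ln8 ~ 0.667; sim(x,a) = sim(x,b) =
  # 2*IC(x)/(IC(x)+IC(a)) = 2 ln4/(ln4+ln8) ~ 0.8; all above cutoff 0.5.
  # Expected replay with p_adj x < a < b:
  #   step 1: best pair (x,a) or (x,b) at 0.8 -- tie broken by id order
  #           -> pair (x,a): discard a (larger p_adj)
  #   step 2: remaining (x,b) at 0.8 -> discard b
  #   survivor: x alone
  cc <- branchy_corpus()
  ic <- information_content(cc$dag, cc$annset)
  fam <- tibble::tibble(term = c("GO:0000011", "GO:0000012", "GO:0000013"),
                        p_adj = c(0.001, 0.005, 0.01))
  red <- reduce_terms(fam, cc$dag, ic, cutoff = 0.5)
  expect_equal(red$representatives$term, "GO:0000011")
  expect_setequal(red$merged$term, c("GO:0000012", "GO:0000013"))
  expect_equal(unique(red$merged$representative), "GO:0000011")
})

test_that("reduction output is deterministic and respects the cutoff", {
  sim <- generate_go_resources(
    simulation_config(seed = 23),
    list(s1 = sprintf("g%02d", 1:10), s2 = sprintf("g%02d", 11:20)),
    universe = sprintf("g%02d", 1:40)
  )
  annset <- propagate_annotations(sim$dag, sim$annotations)
  ic <- suppressWarnings(information_content(sim$dag, annset))
  ns <- "biological_process"
  terms <- intersect(
    unique(annset$propagated$term[annset$propagated$namespace == ns]),
    ic$term
  )
  terms <- setdiff(terms, annset$roots[[ns]])[1:12]
  set.seed(1)
  fam <- tibble::tibble(term = sort(terms), p_adj = runif(length(terms)))

  r1 <- reduce_terms(fam, sim$dag, ic, cutoff = 0.5)
  r2 <- reduce_terms(fam, sim$dag, ic, cutoff = 0.5)
  expect_identical(r1$representatives, r2$representatives)
  expect_identical(r1$merged, r2$merged)
  expect_lte(nrow(r1$representatives), nrow(fam))

  # surviving pairs all at or below the cutoff
  surv <- r1$representatives$term
  if (length(surv) >= 2) {
    for (pair in asplit(combn(surv, 2), 2)) {
      expect_lte(lin_similarity(pair[1], pair[2], sim$dag, ic), 0.5)
    }
  }
  # tidy() maps every input term to a surviving representative
  td <- tidy(r1)
  expect_setequal(td$term, fam$term)
  expect_true(all(td$representative %in% surv))
})
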