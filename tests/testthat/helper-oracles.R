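# Independent brute-force oracles used across the suite. These deliberately
# use naive enumeration, not the package's code paths.

# all maximal cliques of a small graph by exhaustive subset enumeration
brute_cliques <- function(edges, nodes = NULL) {
  nodes <- sort(unique(c(nodes, edges$protein1, edges$protein2)))
  stopifnot(length(nodes) <= 12)
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges$protein1[i], edges$protein2[i]] <- TRUE
    adj[edges$protein2[i], edges$protein1[i]] <- TRUE
  }
  is_complete <- function(s) {
    if (length(s) < 2) return(FALSE)
    all(adj[s, s][upper.tri(diag(length(s)))])
  }
  subsets <- unlist(lapply(2:length(nodes), function(sz) {
    asplit(combn(nodes, sz), 2)
  }), recursive = FALSE)
  complete <- Filter(is_complete, lapply(subsets, as.character))
  Filter(function(s) {
    !any(vapply(complete, function(t) {
      length(t) > length(s) && all(s %in% t)
    }, logical(1)))
  }, complete)
}

# MCC from a clique list
brute_mcc <- function(cliques, nodes) {
  score <- setNames(numeric(length(nodes)), nodes)
  for (C in cliques) score[C] <- score[C] + factorial(length(C) - 1)
  score
}

# upper-tail hypergeometric probability by exhaustive draw enumeration:
# draws of size n from 1..N, successes are 1..K, P(X >= k)
enum_hyper <- function(k, K, N, n) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# random simple graph edge tibble on n nodes
random_edges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  tibble::tibble(protein1 = pairs[keep, 1], protein2 = pairs[keep, 2],
                 combined_score = 900L)
}

# small handcrafted DAG: one namespace, diamond under the root
#   root <- m1, m2 ; t is_a m1 and m2 (shared grandparent root)
diamond_dag <- function() {
  go_dag(
    terms = tibble::tibble(
      id = c("GO:0000001", "GO:0000002", "GO:0000003", "GO:0000004"),
      name = c("root", "mid1", "mid2", "leaf"),
      namespace = "biological_process"
    ),
    parents = tibble::tibble(
      id = c("GO:0000002", "GO:0000003", "GO:0000004", "GO:0000004"),
      parent = c("GO:0000001", "GO:0000001", "GO:0000002", "GO:0000003")
    )
  )
}

# namespace with a controlled annotation-count structure for IC/Lin tests:
# root; x is_a root; a,b is_a x; c is_a root
branchy_dag <- function() {
  go_dag(
    terms = tibble::tibble(
      id = sprintf("GO:000001%d", 0:4),
      name = c("root", "x", "a", "b", "c"),
      namespace = "molecular_function"
    ),
    parents = tibble::tibble(
      id = c("GO:0000011", "GO:0000012", "GO:0000013", "GO:0000014"),
      parent = c("GO:0000010", "GO:0000011", "GO:0000011", "GO:0000010")
    )
  )
}

# tiny abundance tibble builder
abundance_row <- function(protein, values) {
  tibble::as_tibble(c(list(protein = protein),
                      setNames(as.list(values), pap_conditions())))
}
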