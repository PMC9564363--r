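#' Enumerate the maximal cliques of a subnetwork
#'
#' Complete enumeration of maximal cliques (size >= 2) of the simple
#' undirected graph, in deterministic order: decreasing size, then
#' lexicographically by the sorted member list. Isolated nodes belong to
#' no clique and are reported separately.
#'
#' @param x A `pap_subnetwork`, an edge tibble (`protein1`/`protein2`), or
#'   an igraph object.
#' @return A `clique_set`: `cliques` (list of sorted character vectors),
#'   `nodes`, `isolated`, `fingerprint` (md5 of the canonical edge list).
#' @export
maximal_cliques <- function(x) {
  g <- as_subnetwork_graph(x)
  nodes <- sort(igraph::V(g)$name)
  cl <- igraph::max_cliques(g, min = 2)
  cliques <- lapply(cl, function(v) sort(names(v)))
  key <- vapply(cliques, paste, character(1), collapse = "|")
  ord <- order(-lengths(cliques), key)
  cliques <- cliques[ord]
  in_clique <- unique(unlist(cliques))
  edge_canon <- paste(
    apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "~")),
    collapse = ";"
  )
  structure(
    list(
      cliques = cliques,
      nodes = nodes,
      isolated = setdiff(nodes, in_clique),
      fingerprint = digest_string(edge_canon)
    ),
    class = "clique_set"
  )
}

# md5 of a string via a temp file (tools::md5sum is file-based)
digest_string <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(tools::md5sum(f))
}

as_subnetwork_graph <- function(x) {
  if (inherits(x, "igraph")) return(x)
  if (inherits(x, "pap_subnetwork")) {
    return(igraph::graph_from_data_frame(
      x$edges[, c("protein1", "protein2")],
      directed = FALSE, vertices = x$nodes
    ))
  }
  edges_to_igraph(tibble::as_tibble(x))
}

#' @export
print.clique_set <- function(x, ...) {
  cat("<clique_set> ", length(x$cliques), " maximal clique(s) over ",
      length(x$nodes), " nodes (", length(x$isolated), " isolated)\n",
      sep = "")
  invisible(x)
}

#' Maximal Clique Centrality scores
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over the maximal cliques `C` that
#' contain `v`. When a node's neighbours share no edges, all its cliques
#' are single edges and MCC reduces to the node degree. Scores are exact
#' integers as long as they stay below 2^53 (maximal cliques up to size
#' 19), which covers realistically sized PPI subnetworks.
#'
#' @param x Graph input accepted by [maximal_cliques()].
#' @param cliques Optional precomputed [maximal_cliques()] result for `x`.
#' @return Tibble: `node`, `mcc`, `degree`, sorted by MCC descending,
#'   degree descending, node id ascending.
#' @export
mcc_score <- function(x, cliques = NULL) {
  g <- as_subnetwork_graph(x)
  cliques <- cliques %||% maximal_cliques(g)
  stopifnot(inherits(cliques, "clique_set"))
  deg <- igraph::degree(g)
  score <- setNames(numeric(length(deg)), names(deg))
  for (C in cliques$cliques) {
    score[C] <- score[C] + factorial(length(C) - 1)
  }
  tibble::tibble(
    node = names(score),
    mcc = unname(score),
    degree = unname(deg)
  ) |>
    dplyr::arrange(dplyr::desc(.data$mcc), dplyr::desc(.data$degree),
                   .data$node)
}

#' Top-k hub genes by Maximal Clique Centrality
#'
#' Ranks non-isolated nodes by MCC (ties by degree, then node id) and
#' reports the top `k` as hub genes, plus whether those hubs induce a
#' complete subgraph — for k = 3, whether the hub genes form a triangle.
#'
#' @param x Graph input accepted by [maximal_cliques()].
#' @param k Number of hubs to report (default 3).
#' @return A `hub_ranking`: `scores` tibble (node, mcc, degree, rank),
#'   `top` character vector, `hub_clique` flag, `short` flag (fewer than k
#'   rankable nodes), `k`, `n_cliques`.
#' @export
top_hubs <- function(x, k = 3) {
  g <- as_subnetwork_graph(x)
  if (igraph::vcount(g) == 0) abort("empty graph")
  cliques <- maximal_cliques(g)
  scores <- mcc_score(g, cliques)
  rankable <- scores[!scores$node %in% cliques$isolated, ]
  rankable$rank <- seq_len(nrow(rankable))
  short <- nrow(rankable) < k
  if (short) {
    warn(paste0("only ", nrow(rankable), " rankable node(s) for top-", k))
  }
  top <- head(rankable$node, k)
  hub_clique <- length(top) >= 2 && all(apply(
    combn(top, 2), 2,
    function(p) igraph::are_adjacent(g, p[1], p[2])
  ))
  structure(
    list(
      scores = rankable,
      top = top,
      hub_clique = hub_clique,
      short = short,
      k = k,
      n_cliques = length(cliques$cliques),
      isolated = cliques$isolated
    ),
    class = "hub_ranking"
  )
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat("<hub_ranking> top-", x$k, ": ", paste(x$top, collapse = ", "),
      "\n  hub clique (all pairwise edges): ", x$hub_clique, "\n", sep = "")
  invisible(x)
}

#' @rdname top_hubs
#' @param x A `hub_ranking` object.
#' @param ... Unused.
#' @method tidy hub_ranking
#' @export
tidy.hub_ranking <- function(x, ...) {
  dplyr::mutate(x$scores, hub = .data$rank <= x$k)
}

#' @rdname top_hubs
#' @method glance hub_ranking
#' @export
glance.hub_ranking <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$scores) + length(x$isolated),
    n_rankable = nrow(x$scores),
    n_cliques = x$n_cliques,
    top_mcc = if (nrow(x$scores)) x$scores$mcc[1] else NA_real_,
    hub_clique = x$hub_clique
  )
}

#' Bar plot of the highest-MCC nodes
#'
#' @param object A `hub_ranking`.
#' @param n_show Number of nodes displayed (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hub_ranking
#' @export
autoplot.hub_ranking <- function(object, n_show = 10, ...) {
  d <- head(tidy(object), n_show)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$node, .data$mcc),
    y = .data$mcc, fill = .data$hub
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "MCC (log scale)", fill = "hub") +
    ggplot2::theme_minimal()
}
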