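#' Filter a PPI network to high-confidence edges
#'
#' Keeps exactly the edges with `combined_score >= min_score`. The default
#' 700 is the conventional "high confidence" cut on the STRING 0--1000
#' combined-score scale (a stated score of 0.7 on the unit scale). The full
#' pre-filter node set is preserved in attribute `all_nodes` so that seeds
#' left isolated by the filter can still be reported downstream.
#'
#' @param net Canonical edge tibble (see [ppi_network()]).
#' @param min_score Integer threshold in \[0, 1000\] (default 700).
#' @return Filtered edge tibble.
#' @export
filter_high_confidence <- function(net, min_score = 700) {
  if (min_score < 0 || min_score > 1000) {
    abort("min_score must lie in [0, 1000]")
  }
  all_nodes <- attr(net, "all_nodes") %||%
    sort(unique(c(net$protein1, net$protein2)))
  out <- dplyr::filter(net, .data$combined_score >= min_score)
  attr(out, "all_nodes") <- all_nodes
  attr(out, "min_score") <- min_score
  out
}

edges_to_igraph <- function(edges) {
  igraph::graph_from_data_frame(
    edges[, c("protein1", "protein2")],
    directed = FALSE,
    vertices = sort(unique(c(edges$protein1, edges$protein2)))
  )
}

#' Extract a first-neighbour subnetwork around seed proteins
#'
#' The subnetwork contains the seeds present in the network plus every
#' direct neighbour of a seed, with ALL edges of the parent network among
#' that node set (the induced subgraph, so neighbour--neighbour edges are
#' kept). Seeds absent from the network are recorded in the provenance,
#' never silently dropped; seeds known to the network but isolated after
#' confidence filtering are retained in the node list with no edges.
#'
#' @param net High-confidence edge tibble (see [filter_high_confidence()]).
#' @param seeds Character vector of seed protein ids.
#' @param cluster Optional cluster label carried in the provenance.
#' @return A `pap_subnetwork`: `cluster`, `seeds` (requested),
#'   `seeds_present`, `seeds_missing`, `isolated_seeds`, `nodes`, `edges`.
#' @export
extract_subnetwork <- function(net, seeds, cluster = NA) {
  seeds <- unique(as.character(seeds))
  known <- attr(net, "all_nodes") %||%
    sort(unique(c(net$protein1, net$protein2)))
  connected <- unique(c(net$protein1, net$protein2))

  seeds_missing <- setdiff(seeds, known)
  seeds_present <- intersect(seeds, known)
  if (!length(seeds_present)) {
    abort(paste0("no seed of cluster ", cluster,
                 " is present in the network (missing: ",
                 paste(seeds_missing, collapse = ", "), ")"))
  }
  isolated_seeds <- setdiff(seeds_present, connected)
  live_seeds <- intersect(seeds_present, connected)

  neighbours <- character(0)
  if (length(live_seeds)) {
    g <- edges_to_igraph(net)
    nb <- igraph::ego(g, order = 1, nodes = live_seeds, mode = "all")
    neighbours <- unique(unlist(lapply(nb, names)))
  }
  nodes <- sort(unique(c(seeds_present, neighbours)))
  edges <- dplyr::filter(net, .data$protein1 %in% nodes &
                              .data$protein2 %in% nodes)
  attr(edges, "all_nodes") <- NULL

  structure(
    list(
      cluster = cluster,
      seeds = seeds,
      seeds_present = seeds_present,
      seeds_missing = seeds_missing,
      isolated_seeds = isolated_seeds,
      nodes = nodes,
      edges = tibble::as_tibble(edges)
    ),
    class = "pap_subnetwork"
  )
}

#' @export
print.pap_subnetwork <- function(x, ...) {
  cat("<pap_subnetwork> cluster ", x$cluster, ": ",
      length(x$seeds_present), "/", length(x$seeds), " seeds, ",
      length(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  if (length(x$seeds_missing)) {
    cat("  seeds missing from network:",
        paste(x$seeds_missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build one subnetwork per sector-assigned cluster
#'
#' Clusters whose centroid reaches the sector threshold in at least one
#' condition, and that have at least one seed present in the network, each
#' yield a first-neighbour subnetwork. Clusters failing either gate are
#' skipped with a message; per-cluster extraction errors are collected, not
#' fatal to the batch.
#'
#' @param net High-confidence edge tibble.
#' @param clustering A `pap_kmeans` fit.
#' @param sector_assignment A [assign_sectors()] result.
#' @return Named list of `pap_subnetwork` objects, ordered by cluster
#'   label. Skipped clusters are reported in attribute `skipped`.
#' @export
subnetworks_from_clusters <- function(net, clustering, sector_assignment) {
  stopifnot(inherits(clustering, "pap_kmeans"))
  sets <- sector_sets(sector_assignment)
  out <- list()
  skipped <- character(0)
  for (cl in sort(unique(clustering$assignments$cluster))) {
    if (!length(sets[[as.character(cl)]])) {
      inform(paste0("cluster ", cl,
                    " skipped: no condition at sector threshold"))
      skipped <- c(skipped, paste0(cl, ": below sector threshold"))
      next
    }
    seeds <- clustering$assignments$protein[
      clustering$assignments$cluster == cl]
    sub <- tryCatch(
      extract_subnetwork(net, seeds, cluster = cl),
      error = function(e) {
        inform(paste0("cluster ", cl, " skipped: ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(sub)) {
      skipped <- c(skipped, paste0(cl, ": no seeds in network"))
    } else {
      out[[as.character(cl)]] <- sub
    }
  }
  attr(out, "skipped") <- skipped
  out
}
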