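#' Propagate annotations to is_a ancestors (true-path rule)
#'
#' A gene directly annotated to a term is implicitly annotated to every
#' is_a ancestor of that term up to and including the namespace root.
#'
#' @param dag A [go_dag()].
#' @param annotations Direct annotation tibble (`gene`, `term`; a
#'   `namespace` column is recomputed from the DAG).
#' @return A `go_annotations` object: `direct` and `propagated` annotation
#'   tibbles, per-namespace universe (genes with at least one propagated
#'   annotation), and the namespace roots.
#' @export
propagate_annotations <- function(dag, annotations) {
  stopifnot(inherits(dag, "go_dag"))
  annotations <- tibble::as_tibble(annotations)
  unknown <- setdiff(unique(annotations$term), dag$terms$id)
  if (length(unknown)) {
    abort(paste0("annotation term absent from DAG: ", unknown[1]))
  }
  direct <- dplyr::distinct(annotations[, c("gene", "term")])
  direct$namespace <- go_namespace_of(dag, direct$term)

  propagated <- direct |>
    dplyr::mutate(term = lapply(.data$term, function(t) dag$ancestors[[t]])) |>
    tidyr::unnest_longer("term") |>
    dplyr::distinct(.data$gene, .data$term)
  propagated$namespace <- go_namespace_of(dag, propagated$term)
  propagated <- dplyr::arrange(propagated, .data$namespace, .data$term,
                               .data$gene)

  universe <- lapply(split(propagated$gene, propagated$namespace),
                     function(g) sort(unique(g)))

  structure(
    list(direct = direct, propagated = propagated,
         universe = universe, roots = dag$roots),
    class = "go_annotations"
  )
}

#' @export
print.go_annotations <- function(x, ...) {
  cat("<go_annotations> ", nrow(x$direct), " direct / ",
      nrow(x$propagated), " propagated pairs\n", sep = "")
  for (ns in names(x$universe)) {
    cat("  ", ns, ": ", length(x$universe[[ns]]), " annotated genes\n",
        sep = "")
  }
  invisible(x)
}

#' Hypergeometric GO term enrichment of a study gene set
#'
#' For every term of the namespace with at least one propagated annotation
#' in the study set, computes the upper-tail hypergeometric probability of
#' observing at least the study count by drawing the study set from the
#' background universe. Namespace roots (always annotating the whole
#' universe) are excluded. Results sort by raw p, ties by term id.
#'
#' @param study Character vector of study genes (must lie inside the
#'   universe).
#' @param annotations A [propagate_annotations()] result.
#' @param namespace One of [go_namespaces()].
#' @param universe Optional background gene set; defaults to all genes
#'   with at least one propagated annotation in the namespace.
#' @return Tibble: `term`, `namespace`, `k` (study count), `n` (study
#'   size), `K` (background count), `N` (background size), `p_raw`.
#' @export
enrich <- function(study, annotations, namespace, universe = NULL) {
  stopifnot(inherits(annotations, "go_annotations"))
  namespace <- match.arg(namespace, go_namespaces())
  study <- unique(as.character(study))
  if (!length(study)) abort("empty study set")
  universe <- universe %||% annotations$universe[[namespace]]
  if (is.null(universe) || !length(universe)) {
    abort(paste0("no annotated genes in namespace ", namespace))
  }
  outside <- setdiff(study, universe)
  if (length(outside)) {
    abort(paste0("study gene outside background universe: ", outside[1]))
  }

  ann <- annotations$propagated
  ann <- ann[ann$namespace == namespace & ann$gene %in% universe, ]
  root <- annotations$roots[[namespace]]
  N <- length(universe)
  n <- length(study)

  counts <- ann |>
    dplyr::summarise(
      K = dplyr::n_distinct(.data$gene),
      k = sum(unique(.data$gene) %in% study),
      .by = "term"
    ) |>
    dplyr::filter(.data$k >= 1, .data$term != root)

  counts |>
    dplyr::mutate(
      namespace = namespace,
      n = n,
      N = N,
      p_raw = phyper(.data$k - 1, .data$K, N - .data$K, n,
                     lower.tail = FALSE)
    ) |>
    dplyr::select("term", "namespace", "k", "n", "K", "N", "p_raw") |>
    dplyr::arrange(.data$p_raw, .data$term)
}

#' Bonferroni adjustment within one test family
#'
#' One family is one subnetwork crossed with one namespace: `m` is the
#' number of terms actually tested there, `p_adj = min(1, m * p_raw)`, and
#' a term is significant when `p_adj < alpha`. The degenerate threshold
#' `alpha = 1` retains every tested term (capped adjusted values equal 1
#' exactly and would otherwise be excluded by the strict inequality).
#'
#' @param results Enrichment tibble from [enrich()] (a single family).
#' @param alpha Significance level (default 0.05).
#' @return The tibble with `m`, `p_adj` and `significant` columns added.
#' @export
adjust_bonferroni <- function(results, alpha = 0.05) {
  m <- nrow(results)
  out <- dplyr::mutate(
    results,
    m = m,
    p_adj = pmin(1, m * .data$p_raw),
    significant = .data$p_adj < alpha | alpha >= 1
  )
  attr(out, "alpha") <- alpha
  out
}
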