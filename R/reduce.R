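#' Information content of GO terms
#'
#' `p(term)` is the fraction of the namespace's annotated genes carrying
#' the term after true-path propagation; `IC = -ln p(term)` (nats). The
#' namespace root has p = 1 and IC = 0. Terms with zero propagated
#' annotations have undefined IC and are excluded with a warning.
#'
#' @param dag A [go_dag()].
#' @param annotations A [propagate_annotations()] result.
#' @return Tibble: `term`, `namespace`, `n_genes`, `p_term`, `ic`.
#' @export
information_content <- function(dag, annotations) {
  stopifnot(inherits(dag, "go_dag"), inherits(annotations, "go_annotations"))
  totals <- vapply(annotations$universe, length, integer(1))
  counts <- annotations$propagated |>
    dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene),
                     .by = c("term", "namespace"))
  n_zero <- nrow(dag$terms) - nrow(counts)
  if (n_zero > 0) {
    warn(paste0(n_zero, " term(s) with zero propagated annotations",
                " excluded from IC"))
  }
  counts |>
    dplyr::mutate(
      p_term = .data$n_genes / unname(totals[.data$namespace]),
      ic = -log(.data$p_term)
    ) |>
    dplyr::arrange(.data$namespace, .data$term)
}

#' Lin semantic similarity between two terms
#'
#' `sim = 2 * IC(MICA) / (IC(t1) + IC(t2))`, where MICA is the common is_a
#' ancestor (self included) with maximal information content. The
#' similarity is 0 when the denominator is 0 (both terms are the root).
#' Common ancestors without defined IC are ignored.
#'
#' @param t1,t2 Term ids from the same namespace.
#' @param dag A [go_dag()].
#' @param ic IC tibble from [information_content()].
#' @return Similarity in \[0, 1\].
#' @export
lin_similarity <- function(t1, t2, dag, ic) {
  if (!identical(go_namespace_of(dag, t1), go_namespace_of(dag, t2))) {
    abort(paste0("cross-namespace pair: ", t1, " / ", t2))
  }
  ic_of <- setNames(ic$ic, ic$term)
  if (!t1 %in% names(ic_of) || !t2 %in% names(ic_of)) {
    abort("term without defined IC")
  }
  common <- intersect(go_ancestors(dag, t1), go_ancestors(dag, t2))
  common <- common[common %in% names(ic_of)]
  denom <- ic_of[[t1]] + ic_of[[t2]]
  if (denom == 0 || !length(common)) return(0)
  2 * max(ic_of[common]) / denom
}

# all pairwise Lin similarities among terms (one namespace)
lin_similarity_matrix <- function(terms, dag, ic) {
  n <- length(terms)
  s <- diag(1, n)
  dimnames(s) <- list(terms, terms)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        s[i, j] <- s[j, i] <- lin_similarity(terms[i], terms[j], dag, ic)
      }
    }
  }
  s
}

#' REVIGO-style semantic reduction of significant terms
#'
#' Greedy redundancy removal within one namespace: repeatedly take the most
#' similar remaining pair with similarity strictly above `cutoff` and
#' discard the less significant member (larger adjusted p; ties broken
#' toward the more general term, i.e. larger annotation frequency, then
#' the lexicographically larger id), recording it as merged into the
#' survivor. Stops when all surviving pairs are at or below `cutoff`. The
#' default cutoff 0.5 corresponds to stringent grouping of similar terms.
#'
#' @param results Significant enrichment rows (one namespace) with `term`
#'   and `p_adj` columns.
#' @param dag A [go_dag()].
#' @param ic IC tibble from [information_content()].
#' @param cutoff Similarity cutoff in (0, 1\] (default 0.5).
#' @return A `reduced_terms` object: `representatives` (input rows that
#'   survive), `merged` (tibble term/representative/similarity), `cutoff`.
#' @export
reduce_terms <- function(results, dag, ic, cutoff = 0.5) {
  results <- tibble::as_tibble(results)
  stopifnot(all(c("term", "p_adj") %in% names(results)))
  ns <- unique(go_namespace_of(dag, results$term))
  if (length(ns) > 1) abort("reduce_terms expects a single namespace")
  if (anyDuplicated(results$term)) abort("duplicate term in results")

  p_freq <- setNames(ic$p_term, ic$term)
  p_adj <- setNames(results$p_adj, results$term)
  alive <- results$term
  merged <- list()

  if (length(alive) >= 2) {
    sim <- lin_similarity_matrix(alive, dag, ic)
    repeat {
      live_sim <- sim[alive, alive, drop = FALSE]
      diag(live_sim) <- -Inf
      if (max(live_sim) <= cutoff) break
      # most similar pair; ties resolved by term-id order for determinism
      idx <- which(live_sim == max(live_sim), arr.ind = TRUE)
      idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
      ord <- order(rownames(live_sim)[idx[, 1]], colnames(live_sim)[idx[, 2]])
      pair <- c(rownames(live_sim)[idx[ord[1], 1]],
                colnames(live_sim)[idx[ord[1], 2]])
      drop <- pick_discard(pair, p_adj, p_freq)
      keep <- setdiff(pair, drop)
      merged[[drop]] <- tibble::tibble(
        term = drop, representative = keep,
        similarity = sim[pair[1], pair[2]]
      )
      alive <- setdiff(alive, drop)
    }
  }

  merged <- if (length(merged)) dplyr::bind_rows(merged) else
    tibble::tibble(term = character(), representative = character(),
                   similarity = numeric())
  # re-point discarded terms whose representative was itself discarded later
  if (nrow(merged)) {
    repoint <- setNames(merged$representative, merged$term)
    resolve <- function(t) {
      while (t %in% names(repoint)) t <- repoint[[t]]
      t
    }
    merged$representative <- vapply(merged$term, resolve, character(1),
                                    USE.NAMES = FALSE)
  }

  structure(
    list(
      representatives = results[results$term %in% alive, ],
      merged = merged,
      results = results,
      cutoff = cutoff,
      namespace = ns
    ),
    class = "reduced_terms"
  )
}

# discard rule: larger p_adj; ties -> larger annotation frequency (more
# general); ties -> lexicographically larger term id
pick_discard <- function(pair, p_adj, p_freq) {
  pa <- p_adj[pair]
  if (pa[1] != pa[2]) return(pair[which.max(pa)])
  pf <- p_freq[pair]
  if (pf[1] != pf[2]) return(pair[which.max(pf)])
  max(pair)
}

#' @export
print.reduced_terms <- function(x, ...) {
  cat("<reduced_terms> ", nrow(x$representatives), " representative(s), ",
      nrow(x$merged), " merged at cutoff ", x$cutoff, " (", x$namespace,
      ")\n", sep = "")
  invisible(x)
}

#' @rdname reduce_terms
#' @param x A `reduced_terms` object.
#' @param ... Unused.
#' @method tidy reduced_terms
#' @export
tidy.reduced_terms <- function(x, ...) {
  map <- setNames(x$merged$representative, x$merged$term)
  sim <- setNames(x$merged$similarity, x$merged$term)
  x$results |>
    dplyr::mutate(
      representative = dplyr::coalesce(unname(map[.data$term]), .data$term),
      sim_to_representative = ifelse(.data$term %in% names(sim),
                                     unname(sim[.data$term]), 1),
      surviving = .data$term %in% x$representatives$term
    ) |>
    dplyr::arrange(.data$representative, dplyr::desc(.data$surviving),
                   .data$term)
}
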