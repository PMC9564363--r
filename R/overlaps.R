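#' Partition terms across named sets into shared and set-specific groups
#'
#' Every term of the union is classified by the number of sets it occurs
#' in: exactly one set makes it specific to that set's label, two or more
#' make it shared. By construction the specific groups and the shared
#' group partition the union: sum(specific) + shared = unique total.
#'
#' @param named_sets Named list of character vectors (e.g. one GO term set
#'   per subnetwork); at least two sets, all labels non-empty.
#' @return A `term_partition`: `sets` (deduplicated inputs), `specific`
#'   (named list), `shared` (character vector), `unique_total`,
#'   `per_set_counts`.
#' @export
#' @examples
#' partition_terms(list(A = c("t1", "t2"), B = c("t2", "t3"), C = "t4"))
partition_terms <- function(named_sets) {
  if (length(named_sets) < 2) abort("need at least two named sets")
  labels <- names(named_sets)
  if (is.null(labels) || any(is.na(labels) | labels == "")) {
    abort("every set needs a non-empty label")
  }
  if (anyDuplicated(labels)) abort("duplicate set label")
  sets <- lapply(named_sets, function(s) unique(as.character(s)))

  occ <- table(unlist(sets, use.names = FALSE))
  union_terms <- names(occ)
  shared <- sort(union_terms[occ >= 2])
  specific <- lapply(sets, function(s) sort(s[occ[s] == 1]))

  structure(
    list(
      sets = sets,
      specific = specific,
      shared = shared,
      unique_total = length(union_terms),
      per_set_counts = vapply(sets, length, integer(1))
    ),
    class = "term_partition"
  )
}

#' @export
print.term_partition <- function(x, ...) {
  cat("<term_partition> ", length(x$sets), " sets, ", x$unique_total,
      " unique terms: ", length(x$shared), " shared, ",
      sum(lengths(x$specific)), " specific\n", sep = "")
  invisible(x)
}

#' Summary counts of a term partition
#'
#' @param partition A [partition_terms()] result.
#' @return One-row tibble: `n_sets`, `total_with_multiplicity` (terms
#'   summed over sets), `n_unique`, `n_shared`, `n_specific` (summed over
#'   sets), plus a nested `specific_by_set` tibble of per-set specific
#'   counts.
#' @export
summarize_partition <- function(partition) {
  stopifnot(inherits(partition, "term_partition"))
  tibble::tibble(
    n_sets = length(partition$sets),
    total_with_multiplicity = sum(partition$per_set_counts),
    n_unique = partition$unique_total,
    n_shared = length(partition$shared),
    n_specific = sum(lengths(partition$specific)),
    specific_by_set = list(tibble::tibble(
      set = names(partition$specific),
      n = lengths(partition$specific) |> unname()
    ))
  )
}

#' Venn cell counts of a partition
#'
#' Per-intersection breakdown: each occupied combination of sets
#' (membership signature) with its term count.
#'
#' @param partition A [partition_terms()] result.
#' @return Tibble: `sets` (labels joined by `&`), `degree`, `n_terms`.
#' @export
venn_cells <- function(partition) {
  stopifnot(inherits(partition, "term_partition"))
  labels <- names(partition$sets)
  union_terms <- sort(unique(unlist(partition$sets, use.names = FALSE)))
  sig <- vapply(union_terms, function(t) {
    paste(labels[vapply(partition$sets, function(s) t %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  tab <- table(sig)
  tibble::tibble(
    sets = names(tab),
    degree = vapply(strsplit(names(tab), "&", fixed = TRUE), length,
                    integer(1)),
    n_terms = as.integer(tab)
  ) |>
    dplyr::arrange(.data$degree, .data$sets)
}
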