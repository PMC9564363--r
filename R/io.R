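#' Read a protein abundance table
#'
#' Expects a CSV whose first column (`protein`) holds unique protein/spot
#' identifiers and whose remaining columns are the six conditions named by
#' [pap_conditions()], in any order. Values are raw spot densities and must
#' be strictly positive (the log2 normalization downstream is undefined at
#' zero).
#'
#' @param path Path to a CSV file.
#' @return Tibble: `protein` plus the six condition columns in canonical
#'   order.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"protein" %in% names(tbl)) {
    names(tbl)[1] <- "protein"
  }
  missing <- setdiff(pap_conditions(), names(tbl))
  if (length(missing)) {
    abort(paste0("missing condition column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl <- tbl[, c("protein", pap_conditions())]
  tbl$protein <- as.character(tbl$protein)
  dup <- tbl$protein[duplicated(tbl$protein)]
  if (length(dup)) {
    abort(paste0("duplicate protein ID: ", dup[1]))
  }
  validate_abundance(tbl)
  tbl
}

validate_abundance <- function(tbl) {
  for (cond in pap_conditions()) {
    v <- tbl[[cond]]
    if (!is.numeric(v)) {
      abort(paste0("non-numeric abundance in column ", cond))
    }
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad)) {
      abort(paste0("non-positive abundance for protein ",
                   tbl$protein[bad[1]], ", condition ", cond,
                   " (value ", v[bad[1]], ")"))
    }
  }
  invisible(tbl)
}

#' Write a protein abundance table
#' @param table Abundance tibble (`protein` + six condition columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path) {
  readr::write_csv(table[, c("protein", pap_conditions())], path)
  invisible(path)
}

#' Read a STRING-style PPI edge list
#'
#' Tab-separated file with header `protein1`, `protein2`, `combined_score`
#' (integer confidence on the 0--1000 scale). The result is an undirected
#' simple edge list: self-loops are dropped with a warning, and duplicate
#' undirected pairs are collapsed keeping the maximum score (conservative
#' with respect to the downstream high-confidence filter).
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `protein1`, `protein2`, `combined_score`;
#'   endpoints are ordered so `protein1 < protein2`. The set of node ids
#'   seen in the file (including those only on dropped self-loops) is
#'   attached as attribute `all_nodes`.
#' @export
read_ppi_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(tbl))) {
    abort(paste0("PPI file must have columns: ", paste(need, collapse = ", ")))
  }
  tbl <- tbl[, need]
  tbl$protein1 <- as.character(tbl$protein1)
  tbl$protein2 <- as.character(tbl$protein2)
  if (any(is.na(tbl$protein1) | is.na(tbl$protein2) |
          !is.finite(tbl$combined_score))) {
    abort("malformed PPI row (missing endpoint or score)")
  }
  ppi_network(tbl)
}

#' Canonicalize an edge table into a simple undirected PPI network
#'
#' @param edges Tibble/data frame with `protein1`, `protein2`,
#'   `combined_score`.
#' @return Canonical edge tibble (see [read_ppi_tsv()]).
#' @export
ppi_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  sc <- edges$combined_score
  if (any(sc < 0 | sc > 1000 | sc != round(sc))) {
    bad <- which(sc < 0 | sc > 1000 | sc != round(sc))[1]
    abort(paste0("combined_score outside integer [0,1000]: row ", bad,
                 " (", sc[bad], ")"))
  }
  edges$combined_score <- as.integer(sc)
  all_nodes <- sort(unique(c(edges$protein1, edges$protein2)))

  loops <- edges$protein1 == edges$protein2
  if (any(loops)) {
    warn(paste0("dropped ", sum(loops), " self-loop(s)"))
    edges <- edges[!loops, ]
  }
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  edges <- tibble::tibble(protein1 = a, protein2 = b,
                          combined_score = edges$combined_score)
  edges <- edges |>
    dplyr::summarise(
      combined_score = max(.data$combined_score),
      .by = c("protein1", "protein2")
    ) |>
    dplyr::arrange(.data$protein1, .data$protein2)
  attr(edges, "all_nodes") <- all_nodes
  edges
}

#' Write a PPI edge list as TSV
#' @param edges Edge tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ppi_tsv <- function(edges, path) {
  readr::write_tsv(edges[, c("protein1", "protein2", "combined_score")], path)
  invisible(path)
}

#' Read a minimal OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas for `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete`. Obsolete terms are excluded (including as parents).
#' `relationship:` lines (part_of etc.) are ignored and counted; only is_a
#' parentage enters the DAG. Dangling is_a references and cycles are errors.
#'
#' @param path Path to an OBO file.
#' @return A [go_dag()] object; the number of skipped relationship lines is
#'   attached as attribute `n_relationship_skipped`.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)

  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) abort("no [Term] stanzas found")
  stanza_breaks <- which(grepl("^\\[", lines))
  n_rel_skipped <- 0L

  records <- lapply(term_starts, function(s) {
    nxt <- stanza_breaks[stanza_breaks > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):e]
    field <- function(key) {
      m <- grepl(paste0("^", key, ":"), block)
      trimws(sub(paste0("^", key, ":\\s*"), "", block[m]))
    }
    n_rel_skipped <<- n_rel_skipped + sum(grepl("^relationship:", block))
    is_a <- field("is_a")
    is_a <- trimws(sub("!.*$", "", is_a))   # strip trailing "! name" comments
    list(
      id = field("id")[1],
      name = if (length(field("name"))) field("name")[1] else NA_character_,
      namespace = if (length(field("namespace"))) field("namespace")[1]
                  else NA_character_,
      is_a = is_a,
      obsolete = any(field("is_obsolete") == "true")
    )
  })

  obsolete_ids <- vapply(records, function(r) if (r$obsolete) r$id else NA_character_,
                         character(1))
  obsolete_ids <- obsolete_ids[!is.na(obsolete_ids)]
  records <- Filter(function(r) !r$obsolete, records)
  if (!length(records)) abort("no non-obsolete terms")

  ids <- vapply(records, `[[`, character(1), "id")
  if (any(is.na(ids)) || any(!grepl("^GO:\\d{7}$", ids))) {
    abort(paste0("term id does not match GO:NNNNNNN: ",
                 ids[!grepl("^GO:\\d{7}$", ids)][1]))
  }
  ns <- vapply(records, `[[`, character(1), "namespace")
  if (any(is.na(ns))) {
    abort(paste0("term missing namespace: ", ids[is.na(ns)][1]))
  }
  terms <- tibble::tibble(
    id = ids,
    name = vapply(records, `[[`, character(1), "name"),
    namespace = ns
  )
  parents <- purrr::map_dfr(records, function(r) {
    if (!length(r$is_a)) return(NULL)
    tibble::tibble(id = r$id, parent = r$is_a)
  })
  # references to obsolete parents are dropped like the obsolete terms
  if (nrow(parents)) parents <- parents[!parents$parent %in% obsolete_ids, ]

  dag <- go_dag(terms, parents)
  attr(dag, "n_relationship_skipped") <- n_rel_skipped
  dag
}

#' Write a DAG as minimal OBO 1.2
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  parents <- split(dag$parents$parent, dag$parents$id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c(
      "[Term]",
      paste0("id: ", id),
      paste0("name: ", dag$terms$name[i]),
      paste0("namespace: ", dag$terms$namespace[i]),
      if (!is.null(parents[[id]])) paste0("is_a: ", parents[[id]]),
      ""
    ), con)
  }
  invisible(path)
}

#' Read gene-to-term annotations
#'
#' Tab-separated file with header `gene`, `term`, `namespace` (direct
#' annotations, one pair per row). Pairs referencing terms absent from the
#' DAG are dropped with a message reporting the count; duplicates collapse
#' to one (set semantics). The stored namespace is taken from the DAG.
#'
#' @param path Path to a TSV file.
#' @param dag A [go_dag()] the terms must belong to.
#' @return Tibble `gene`, `term`, `namespace`; number of dropped rows in
#'   attribute `n_dropped`.
#' @export
read_annotations <- function(path, dag) {
  stopifnot(inherits(dag, "go_dag"))
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("gene", "term") %in% names(tbl))) {
    abort("annotation file must have columns gene, term")
  }
  tbl$gene <- as.character(tbl$gene)
  if (any(is.na(tbl$gene) | is.na(tbl$term))) abort("unreadable annotation row")
  known <- tbl$term %in% dag$terms$id
  n_dropped <- sum(!known)
  if (n_dropped) {
    inform(paste0("dropped ", n_dropped,
                  " annotation(s) referencing unknown terms"))
  }
  tbl <- tbl[known, c("gene", "term")]
  tbl$namespace <- go_namespace_of(dag, tbl$term)
  tbl <- dplyr::distinct(tbl) |>
    dplyr::arrange(.data$gene, .data$term)
  attr(tbl, "n_dropped") <- n_dropped
  tbl
}

#' Write annotations as TSV
#' @param annotations Tibble `gene`, `term`, `namespace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  readr::write_tsv(annotations[, c("gene", "term", "namespace")], path)
  invisible(path)
}
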