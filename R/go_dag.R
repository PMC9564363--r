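#' Construct a GO DAG from term and parent tables
#'
#' Builds the in-memory ontology object used by annotation propagation,
#' enrichment and semantic reduction. Only `is_a` parentage is modelled.
#' Each namespace must contain exactly one root (a term with no parents),
#' the parent relation must be acyclic, every parent reference must resolve,
#' and parent/child must share a namespace.
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`.
#' @param parents Tibble with columns `id`, `parent` (is_a edges).
#' @return An object of class `go_dag`: the term table, the edge table, a
#'   named vector of namespace roots, and a precomputed ancestor map
#'   (each term's is_a ancestors, self included).
#' @export
go_dag <- function(terms, parents) {
  terms <- tibble::as_tibble(terms)
  parents <- tibble::as_tibble(parents)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  stopifnot(all(c("id", "parent") %in% names(parents)))
  if (anyDuplicated(terms$id)) {
    abort(paste0("duplicate term id: ",
                 terms$id[duplicated(terms$id)][1]))
  }
  bad_ns <- setdiff(unique(terms$namespace), go_namespaces())
  if (length(bad_ns)) {
    abort(paste0("unknown namespace: ", bad_ns[1]))
  }
  dangling <- setdiff(c(parents$id, parents$parent), terms$id)
  if (length(dangling)) {
    abort(paste0("is_a reference to unknown term: ", dangling[1]))
  }

  ns <- setNames(terms$namespace, terms$id)
  cross <- ns[parents$id] != ns[parents$parent]
  if (any(cross)) {
    abort(paste0("is_a edge crosses namespaces: ",
                 parents$id[cross][1], " -> ", parents$parent[cross][1]))
  }

  g <- igraph::graph_from_data_frame(
    parents[, c("id", "parent")],
    directed = TRUE,
    vertices = terms$id
  )
  if (!igraph::is_dag(g)) {
    abort("cycle detected in is_a relationships")
  }

  # ancestors (self included) for every term, child -> parent direction
  anc <- lapply(
    igraph::ego(g, order = igraph::vcount(g), mode = "out"),
    function(v) names(v)
  )
  names(anc) <- igraph::V(g)$name

  has_parent <- terms$id %in% parents$id
  roots <- terms[!has_parent, ]
  root_per_ns <- split(roots$id, roots$namespace)
  multi <- names(root_per_ns)[lengths(root_per_ns) > 1]
  if (length(multi)) {
    abort(paste0("namespace ", multi[1], " has more than one root"))
  }
  root_vec <- vapply(root_per_ns, identity, character(1))

  # every non-root term must reach its namespace root
  reaches <- vapply(terms$id, function(id) {
    root_vec[[ns[[id]]]] %in% anc[[id]]
  }, logical(1))
  if (!all(reaches)) {
    abort(paste0("term does not reach its namespace root: ",
                 terms$id[!reaches][1]))
  }

  structure(
    list(terms = terms, parents = parents, roots = root_vec, ancestors = anc),
    class = "go_dag"
  )
}

#' is_a ancestors of a term
#'
#' @param dag A `go_dag`.
#' @param term Term id.
#' @param include_self Include the term itself (default TRUE).
#' @return Character vector of ancestor ids.
#' @export
go_ancestors <- function(dag, term, include_self = TRUE) {
  stopifnot(inherits(dag, "go_dag"))
  if (!term %in% names(dag$ancestors)) {
    abort(paste0("term not in DAG: ", term))
  }
  out <- dag$ancestors[[term]]
  if (!include_self) out <- setdiff(out, term)
  out
}

#' Namespace of each given term
#' @param dag A `go_dag`.
#' @param terms Term ids.
#' @return Character vector of namespaces.
#' @export
go_namespace_of <- function(dag, terms) {
  ns <- setNames(dag$terms$namespace, dag$terms$id)
  unknown <- setdiff(terms, names(ns))
  if (length(unknown)) abort(paste0("term not in DAG: ", unknown[1]))
  unname(ns[terms])
}

#' @export
print.go_dag <- function(x, ...) {
  cat("<go_dag> ", nrow(x$terms), " terms, ", nrow(x$parents),
      " is_a edges, ", length(x$roots), " namespace root(s)\n", sep = "")
  for (ns in names(x$roots)) {
    cat("  ", ns, ": root ", x$roots[[ns]], " (",
        sum(x$terms$namespace == ns), " terms)\n", sep = "")
  }
  invisible(x)
}
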