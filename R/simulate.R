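#' Simulation configuration with planted, recoverable structure
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the bent-root study design this pipeline is built around: 66 proteins in
#' six condition-peaking clusters of sizes 12/4/11/3/16/20 over the six
#' sector/side conditions, a PPI layer in which each cluster has one
#' designated hub sitting in clique-rich high-confidence neighbourhoods on
#' a sparse low-confidence background, and a three-namespace GO corpus in
#' which one leaf term per (cluster, namespace) is over-represented among
#' that cluster's subnetwork genes.
#'
#' @param n_proteins Number of abundance rows (default 66).
#' @param cluster_sizes Planted cluster sizes, summing to `n_proteins`
#'   (default `c(12, 4, 11, 3, 16, 20)`).
#' @param centroid_matrix Per-cluster mean normalized profile, a
#'   `n_clusters x 6` matrix in log2 units (default: the package's built-in
#'   reference centroid matrix, see [reference_centroids()]).
#' @param noise_sd Gaussian noise standard deviation in log2 units
#'   (default 0.3, a realistic spot-density log-ratio spread).
#' @param base_level Raw density around which profiles are back-transformed
#'   (default 1000 arbitrary units).
#' @param n_background_nodes Extra background proteins in the PPI layer
#'   (default 60).
#' @param background_edge_prob Erdős–Rényi probability of a low-confidence
#'   background edge (default 0.05).
#' @param planted_clique_sizes Sizes of the cliques planted through each
#'   cluster's hub (default `c(5, 5, 5)`), all >= 2; cliques overlap only
#'   at the hub, so the hub's planted MCC is `sum((sizes - 1)!)` in the
#'   full graph.
#' @param score_high_range,score_low_range Integer score intervals inside
#'   \[0, 1000\] for planted and background edges; the high range must lie
#'   entirely at or above `min_score`, the low range entirely below.
#' @param min_score High-confidence threshold the score ranges must
#'   respect (default 700).
#' @param n_terms_per_namespace GO terms per namespace, root included
#'   (default 40).
#' @param dag_depth Levels below the namespace root (default 4, >= 2).
#' @param extra_parent_prob Probability of a second is_a parent (diamond
#'   structure; default 0.2).
#' @param baseline_annotation_prob Probability that a gene carries a given
#'   leaf term (default 0.05).
#' @param enriched_annotation_prob Elevated probability for planted
#'   (term, gene-set) pairs (default 0.9); must exceed the baseline.
#' @param seed Integer RNG seed; one seed drives all components through
#'   deterministic sub-streams.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_proteins = 66,
                              cluster_sizes = c(12, 4, 11, 3, 16, 20),
                              centroid_matrix = NULL,
                              noise_sd = 0.3,
                              base_level = 1000,
                              n_background_nodes = 60,
                              background_edge_prob = 0.05,
                              planted_clique_sizes = c(5, 5, 5),
                              score_high_range = c(700, 1000),
                              score_low_range = c(150, 699),
                              min_score = 700,
                              n_terms_per_namespace = 40,
                              dag_depth = 4,
                              extra_parent_prob = 0.2,
                              baseline_annotation_prob = 0.05,
                              enriched_annotation_prob = 0.9,
                              seed = 1) {
  n_clusters <- length(cluster_sizes)
  if (sum(cluster_sizes) != n_proteins) {
    abort("cluster_sizes must sum to n_proteins")
  }
  if (is.null(centroid_matrix)) {
    ref <- reference_centroids()
    if (n_clusters > nrow(ref)) {
      abort("supply centroid_matrix when asking for more than 6 clusters")
    }
    centroid_matrix <- as.matrix(ref[seq_len(n_clusters), pap_conditions()])
  }
  centroid_matrix <- as.matrix(centroid_matrix)
  if (!all(dim(centroid_matrix) == c(n_clusters, 6))) {
    abort("centroid_matrix must be n_clusters x 6")
  }
  colnames(centroid_matrix) <- pap_conditions()
  if (noise_sd <= 0) abort("noise_sd must be > 0")
  for (p in c(background_edge_prob, baseline_annotation_prob,
              enriched_annotation_prob)) {
    if (p < 0 || p > 1) abort("probabilities must lie in [0, 1]")
  }
  if (enriched_annotation_prob <= baseline_annotation_prob) {
    abort("enriched_annotation_prob must exceed baseline_annotation_prob")
  }
  check_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1000) {
      abort(paste0(nm, " must be an ordered sub-interval of [0, 1000]"))
    }
  }
  check_range(score_high_range, "score_high_range")
  check_range(score_low_range, "score_low_range")
  if (score_high_range[1] < min_score) {
    abort("score_high_range must lie entirely at or above min_score")
  }
  if (score_low_range[2] >= min_score) {
    abort("score_low_range must lie entirely below min_score")
  }
  if (any(planted_clique_sizes < 2)) {
    abort("planted clique sizes must be >= 2")
  }
  if (dag_depth < 2) abort("dag_depth must be >= 2")

  structure(
    list(
      n_proteins = n_proteins,
      n_clusters = n_clusters,
      cluster_sizes = cluster_sizes,
      centroid_matrix = centroid_matrix,
      noise_sd = noise_sd,
      base_level = base_level,
      n_background_nodes = n_background_nodes,
      background_edge_prob = background_edge_prob,
      planted_clique_sizes = planted_clique_sizes,
      score_high_range = score_high_range,
      score_low_range = score_low_range,
      min_score = min_score,
      n_terms_per_namespace = n_terms_per_namespace,
      dag_depth = dag_depth,
      extra_parent_prob = extra_parent_prob,
      baseline_annotation_prob = baseline_annotation_prob,
      enriched_annotation_prob = enriched_annotation_prob,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Built-in reference centroid matrix
#'
#' The six-cluster centroid matrix (log2 profile units over the six
#' conditions) reported by the bent-poplar-root proteomic study this
#' pipeline reimplements, shipped as plain text in `extdata`. Used as the
#' default planted centroids of the simulator and as the worked example
#' for sector assignment.
#'
#' @return Tibble: `cluster` (1--6), the six condition columns, `size`,
#'   `withinss`.
#' @export
reference_centroids <- function() {
  path <- system.file("extdata", "reference_centroids.tsv",
                      package = "papnet", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Published subnetwork-specific GO term lists
#'
#' The per-subnetwork-specific GO identifiers (by namespace) reported by
#' the study, shipped as plain text; used as worked-example input to the
#' term-partition operations.
#'
#' @return Tibble: `cluster`, `namespace`, `term`.
#' @export
reference_specific_terms <- function() {
  path <- system.file("extdata", "reference_specific_go_terms.tsv",
                      package = "papnet", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# recentre a log2 profile so mean(2^p) == 1, making the downstream
# normalization its exact inverse
recentre_profile <- function(p) {
  p - log2(mean(2^p))
}

#' Generate a synthetic abundance table with planted clusters
#'
#' Rows are drawn per cluster as centroid + iid Gaussian noise in log2
#' profile space, recentred so the per-row geometric constraint
#' `mean(2^profile) = 1` holds exactly, then back-transformed to strictly
#' positive raw densities around `base_level`. [normalize_abundance()]
#' recovers the profile exactly.
#'
#' @param config A [simulation_config()].
#' @return List: `table` (abundance tibble), `labels` (tibble
#'   protein/cluster ground truth), `profiles` (the planted normalized
#'   profiles).
#' @export
generate_abundance_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_local_seed(derive_seed(config$seed, "abundance"), {
    labels <- rep(seq_len(config$n_clusters), config$cluster_sizes)
    ids <- sprintf("P%03d", seq_len(config$n_proteins))
    for (attempt in 1:10) {
      prof <- t(vapply(labels, function(cl) {
        recentre_profile(config$centroid_matrix[cl, ] +
                           rnorm(6, 0, config$noise_sd))
      }, numeric(6)))
      values <- config$base_level * 2^prof
      if (all(is.finite(values) & values > 0)) break
      if (attempt == 10) {
        abort("could not generate strictly positive abundances; centroid/noise out of range")
      }
    }
    colnames(values) <- pap_conditions()
    colnames(prof) <- pap_conditions()
    list(
      table = dplyr::bind_cols(tibble::tibble(protein = ids),
                               tibble::as_tibble(values)),
      labels = tibble::tibble(protein = ids, cluster = labels),
      profiles = dplyr::bind_cols(tibble::tibble(protein = ids),
                                  tibble::as_tibble(prof))
    )
  })
}

#' Generate a synthetic PPI network with planted hub cliques
#'
#' For each cluster, one designated hub node is planted inside
#' high-confidence cliques (sizes from `planted_clique_sizes`) that
#' pairwise overlap only at the hub, so the hub's planted MCC is known in
#' closed form as `sum((size - 1)!)`. Clique members are the cluster's
#' seed proteins (spread round-robin so each clique touches a seed when
#' enough seeds exist) padded with filler nodes. On top sits an
#' Erdős–Rényi background among background nodes and seeds with
#' low-confidence scores, so the high-confidence filter separates planted
#' from background edges exactly.
#'
#' @param config A [simulation_config()].
#' @param seed_assignments Named list: cluster label -> seed protein ids.
#' @return List: `edges` (canonical edge tibble), `hubs` (tibble
#'   cluster/hub), `planted_edges` (tibble of the planted high-confidence
#'   edges), `cliques` (list of planted clique node sets).
#' @export
generate_ppi_network <- function(config, seed_assignments) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(names(seed_assignments))) {
    abort("seed_assignments must be a named list (cluster -> proteins)")
  }
  all_seeds <- unlist(seed_assignments, use.names = FALSE)
  if (anyDuplicated(all_seeds)) abort("duplicate node identifiers in seeds")

  with_local_seed(derive_seed(config$seed, "network"), {
    hub_tbl <- tibble::tibble(
      cluster = names(seed_assignments),
      hub = sprintf("HUB_%s", names(seed_assignments))
    )
    planted <- list()
    clique_list <- list()
    for (ci in seq_along(seed_assignments)) {
      cl <- names(seed_assignments)[ci]
      hub <- hub_tbl$hub[ci]
      seeds <- seed_assignments[[ci]]
      sizes <- config$planted_clique_sizes
      # round-robin the seeds over the cliques; pad with filler nodes
      pools <- split(seeds, rep_len(seq_along(sizes), length(seeds)))
      fill_counter <- 0L
      for (qi in seq_along(sizes)) {
        need <- sizes[qi] - 1L           # hub occupies one slot
        members <- head(pools[[as.character(qi)]] %||% character(0), need)
        while (length(members) < need) {
          fill_counter <- fill_counter + 1L
          members <- c(members, sprintf("FILL_%s_%02d", cl, fill_counter))
        }
        clique <- c(hub, members)
        clique_list[[length(clique_list) + 1L]] <- clique
        pr <- t(combn(sort(clique), 2))
        planted[[length(planted) + 1L]] <- tibble::tibble(
          protein1 = pr[, 1], protein2 = pr[, 2]
        )
      }
    }
    planted <- dplyr::distinct(dplyr::bind_rows(planted))
    planted$combined_score <- sample(
      config$score_high_range[1]:config$score_high_range[2],
      nrow(planted), replace = TRUE
    )

    bg_nodes <- if (config$n_background_nodes > 0) {
      sprintf("BG%03d", seq_len(config$n_background_nodes))
    } else character(0)
    er_nodes <- sort(unique(c(bg_nodes, all_seeds)))
    bg_edges <- NULL
    if (length(er_nodes) >= 2 && config$background_edge_prob > 0) {
      pairs <- t(combn(er_nodes, 2))
      keep <- runif(nrow(pairs)) < config$background_edge_prob
      pairs <- pairs[keep, , drop = FALSE]
      if (nrow(pairs)) {
        bg_edges <- tibble::tibble(
          protein1 = pairs[, 1], protein2 = pairs[, 2],
          combined_score = sample(
            config$score_low_range[1]:config$score_low_range[2],
            nrow(pairs), replace = TRUE
          )
        )
        # planted pairs win over background duplicates
        bg_edges <- dplyr::anti_join(
          bg_edges, planted, by = c("protein1", "protein2")
        )
      }
    }
    edges <- ppi_network(dplyr::bind_rows(planted, bg_edges))
    list(
      edges = edges,
      hubs = hub_tbl,
      planted_edges = planted,
      cliques = clique_list
    )
  })
}

go_term_ids <- function(namespace, n) {
  offset <- switch(namespace,
                   biological_process = 1000000L,
                   molecular_function = 2000000L,
                   cellular_component = 3000000L)
  sprintf("GO:%07d", offset + seq_len(n))
}

#' Generate a synthetic GO DAG and annotation corpus with planted signal
#'
#' Builds one rooted is_a DAG per namespace (a layered tree of depth
#' `dag_depth` with occasional second parents forming diamonds), annotates
#' every gene of the universe to each leaf term independently at the
#' baseline probability, then over-annotates one designated leaf term per
#' (gene set, namespace) at the enriched probability. The planted terms
#' are returned as ground truth.
#'
#' @param config A [simulation_config()].
#' @param subnetwork_gene_sets Named list: set label -> gene ids to enrich.
#' @param universe Character vector of all genes to annotate (defaults to
#'   the union of the gene sets).
#' @return List: `dag` (a [go_dag()]), `annotations` (tibble
#'   gene/term/namespace), `planted` (tibble set/namespace/term).
#' @export
generate_go_resources <- function(config, subnetwork_gene_sets,
                                  universe = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  universe <- universe %||%
    sort(unique(unlist(subnetwork_gene_sets, use.names = FALSE)))
  if (!length(universe)) abort("empty annotation universe")

  with_local_seed(derive_seed(config$seed, "annotation"), {
    terms <- list()
    parents <- list()
    leaves <- list()
    for (ns in go_namespaces()) {
      ids <- go_term_ids(ns, config$n_terms_per_namespace)
      root <- ids[1]
      level <- c(0L, sort(rep_len(seq_len(config$dag_depth),
                                  length(ids) - 1L)))
      terms[[ns]] <- tibble::tibble(
        id = ids,
        name = paste0("synthetic ", ns, " term ", seq_along(ids)),
        namespace = ns
      )
      par <- list()
      for (i in seq_along(ids)[-1]) {
        above <- ids[level == level[i] - 1L]
        p1 <- if (length(above) == 1) above else sample(above, 1)
        ps <- p1
        if (length(above) > 1 && runif(1) < config$extra_parent_prob) {
          ps <- c(ps, sample(setdiff(above, p1), 1))
        }
        par[[ids[i]]] <- tibble::tibble(id = ids[i], parent = ps)
      }
      parents[[ns]] <- dplyr::bind_rows(par)
      leaves[[ns]] <- setdiff(ids, parents[[ns]]$parent)
    }
    dag <- go_dag(dplyr::bind_rows(terms), dplyr::bind_rows(parents))

    planted <- list()
    ann <- list()
    for (ns in go_namespaces()) {
      lv <- leaves[[ns]]
      set_labels <- names(subnetwork_gene_sets) %||% character(0)
      if (length(lv) < length(set_labels)) {
        abort("not enough leaf terms to plant one per gene set")
      }
      planted_terms <- if (length(set_labels)) sample(lv, length(set_labels))
                       else character(0)
      planted[[ns]] <- tibble::tibble(
        set = set_labels, namespace = ns, term = planted_terms
      )
      for (t in lv) {
        hit <- runif(length(universe)) < config$baseline_annotation_prob
        genes <- universe[hit]
        si <- match(t, planted_terms)
        if (!is.na(si)) {
          members <- intersect(subnetwork_gene_sets[[si]], universe)
          extra <- members[runif(length(members)) <
                             config$enriched_annotation_prob]
          genes <- union(genes, extra)
          # degenerate baseline 0 means: exactly the enriched draws
          if (config$baseline_annotation_prob == 0) genes <- extra
        }
        if (length(genes)) {
          ann[[paste(ns, t)]] <- tibble::tibble(gene = genes, term = t,
                                                namespace = ns)
        }
      }
    }
    annotations <- dplyr::bind_rows(ann) |>
      dplyr::distinct() |>
      dplyr::arrange(.data$namespace, .data$term, .data$gene)
    list(dag = dag, annotations = annotations,
         planted = dplyr::bind_rows(planted))
  })
}

#' Simulate a complete study bundle
#'
#' Runs the three generators with one seed: abundance table with planted
#' cluster labels, PPI network with planted hubs seeded by the true
#' cluster memberships, and GO resources enriching one term per (cluster,
#' namespace) among each cluster's subnetwork genes (seeds plus planted
#' clique members), over the universe of all network nodes. Optionally
#' writes every artifact plus a ground-truth JSON to `outdir`.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional output directory.
#' @return List: `config`, `abundance`, `labels`, `profiles`, `network`
#'   (edges/hubs/planted), `go` (dag/annotations/planted), `files`
#'   (written paths, when `outdir` is given).
#' @export
simulate_study <- function(config = simulation_config(), outdir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  ab <- generate_abundance_table(config)
  seed_sets <- split(ab$labels$protein, ab$labels$cluster)
  net <- generate_ppi_network(config, seed_sets)

  clique_nodes <- lapply(net$cliques, identity)
  gene_sets <- lapply(seq_along(seed_sets), function(ci) {
    cl <- names(seed_sets)[ci]
    hub <- net$hubs$hub[net$hubs$cluster == cl]
    members <- unlist(Filter(function(q) hub %in% q, clique_nodes))
    sort(unique(c(seed_sets[[ci]], members)))
  })
  names(gene_sets) <- names(seed_sets)
  universe <- sort(unique(c(net$edges$protein1, net$edges$protein2)))
  go <- generate_go_resources(config, gene_sets, universe = universe)

  out <- list(config = config, abundance = ab$table, labels = ab$labels,
              profiles = ab$profiles, network = net, go = go)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      abundance = file.path(outdir, "abundance.csv"),
      ppi = file.path(outdir, "ppi.tsv"),
      obo = file.path(outdir, "ontology.obo"),
      annotations = file.path(outdir, "annotations.tsv"),
      truth = file.path(outdir, "ground_truth.json")
    )
    write_abundance(ab$table, files[["abundance"]])
    write_ppi_tsv(net$edges, files[["ppi"]])
    write_obo(go$dag, files[["obo"]])
    write_annotations(go$annotations, files[["annotations"]])
    jsonlite::write_json(
      list(
        labels = ab$labels,
        hubs = net$hubs,
        planted_terms = go$planted,
        seed = config$seed
      ),
      files[["truth"]], dataframe = "columns", auto_unbox = TRUE
    )
    out$files <- files
  }
  out
}
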