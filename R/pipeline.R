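#' Pipeline run configuration
#'
#' Collects every stage parameter plus either input paths or a simulation
#' config. Defaults are the study's printed parameters: k = 6 clusters,
#' sector score threshold 0.3, STRING combined-score threshold 700,
#' Bonferroni alpha 0.05, semantic-reduction cutoff 0.5, top 3 hub genes.
#'
#' @param abundance,ppi,obo,annotations Input paths (all four, or none to
#'   simulate).
#' @param simulation A [simulation_config()] used when paths are absent.
#' @param k Number of k-means clusters.
#' @param sector_threshold Centroid score threshold (log2 units).
#' @param min_score High-confidence combined-score threshold in \[0,1000\].
#' @param alpha Bonferroni significance level in (0, 1\].
#' @param reduction_cutoff Semantic similarity cutoff in (0, 1\].
#' @param top_k Number of hub genes per subnetwork.
#' @param n_init,max_iter k-means restart and iteration caps.
#' @param seed Integer seed driving the whole run.
#' @param outdir Output directory (default a fresh temporary directory).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(abundance = NULL, ppi = NULL, obo = NULL,
                            annotations = NULL,
                            simulation = simulation_config(),
                            k = 6, sector_threshold = 0.3, min_score = 700,
                            alpha = 0.05, reduction_cutoff = 0.5, top_k = 3,
                            n_init = 25, max_iter = 100,
                            seed = 1, outdir = tempfile("papnet_run_")) {
  paths <- list(abundance = abundance, ppi = ppi, obo = obo,
                annotations = annotations)
  given <- !vapply(paths, is.null, logical(1))
  if (any(given) && !all(given)) {
    abort("provide all four input paths, or none (simulation mode)")
  }
  if (min_score < 0 || min_score > 1000) abort("min_score outside [0, 1000]")
  if (alpha <= 0 || alpha > 1) abort("alpha outside (0, 1]")
  if (reduction_cutoff <= 0 || reduction_cutoff > 1) {
    abort("reduction_cutoff outside (0, 1]")
  }
  if (top_k < 1) abort("top_k must be >= 1")
  structure(
    list(paths = if (all(given)) paths else NULL,
         simulation = simulation, k = k,
         sector_threshold = sector_threshold, min_score = min_score,
         alpha = alpha, reduction_cutoff = reduction_cutoff,
         top_k = top_k, n_init = n_init, max_iter = max_iter,
         seed = as.integer(seed), outdir = outdir),
    class = "pipeline_config"
  )
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value` (comments with `#`); numeric values are
#' coerced. Recognized keys are the arguments of [pipeline_config()]
#' (paths and scalar parameters).
#'
#' @param path Config file path.
#' @param overrides Named character vector of `key=value` overrides.
#' @return A `pipeline_config`.
#' @export
read_run_config <- function(path, overrides = character(0)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  vals <- setNames(vapply(kv, `[[`, character(1), 2),
                   vapply(kv, `[[`, character(1), 1))
  if (length(overrides)) {
    okv <- strsplit(overrides, "=", fixed = TRUE)
    vals[vapply(okv, `[[`, character(1), 1)] <-
      vapply(okv, function(x) paste(x[-1], collapse = "="), character(1))
  }
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  known <- setdiff(names(formals(pipeline_config)), c("simulation", "outdir"))
  unknown <- setdiff(names(args), c(known, "outdir"))
  if (length(unknown)) {
    abort(paste0("unknown config key: ", unknown[1]))
  }
  do.call(pipeline_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full pipeline
#'
#' Executes simulate/read -> normalize -> k-means -> sector assignment ->
#' high-confidence filter -> first-neighbour subnetworks -> per-namespace
#' enrichment with Bonferroni control -> semantic reduction -> shared vs
#' specific term partitioning -> MCC hub ranking, writing every
#' intermediate artifact under `config$outdir` plus a JSON manifest with
#' per-stage counts and md5 checksums. Identical config and seed yield
#' identical artifacts and checksums.
#'
#' @param config A [pipeline_config()].
#' @return A `papnet_run`: all in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files[[name]] <<- path
    path
  }
  counts <- list()

  # ---- inputs ----
  if (is.null(config$paths)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- config$seed
    sim <- stage("simulate", simulate_study(sim_cfg, outdir = outdir))
    for (nm in names(sim$files)) files[[basename(sim$files[[nm]])]] <-
      sim$files[[nm]]
    abundance <- sim$abundance
    dag <- sim$go$dag
    annotations_tbl <- sim$go$annotations
    net_raw <- sim$network$edges
    truth <- list(labels = sim$labels, hubs = sim$network$hubs,
                  planted_terms = sim$go$planted)
  } else {
    abundance <- stage("read_abundance", read_abundance(config$paths$abundance))
    net_raw <- stage("read_ppi", read_ppi_tsv(config$paths$ppi))
    dag <- stage("read_obo", read_obo(config$paths$obo))
    annotations_tbl <- stage("read_annotations",
                             read_annotations(config$paths$annotations, dag))
    truth <- NULL
  }
  counts$proteins <- nrow(abundance)
  counts$ppi_edges <- nrow(net_raw)

  # ---- profiles ----
  profiles <- stage("normalize", normalize_abundance(abundance))
  fit <- stage("kmeans", kmeans_profiles(
    profiles, k = config$k, n_init = config$n_init,
    max_iter = config$max_iter, seed = derive_seed(config$seed, "pipeline")
  ))
  stopifnot(sum(fit$sizes) == nrow(abundance))   # cluster-size conservation
  sectors <- assign_sectors(fit, threshold = config$sector_threshold)
  emit("clusters.tsv", \(p) readr::write_tsv(augment(fit), p))
  emit("centroids.tsv", \(p) readr::write_tsv(tidy(fit), p))
  emit("sectors.json", \(p) jsonlite::write_json(
    sector_sets(sectors), p, auto_unbox = FALSE))
  counts$clusters <- fit$k
  counts$cluster_sizes <- as.integer(fit$sizes)

  # ---- network ----
  net <- stage("filter", filter_high_confidence(net_raw, config$min_score))
  counts$high_confidence_edges <- nrow(net)
  subnets <- stage("subnetworks",
                   subnetworks_from_clusters(net, fit, sectors))
  counts$subnetworks <- length(subnets)
  for (nm in names(subnets)) {
    emit(paste0("subnetwork_", nm, ".tsv"),
         \(p) write_ppi_tsv(subnets[[nm]]$edges, p))
  }
  emit("subnetworks.json", \(p) jsonlite::write_json(
    lapply(subnets, function(s) list(
      cluster = s$cluster, seeds = s$seeds_present,
      missing_seeds = s$seeds_missing, n_nodes = length(s$nodes),
      n_edges = nrow(s$edges))),
    p, auto_unbox = TRUE))

  # ---- enrichment + reduction ----
  annset <- stage("propagate", propagate_annotations(dag, annotations_tbl))
  ic <- suppressWarnings(information_content(dag, annset))
  enrichment <- list()
  reduced <- list()
  for (nm in names(subnets)) {
    nodes <- subnets[[nm]]$nodes
    for (ns in go_namespaces()) {
      study <- intersect(nodes, annset$universe[[ns]])
      if (!length(study)) next
      res <- stage(paste0("enrich_", nm, "_", ns), {
        enrich(study, annset, ns) |> adjust_bonferroni(config$alpha)
      })
      enrichment[[paste(nm, ns, sep = ".")]] <- res
      sig <- res[res$significant, ]
      if (nrow(sig)) {
        reduced[[paste(nm, ns, sep = ".")]] <- stage(
          paste0("reduce_", nm, "_", ns),
          reduce_terms(sig, dag, ic, cutoff = config$reduction_cutoff)
        )
      }
    }
  }
  enr_cols <- c("cluster", "term", "namespace", "k", "n", "K", "N",
                "p_raw", "m", "p_adj", "significant")
  enr_tbl <- if (length(enrichment)) {
    dplyr::bind_rows(enrichment, .id = "family") |>
      tidyr::separate_wider_delim("family", delim = ".",
                                  names = c("cluster", "ns_key"))
  } else {
    tibble::as_tibble(setNames(rep(list(character(0)), length(enr_cols)),
                               enr_cols))
  }
  emit("enrichment.tsv", \(p) readr::write_tsv(enr_tbl[, enr_cols], p))
  red_tbl <- dplyr::bind_rows(
    lapply(reduced, tidy), .id = "family"
  )
  emit("reduced_terms.tsv", \(p) readr::write_tsv(red_tbl, p))
  counts$enriched_terms <- sum(vapply(enrichment,
                                      function(r) sum(r$significant),
                                      integer(1)))
  counts$reduced_terms <- sum(vapply(reduced,
                                     function(r) nrow(r$representatives),
                                     integer(1)))

  # ---- overlaps ----
  partitions <- list()
  for (ns in go_namespaces()) {
    sets <- lapply(names(subnets), function(nm) {
      r <- reduced[[paste(nm, ns, sep = ".")]]
      if (is.null(r)) character(0) else r$representatives$term
    })
    names(sets) <- names(subnets)
    if (length(sets) >= 2) {
      partitions[[ns]] <- stage(paste0("partition_", ns),
                                partition_terms(sets))
    }
  }
  part_summary <- dplyr::bind_rows(
    lapply(partitions, function(p) {
      s <- summarize_partition(p)
      s$specific_by_set <- NULL
      s
    }),
    .id = "namespace"
  )
  emit("term_partition.json", \(p) jsonlite::write_json(
    lapply(partitions, function(x) list(
      shared = x$shared, specific = x$specific,
      unique_total = x$unique_total)),
    p, auto_unbox = FALSE))
  emit("term_partition_summary.tsv", \(p) readr::write_tsv(part_summary, p))

  # ---- hubs ----
  hubs <- list()
  for (nm in names(subnets)) {
    if (!nrow(subnets[[nm]]$edges)) next
    hubs[[nm]] <- stage(paste0("hubs_", nm),
                        top_hubs(subnets[[nm]], k = config$top_k))
    emit(paste0("hubs_", nm, ".tsv"),
         \(p) readr::write_tsv(tidy(hubs[[nm]]), p))
  }
  emit("hubs.json", \(p) jsonlite::write_json(
    lapply(hubs, function(h) list(top = h$top, hub_clique = h$hub_clique,
                                  n_cliques = h$n_cliques)),
    p, auto_unbox = TRUE))
  counts$hub_triangles <- sum(vapply(hubs, function(h) h$hub_clique,
                                     logical(1)))

  # ---- manifest ----
  manifest <- list(
    package_version = as.character(utils::packageVersion("papnet")),
    seed = config$seed,
    parameters = list(
      k = config$k, sector_threshold = config$sector_threshold,
      min_score = config$min_score, alpha = config$alpha,
      reduction_cutoff = config$reduction_cutoff, top_k = config$top_k
    ),
    counts = counts,
    checksums = as.list(tools::md5sum(unlist(files)) |>
                          setNames(names(files)))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  structure(
    list(config = config, abundance = abundance, profiles = profiles,
         clustering = fit, sectors = sectors, network = net,
         subnetworks = subnets, annotations = annset, ic = ic,
         enrichment = enrichment, reduced = reduced,
         partitions = partitions, hubs = hubs, truth = truth,
         manifest = manifest, outdir = outdir),
    class = "papnet_run"
  )
}

#' @export
print.papnet_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<papnet_run> seed ", x$config$seed, "\n",
      "  ", cts$proteins, " proteins -> ", cts$clusters, " clusters (",
      paste(cts$cluster_sizes, collapse = "/"), ")\n",
      "  ", cts$high_confidence_edges, "/", cts$ppi_edges,
      " high-confidence edges -> ", cts$subnetworks, " subnetworks\n",
      "  ", cts$enriched_terms, " significant terms -> ",
      cts$reduced_terms, " after semantic reduction\n",
      "  hub triangles: ", cts$hub_triangles, "/", length(x$hubs), "\n",
      sep = "")
  invisible(x)
}
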