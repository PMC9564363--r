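#' Normalize abundances into protein abundance profiles (PAPs)
#'
#' Each value becomes `log2(x / mean_protein)` where `mean_protein` is that
#' protein's mean raw abundance over the six conditions. The profile is
#' therefore scale-free per protein: multiplying a row by any positive
#' constant leaves it unchanged, and for every protein the mean of
#' `2^profile` over conditions is exactly 1.
#'
#' @param table Abundance tibble (`protein` + six condition columns), all
#'   values strictly positive.
#' @return Tibble of the same shape with log2-ratio values.
#' @export
#' @examples
#' tbl <- tibble::tibble(protein = "p1",
#'   `ABS-cx` = 8, `BS-cx` = 2, `BBS-cx` = 2,
#'   `ABS-cv` = 2, `BS-cv` = 2, `BBS-cv` = 2)
#' normalize_abundance(tbl)
normalize_abundance <- function(table) {
  table <- tibble::as_tibble(table)
  validate_abundance(table)
  m <- as.matrix(table[, pap_conditions()])
  prof <- log2(m / rowMeans(m))
  out <- tibble::as_tibble(prof)
  dplyr::bind_cols(table["protein"], out)
}

profile_matrix <- function(profiles) {
  m <- as.matrix(profiles[, pap_conditions()])
  rownames(m) <- profiles$protein
  if (any(!is.finite(m))) abort("non-finite profile value")
  m
}

# squared Euclidean distances points x centers
dist2 <- function(X, C) {
  d <- outer(rowSums(X^2), rowSums(C^2), `+`) - 2 * X %*% t(C)
  pmax(d, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    for (j in 2:k) {
      d <- dist2(X, X[centers[1:(j - 1)], , drop = FALSE])
      dmin <- apply(d, 1, min)
      if (sum(dmin) == 0) {
        centers[j] <- sample.int(n, 1)
      } else {
        centers[j] <- sample.int(n, 1, prob = dmin / sum(dmin))
      }
    }
  }
  X[centers, , drop = FALSE]
}

# Lloyd iterations; ties to the lowest cluster index; an emptied cluster is
# reseeded from the point farthest from its current centroid
lloyd <- function(X, C, max_iter) {
  n <- nrow(X); k <- nrow(C)
  assign_old <- rep(0L, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d <- dist2(X, C)
    assign_new <- max.col(-d, ties.method = "first")
    for (j in which(tabulate(assign_new, k) == 0)) {
      far <- which.max(d[cbind(seq_len(n), assign_new)])
      assign_new[far] <- j
    }
    for (j in seq_len(k)) {
      members <- assign_new == j
      if (any(members)) C[j, ] <- colMeans(X[members, , drop = FALSE])
    }
    if (identical(assign_new, assign_old) || iter >= max_iter) break
    assign_old <- assign_new
  }
  d <- dist2(X, C)
  withinss <- vapply(seq_len(k), function(j) {
    sum(d[assign_new == j, j])
  }, numeric(1))
  list(assignment = assign_new, centers = C, withinss = withinss, iter = iter)
}

#' Cluster abundance profiles by k-means
#'
#' Lloyd's algorithm with squared-Euclidean distance, k-means++ seeding and
#' `n_init` restarts, keeping the restart with the lowest total
#' within-cluster sum of squares. Fully deterministic for a given seed.
#' Nearest-centroid ties break to the lowest cluster index; a cluster
#' emptied during iteration is reseeded from the farthest point. Cluster
#' labels are re-indexed in decreasing cluster-size order after fitting so
#' that labels are stable across runs.
#'
#' @param profiles Normalized profile tibble from [normalize_abundance()].
#' @param k Number of clusters (default 6).
#' @param n_init Number of k-means++ restarts (default 25).
#' @param max_iter Maximum Lloyd iterations per restart (default 100).
#' @param seed Integer RNG seed.
#' @return A `pap_kmeans` object: `assignments` (tibble protein/cluster),
#'   `centroids` (tibble cluster + condition columns, log2 units),
#'   `withinss`, `sizes`, `totss`, `k`, `seed`, `iterations`.
#' @export
kmeans_profiles <- function(profiles, k = 6, n_init = 25, max_iter = 100,
                            seed = 1) {
  X <- profile_matrix(profiles)
  if (k > nrow(X)) abort(paste0("k = ", k, " exceeds n proteins = ", nrow(X)))
  if (n_init < 1) abort("n_init must be >= 1")

  best <- NULL
  with_local_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- lloyd(X, kmeanspp_init(X, k), max_iter)
      if (is.null(best) || sum(fit$withinss) < sum(best$withinss)) best <- fit
    }
  })

  # relabel in decreasing size order (stable: ties keep first-seen order)
  sizes <- tabulate(best$assignment, k)
  relabel <- order(order(-sizes))          # old label -> new label
  new_assign <- relabel[best$assignment]
  perm <- order(relabel)                   # new label -> old label
  centers <- best$centers[perm, , drop = FALSE]
  withinss <- best$withinss[perm]
  sizes <- sizes[perm]

  centroids <- tibble::as_tibble(centers)
  names(centroids) <- pap_conditions()
  centroids <- dplyr::bind_cols(
    tibble::tibble(cluster = seq_len(k)), centroids
  )

  structure(
    list(
      assignments = tibble::tibble(protein = rownames(X),
                                   cluster = new_assign),
      centroids = centroids,
      withinss = withinss,
      sizes = sizes,
      totss = sum(scale(X, scale = FALSE)^2),
      k = k,
      n_init = n_init,
      iterations = best$iter,
      seed = seed,
      profiles = tibble::as_tibble(profiles)
    ),
    class = "pap_kmeans"
  )
}

#' @export
print.pap_kmeans <- function(x, ...) {
  cat("<pap_kmeans> k =", x$k, "on", nrow(x$assignments), "proteins\n")
  cat("  sizes:   ", paste(x$sizes, collapse = ", "), "\n")
  cat("  withinss:", paste(signif(x$withinss, 6), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname kmeans_profiles
#' @param x,object A `pap_kmeans` object.
#' @param ... Unused.
#' @method tidy pap_kmeans
#' @export
tidy.pap_kmeans <- function(x, ...) {
  dplyr::bind_cols(
    x$centroids,
    tibble::tibble(size = x$sizes, withinss = x$withinss)
  )
}

#' @rdname kmeans_profiles
#' @method glance pap_kmeans
#' @export
glance.pap_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n = nrow(x$assignments),
    tot_withinss = sum(x$withinss),
    totss = x$totss,
    iterations = x$iterations
  )
}

#' @rdname kmeans_profiles
#' @method augment pap_kmeans
#' @export
augment.pap_kmeans <- function(x, ...) {
  dplyr::left_join(x$profiles, x$assignments, by = "protein")
}

#' Assign clusters to bent-root sectors/sides by centroid score
#'
#' A cluster characterizes every condition whose centroid value (log2
#' profile units) is at or above `threshold`. A cluster may characterize
#' several conditions or none; clusters with no condition at threshold do
#' not seed subnetworks downstream.
#'
#' @param x A `pap_kmeans` fit, or a centroid tibble with a `cluster`
#'   column and the six condition columns.
#' @param threshold Score threshold in log2 units (default 0.3).
#' @return A `sector_assignment` tibble: `cluster`, `sector`, `score`, one
#'   row per (cluster, condition) at or above threshold. The threshold and
#'   the full cluster list are carried as attributes.
#' @export
assign_sectors <- function(x, threshold = 0.3) {
  centroids <- if (inherits(x, "pap_kmeans")) x$centroids else
    tibble::as_tibble(x)
  stopifnot("cluster" %in% names(centroids),
            all(pap_conditions() %in% names(centroids)))
  long <- tidyr::pivot_longer(
    centroids[, c("cluster", pap_conditions())],
    cols = dplyr::all_of(pap_conditions()),
    names_to = "sector", values_to = "score"
  )
  out <- long |>
    dplyr::filter(.data$score >= threshold) |>
    dplyr::arrange(.data$cluster,
                   match(.data$sector, pap_conditions()))
  attr(out, "threshold") <- threshold
  attr(out, "clusters") <- centroids$cluster
  class(out) <- c("sector_assignment", class(out))
  out
}

#' Sector sets per cluster
#'
#' @param assignment A [assign_sectors()] result.
#' @return Named list, one character vector of conditions per cluster
#'   (possibly empty).
#' @export
sector_sets <- function(assignment) {
  clusters <- attr(assignment, "clusters")
  out <- lapply(clusters, function(cl) {
    assignment$sector[assignment$cluster == cl]
  })
  names(out) <- as.character(clusters)
  out
}

#' Profile plot of a k-means fit
#'
#' One panel per cluster; grey lines are member profiles, the coloured line
#' the cluster centroid, with the sector-score threshold as a dashed rule.
#'
#' @param object A `pap_kmeans` object.
#' @param threshold Reference threshold drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pap_kmeans
#' @export
autoplot.pap_kmeans <- function(object, threshold = 0.3, ...) {
  members <- augment(object) |>
    tidyr::pivot_longer(dplyr::all_of(pap_conditions()),
                        names_to = "condition", values_to = "value")
  cent <- object$centroids |>
    tidyr::pivot_longer(dplyr::all_of(pap_conditions()),
                        names_to = "condition", values_to = "value")
  members$condition <- factor(members$condition, levels = pap_conditions())
  cent$condition <- factor(cent$condition, levels = pap_conditions())
  ggplot2::ggplot(members,
                  ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$protein),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(
      data = cent,
      ggplot2::aes(group = .data$cluster, colour = factor(.data$cluster)),
      linewidth = 1
    ) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "log2 abundance / mean", colour = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
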