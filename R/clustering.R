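#' One-dimensional k-means
#'
#' Lloyd iterations to convergence, best of `n_restarts` random
#' initializations by within-cluster sum of squares (WCSS), deterministic
#' given `seed`. Centroids are returned in ascending order with
#' assignments relabelled accordingly.
#'
#' @param values Numeric vector.
#' @param k Number of clusters, `<=` the number of distinct values.
#' @param n_restarts Random restarts (default 25).
#' @param seed Integer seed.
#' @return List with `assignments` (integer cluster per value),
#'   `centroids` (ascending), `wcss`.
#' @export
kmeans_1d <- function(values, k, n_restarts = 25L, seed = 1L) {
  if (anyNA(values)) abort_domain("kmeans_1d: missing values not allowed")
  n_distinct <- length(unique(values))
  if (k > n_distinct) {
    abort_domain(sprintf("kmeans_1d: k = %d exceeds %d distinct values",
                         k, n_distinct))
  }
  if (k == 1L) {
    ctr <- mean(values)
    return(list(assignments = rep(1L, length(values)), centroids = ctr,
                wcss = sum((values - ctr)^2)))
  }
  fit <- withr::with_seed(seed, suppressWarnings(
    stats::kmeans(values, centers = k, nstart = n_restarts,
                  iter.max = 300L, algorithm = "Lloyd")))
  ord <- order(fit$centers[, 1])
  relabel <- match(seq_len(k), ord)
  list(assignments = relabel[fit$cluster],
       centroids = as.numeric(fit$centers[ord, 1]),
       wcss = fit$tot.withinss)
}

#' Elbow-based selection of the cluster count
#'
#' Runs [kmeans_1d()] for `k = 1..k_max` and selects the elbow of the
#' WCSS curve as the `k` (searched over `2..k_max-1`) maximizing the
#' second difference of the curve. By default the second difference is
#' taken on `log(WCSS)` — relative curvature — because absolute second
#' differences are dominated by the largest-scale drops (e.g. splitting
#' off one extreme outlier) and miss the visually obvious elbow;
#' `scale = "raw"` gives the absolute-scale variant. A flat curve returns
#' `k = 1` with a warning. `k_override` forces the selection.
#'
#' @param values Numeric vector.
#' @param k_max Largest k to evaluate (`>= 3`).
#' @param seed Integer seed for the restarts.
#' @param n_restarts Restarts per k.
#' @param scale `"log"` (default) or `"raw"` WCSS scale for the second
#'   difference.
#' @param k_override Optional manual k.
#' @return List with `k_selected` and `wcss_curve` (tibble `k`, `wcss`).
#' @export
elbow_select <- function(values, k_max = 8L, seed = 1L, n_restarts = 25L,
                         scale = c("log", "raw"), k_override = NULL) {
  scale <- match.arg(scale)
  if (k_max < 3L) abort_domain("elbow_select needs k_max >= 3")
  k_max <- min(k_max, length(unique(values)))
  wcss <- vapply(seq_len(k_max), function(k) {
    kmeans_1d(values, k, n_restarts = n_restarts, seed = seed + k)$wcss
  }, numeric(1))
  curve <- tibble::tibble(k = seq_len(k_max), wcss = wcss)
  if (!is.null(k_override)) {
    return(list(k_selected = as.integer(k_override), wcss_curve = curve))
  }
  if (k_max < 3L || wcss[1] <= sqrt(.Machine$double.eps)) {
    warning("degenerate WCSS curve; returning k = 1")
    return(list(k_selected = 1L, wcss_curve = curve))
  }
  w <- if (scale == "log") log(pmax(wcss, 1e-12)) else wcss
  ks <- 2:(k_max - 1L)
  d2 <- vapply(ks, function(k) w[k - 1] - 2 * w[k] + w[k + 1], numeric(1))
  list(k_selected = ks[which.max(d2)], wcss_curve = curve)
}

#' Cluster patients on normalized elongation
#'
#' K-means clustering of the cohort's NE values with elbow-based k
#' selection. Clusters of size `<= outlier_size` are flagged as outliers
#' and their members removed; the remaining clusters are relabelled
#' `low` / `intermediate` / `high` (or `low` / `high` for two) by
#' ascending centroid. Clustering is not rerun after removal: outliers
#' are excluded from downstream analysis, not from the fit.
#'
#' @param cohort Tibble with `patient_id` and `ne` columns.
#' @param k_max Largest k for the elbow search.
#' @param seed Integer seed.
#' @param outlier_size Maximum cluster cardinality flagged as outlier
#'   (default 1, singletons).
#' @param ... Passed to [elbow_select()].
#' @return List of class `cluster_result`: `k_selected`, `assignments`
#'   (tibble `patient_id`, `cluster`, `group`), `centroids` (named by
#'   group), `wcss_curve`, `removed_outliers` (patient ids).
#' @export
cluster_ne <- function(cohort, k_max = 8L, seed = 1L, outlier_size = 1L, ...) {
  ne <- cohort$ne
  if (sum(is.finite(ne)) < 4L) abort_domain("cluster_ne needs >= 4 finite NE values")
  if (length(unique(ne)) < 2L) abort_domain("cluster_ne: all NE values equal")
  sel <- elbow_select(ne, k_max = k_max, seed = seed, ...)
  fit <- kmeans_1d(ne, sel$k_selected, seed = seed)
  sizes <- tabulate(fit$assignments, nbins = sel$k_selected)
  outlier_clusters <- which(sizes <= outlier_size)
  removed <- cohort$patient_id[fit$assignments %in% outlier_clusters]
  keep_clusters <- setdiff(seq_len(sel$k_selected), outlier_clusters)
  if (length(keep_clusters) < 2L) {
    abort_domain("cluster_ne: fewer than 2 clusters remain after outlier removal")
  }
  group_names <- if (length(keep_clusters) == 2L) c("low", "high")
  else if (length(keep_clusters) == 3L) c("low", "intermediate", "high")
  else paste0("group", seq_along(keep_clusters))
  # keep_clusters is already in ascending-centroid order (kmeans_1d sorts)
  relabel <- stats::setNames(group_names, keep_clusters)
  keep <- fit$assignments %in% keep_clusters
  assignments <- tibble::tibble(
    patient_id = cohort$patient_id[keep],
    cluster = fit$assignments[keep],
    group = unname(relabel[as.character(fit$assignments[keep])])
  )
  structure(list(
    k_selected = sel$k_selected,
    assignments = assignments,
    centroids = stats::setNames(fit$centroids[keep_clusters], group_names),
    wcss_curve = sel$wcss_curve,
    removed_outliers = removed
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> k = %d, %d final groups, %d outlier(s) removed\n",
              x$k_selected, length(x$centroids), length(x$removed_outliers)))
  cat("centroids:\n"); print(round(x$centroids, 3))
  invisible(x)
}

#' Draw NE values for calibrated patient groups
#'
#' Gaussian NE draws for a set of groups plus optional extreme outlier
#' patients, used to probe the clustering stage against known group
#' means.
#'
#' @param n_per_group Integer vector of group sizes.
#' @param means Group means (same length).
#' @param sd Common within-group standard deviation.
#' @param outliers Numeric vector of outlier NE values appended at the
#'   end (default none).
#' @param seed Integer seed.
#' @return Tibble with `patient_id`, `ne`, `true_group` (group index, or
#'   `"outlier"`).
#' @export
simulate_ne_groups <- function(n_per_group, means, sd = 0.12,
                               outliers = numeric(), seed = 1L) {
  stopifnot(length(n_per_group) == length(means))
  ne <- withr::with_seed(seed, unlist(Map(function(n, m) stats::rnorm(n, m, sd),
                                          n_per_group, means)))
  grp <- rep(as.character(seq_along(means)), n_per_group)
  ne <- c(ne, outliers)
  grp <- c(grp, rep("outlier", length(outliers)))
  tibble::tibble(patient_id = sprintf("S%03d", seq_along(ne)),
                 ne = ne, true_group = grp)
}
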