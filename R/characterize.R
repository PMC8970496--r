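## Stage 1: measure dataset and cluster-structure characteristics from a
## (possibly labelled) matrix. Elongation is assessed in the 2-component PCA
## projection, mirroring visual inspection of score plots; density and
## outliers are assessed in the full feature space.

#' Default characterization thresholds
#'
#' The qualitative characteristics are operationalized with configurable
#' cutoffs: a dataset is "small" below 1000 samples and "high-dimensional"
#' above 50 features; clusters are "uneven" when min/max size falls below
#' 0.5, "variable density" when the max/min ratio of per-cluster mean
#' nearest-neighbour distances exceeds 2, "non-spherical" when the
#' axis-ratio of the within-cluster 2-D projected covariance exceeds 2, and
#' "outliers present" when more than 2% of points are flagged.
#'
#' @param small_threshold samples below which a dataset is small.
#' @param high_dim_threshold features above which a dataset is
#'   high-dimensional.
#' @param balance_threshold min/max cluster-size ratio below which sizes are
#'   uneven.
#' @param density_threshold density-variation ratio above which density is
#'   variable.
#' @param elongation_threshold projected axis ratio above which clusters are
#'   non-spherical.
#' @param outlier_threshold outlier fraction above which outliers are flagged.
#' @return A named list of thresholds.
#' @export
characterize_thresholds <- function(small_threshold = 1000,
                                    high_dim_threshold = 50,
                                    balance_threshold = 0.5,
                                    density_threshold = 2,
                                    elongation_threshold = 2,
                                    outlier_threshold = 0.02) {
  list(small_threshold = small_threshold,
       high_dim_threshold = high_dim_threshold,
       balance_threshold = balance_threshold,
       density_threshold = density_threshold,
       elongation_threshold = elongation_threshold,
       outlier_threshold = outlier_threshold)
}

#' Dataset-level characteristics
#'
#' Counts and the two threshold flags that drive the dataset side of a
#' requirement profile.
#'
#' @param m a [dataset_matrix()].
#' @param thresholds see [characterize_thresholds()].
#' @return A list of class `dataset_characteristics`: `n_samples`,
#'   `n_features`, `n_classes` (or `NA` when unlabelled), `small_dataset`,
#'   `high_dimensional`.
#' @examples
#' characterize_dataset(dataset_matrix(matrix(0, 150, 4) + rnorm(600)))
#' @export
characterize_dataset <- function(m, thresholds = characterize_thresholds()) {
  stopifnot(inherits(m, "dataset_matrix"))
  if (nrow(m$values) == 0 || ncol(m$values) == 0) stop("empty dataset")
  n <- nrow(m$values); p <- ncol(m$values)
  structure(list(
    n_samples = n, n_features = p,
    n_classes = if (is.null(m$labels)) NA_integer_
                else length(unique(m$labels[m$labels > 0L])),
    small_dataset = n < thresholds$small_threshold,
    high_dimensional = p > thresholds$high_dim_threshold),
    class = "dataset_characteristics")
}

#' @export
print.dataset_characteristics <- function(x, ...) {
  cat("<dataset_characteristics> ", x$n_samples, " x ", x$n_features,
      if (!is.na(x$n_classes)) paste0(", ", x$n_classes, " classes"),
      "; small=", x$small_dataset, ", high_dimensional=", x$high_dimensional,
      "\n", sep = "")
  invisible(x)
}

#' Principal component projection
#'
#' Mean-centred (not scaled) projection onto the top `q` principal axes,
#' with the per-axis share of total variance — the score-plot view used to
#' inspect cluster structure. Scaling, where appropriate, is the
#' preprocessing module's job ([standardize()]).
#'
#' @param m a [dataset_matrix()] or numeric matrix.
#' @param q number of components, at most `min(n_samples - 1, n_features)`.
#' @return A list of class `pca_result` with `scores` (n x q) and
#'   `explained_fraction` (length q, non-increasing, summing to at most 1).
#' @export
project_pca <- function(m, q = 2) {
  x <- if (inherits(m, "dataset_matrix")) m$values else as.matrix(m)
  if (q > min(nrow(x) - 1L, ncol(x)))
    stop("q = ", q, " exceeds min(n_samples - 1, n_features) = ",
         min(nrow(x) - 1L, ncol(x)))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = q)
  total_var <- sum(apply(x, 2, stats::var))
  ef <- if (total_var > 0) pc$sdev[seq_len(q)]^2 / total_var else rep(0, q)
  structure(list(scores = pc$x[, seq_len(q), drop = FALSE],
                 explained_fraction = ef),
            class = "pca_result")
}

## mean distance to the nearest same-cluster neighbour; NA for size-1 groups
.cluster_nn_dists <- function(x) {
  n <- nrow(x)
  if (n < 2) return(NA_real_)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  apply(d, 1, min)
}

#' Cluster-structure characteristics
#'
#' Measures the structure of labelled clusters: per-cluster sizes and
#' balance, singleton clusters, density variation (max/min of per-cluster
#' mean nearest-neighbour distance in full space), elongation (largest
#' within-cluster axis ratio sqrt(lambda1/lambda2) in the 2-component PCA
#' projection), and an outlier fraction. Outliers are points whose
#' within-cluster nearest-neighbour distance exceeds a robust fence
#' (cluster median plus three MADs, taken on the log scale because the
#' distances are right-skewed), plus any points already carrying the `0`
#' noise label.
#' Clusters of size 1 are excluded from density and elongation statistics
#' (and their lone point cannot be an outlier: it IS the cluster).
#'
#' @param m a [dataset_matrix()].
#' @param labels integer labels; defaults to `m$labels`. `0` marks
#'   noise/outlier points, which are excluded from cluster sizes.
#' @param thresholds see [characterize_thresholds()].
#' @param estimated marks the result as derived from provisional labels.
#' @return A list of class `cluster_structure` with fields `n_clusters`,
#'   `sizes`, `balance_ratio`, `has_single_point_cluster`,
#'   `density_variation_ratio`, `max_elongation`, `outlier_fraction`,
#'   `flags` (named logical over the five cluster characteristics), and
#'   `estimated`.
#' @export
characterize_clusters <- function(m, labels = m$labels,
                                  thresholds = characterize_thresholds(),
                                  estimated = FALSE) {
  stopifnot(inherits(m, "dataset_matrix"))
  if (is.null(labels)) stop("labels are required; see estimate_structure_unlabelled()")
  labels <- as.integer(labels)
  if (length(labels) != nrow(m$values)) stop("labels length mismatch")
  n <- length(labels)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0) stop("no cluster labels > 0")
  sizes <- vapply(ids, function(g) sum(labels == g), 0L)
  names(sizes) <- ids
  balance <- min(sizes) / max(sizes)
  singleton <- min(sizes) == 1L

  ## density: mean nearest-neighbour distance per cluster, full space
  nn_by_cluster <- lapply(ids, function(g)
    .cluster_nn_dists(m$values[labels == g, , drop = FALSE]))
  mean_nn <- vapply(nn_by_cluster, function(v) mean(v), 0)
  mean_nn <- mean_nn[!is.na(mean_nn) & mean_nn > 0]
  density_ratio <- if (length(mean_nn) >= 2) max(mean_nn) / min(mean_nn) else 1

  ## elongation: within-cluster covariance axis ratio in the 2-PC projection
  max_elong <- 1
  if (ncol(m$values) >= 2 && nrow(m$values) >= 3) {
    sc <- project_pca(m, q = 2)$scores
    for (g in ids[sizes >= 3]) {
      ev <- eigen(stats::cov(sc[labels == g, , drop = FALSE]),
                  symmetric = TRUE, only.values = TRUE)$values
      if (ev[2] > 0) max_elong <- max(max_elong, sqrt(ev[1] / ev[2]))
      else if (ev[1] > 0) max_elong <- Inf
    }
  }

  ## outliers: labelled noise plus within-cluster nearest-neighbour outliers.
  ## The robust fence is median + 3 MAD on the log scale: nearest-neighbour
  ## distances are positive and right-skewed, and the symmetric fence fires
  ## on >5% of points of a clean Gaussian cluster in 2-D, which would
  ## contradict the 2% flag threshold on outlier-free data.
  n_out <- sum(labels == 0L)
  for (j in seq_along(ids)) {
    v <- nn_by_cluster[[j]]
    if (length(v) < 3 || anyNA(v) || any(v <= 0)) next
    lv <- log(v)
    cut <- stats::median(lv) + 3 * stats::mad(lv)
    n_out <- n_out + sum(lv > cut)
  }
  out_frac <- n_out / n

  flags <- c(
    non_spherical_shape = max_elong > thresholds$elongation_threshold,
    variable_cluster_density = density_ratio > thresholds$density_threshold,
    single_point_cluster = singleton,
    uneven_cluster_size = balance < thresholds$balance_threshold,
    robust_noise_outliers = out_frac > thresholds$outlier_threshold)

  structure(list(n_clusters = length(ids), sizes = sizes,
                 balance_ratio = balance,
                 has_single_point_cluster = singleton,
                 density_variation_ratio = density_ratio,
                 max_elongation = max_elong,
                 outlier_fraction = out_frac,
                 flags = flags, estimated = estimated),
            class = "cluster_structure")
}

#' @export
print.cluster_structure <- function(x, ...) {
  cat("<cluster_structure>", if (x$estimated) "(estimated)", x$n_clusters,
      "clusters, sizes", paste(x$sizes, collapse = "/"), "\n")
  cat(sprintf("  balance=%.3f singleton=%s density_ratio=%.2f elongation=%.2f outliers=%.3f\n",
              x$balance_ratio, x$has_single_point_cluster,
              x$density_variation_ratio, x$max_elongation, x$outlier_fraction))
  on <- names(x$flags)[x$flags]
  cat("  flags:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Estimate cluster structure without labels
#'
#' When no labels are available, provisional labels are obtained by cutting a
#' Ward-linkage dendrogram at `k` clusters and the labelled characterization
#' is applied to them. The result is marked `estimated`.
#'
#' @param m an unlabelled [dataset_matrix()].
#' @param k provisional number of clusters, `1 <= k <= n_samples`.
#' @param thresholds see [characterize_thresholds()].
#' @return A `cluster_structure` with `estimated = TRUE`.
#' @export
estimate_structure_unlabelled <- function(m, k,
                                          thresholds = characterize_thresholds()) {
  stopifnot(inherits(m, "dataset_matrix"))
  if (k > nrow(m$values)) stop("k exceeds the number of samples")
  if (k < 1) stop("k must be >= 1")
  labels <- if (k == nrow(m$values)) seq_len(k)
            else stats::cutree(stats::hclust(stats::dist(m$values),
                                             method = "ward.D2"), k = k)
  characterize_clusters(m, labels = labels, thresholds = thresholds,
                        estimated = TRUE)
}

#' Derive the data-driven half of a requirement profile
#'
#' Maps measured characteristics to on/off marks for the seven data- and
#' cluster-side characteristics. The four algorithm-side characteristics
#' (hierarchical output, parameter burden, determinism, efficiency) reflect
#' the user's purpose, not the data, and are left to Stage 2.
#' Robustness to noise/outliers is marked only when outliers are present
#' *and* there is no single-point cluster: an algorithm that discards noise
#' would also discard a genuine singleton class, so the two needs are
#' mutually exclusive.
#'
#' @param dc a `dataset_characteristics`.
#' @param cs a `cluster_structure` from the same dataset.
#' @return Named logical vector over the seven data/cluster characteristics.
#' @export
derive_requirement_profile <- function(dc, cs) {
  stopifnot(inherits(dc, "dataset_characteristics"),
            inherits(cs, "cluster_structure"))
  c(small_datasets = dc$small_dataset,
    high_dimensions = dc$high_dimensional,
    non_spherical_shape = unname(cs$flags["non_spherical_shape"]),
    variable_cluster_density = unname(cs$flags["variable_cluster_density"]),
    single_point_cluster = unname(cs$flags["single_point_cluster"]),
    uneven_cluster_size = unname(cs$flags["uneven_cluster_size"]),
    robust_noise_outliers = unname(cs$flags["robust_noise_outliers"]) &&
      !cs$flags["single_point_cluster"])
}
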