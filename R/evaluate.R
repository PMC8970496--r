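## Stage 4: external validity (V-measure from contingency-table entropies)
## and internal indices (silhouette, Davies-Bouldin, Dunn), plus the
## algorithms-by-datasets evaluation grid with per-group totals.

#' Class-by-cluster contingency table
#'
#' Entry `(i, j)` counts the points with true class `i` and predicted
#' cluster `j`.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return An integer matrix with class values as row names and cluster
#'   values as column names.
#' @export
contingency <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  if (length(true_labels) == 0) stop("empty label vectors")
  unclass(table(true = true_labels, pred = pred_labels))
}

## entropy of a count vector, natural log; 0 for degenerate distributions
.entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

## conditional entropy H(rows | cols) from a contingency table
.cond_entropy <- function(tab) {
  n <- sum(tab)
  sum(vapply(seq_len(ncol(tab)), function(j) {
    cj <- tab[, j]
    sum(cj) / n * .entropy(cj)
  }, 0))
}

#' Homogeneity of a clustering
#'
#' `h = 1 - H(class | cluster) / H(class)`: 1 when every cluster contains
#' members of a single class, 0 when clustering carries no class
#' information. By convention `h = 1` when the class distribution is
#' degenerate (`H(class) = 0`). The entropy base cancels in the ratio.
#'
#' @inheritParams contingency
#' @return Homogeneity in `[0, 1]`.
#' @export
homogeneity <- function(true_labels, pred_labels) {
  tab <- contingency(true_labels, pred_labels)
  hk <- .entropy(rowSums(tab))
  if (hk == 0) return(1)
  1 - .cond_entropy(tab) / hk
}

#' Completeness of a clustering
#'
#' `c = 1 - H(cluster | class) / H(cluster)`: 1 when each class falls
#' wholly inside one cluster; by duality
#' `completeness(t, p) == homogeneity(p, t)`.
#'
#' @inheritParams contingency
#' @return Completeness in `[0, 1]`.
#' @export
completeness <- function(true_labels, pred_labels) {
  homogeneity(pred_labels, true_labels)
}

#' V-measure external cluster validity index
#'
#' Combines homogeneity `h` and completeness `c` as
#' `V_beta = (1 + beta) * h * c / (beta * h + c)` (0 when the denominator
#' is 0). With `beta = 1` this is the harmonic mean of `h` and `c`; the
#' score lies in `[0, 1]`, reaching 1.0 exactly when the prediction is a
#' bijective relabelling of the truth and 0.0 when the clustering carries
#' no class information (e.g. a single cluster over several classes).
#'
#' @inheritParams contingency
#' @param beta positive weight: `beta > 1` favours completeness,
#'   `beta < 1` homogeneity.
#' @return A list of class `v_measure` with `h`, `c`, `beta`, `v`.
#' @examples
#' v_measure(c(0, 0, 1, 1), c(0, 0, 1, 2))$v  # 0.8
#' @export
v_measure <- function(true_labels, pred_labels, beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  h <- homogeneity(true_labels, pred_labels)
  c <- completeness(true_labels, pred_labels)
  v <- if (beta * h + c > 0) (1 + beta) * h * c / (beta * h + c) else 0
  structure(list(h = h, c = c, beta = beta, v = v), class = "v_measure")
}

#' @export
print.v_measure <- function(x, ...) {
  cat(sprintf("V_%g = %.4f (homogeneity %.4f, completeness %.4f)\n",
              x$beta, x$v, x$h, x$c))
  invisible(x)
}

## per-cluster split of row indices, ignoring the noise sentinel
.cluster_index <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  lapply(stats::setNames(ids, ids), function(g) which(labels == g))
}

#' Mean silhouette index
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to another cluster; the
#' silhouette is `(b - a) / max(a, b)`, 0 by convention for singleton
#' clusters. Higher is better; range `[-1, 1]`.
#'
#' @param m a [dataset_matrix()] or numeric matrix.
#' @param labels integer cluster labels (`0` = noise, excluded).
#' @return Mean silhouette over the clustered points.
#' @export
silhouette_index <- function(m, labels) {
  x <- if (inherits(m, "dataset_matrix")) m$values else as.matrix(m)
  idx <- .cluster_index(labels)
  if (length(idx) < 2) stop("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(x))
  s <- numeric(0)
  for (g in seq_along(idx)) {
    own <- idx[[g]]
    for (i in own) {
      if (length(own) == 1) { s <- c(s, 0); next }
      a <- mean(d[i, setdiff(own, i)])
      b <- min(vapply(idx[-g], function(other) mean(d[i, other]), 0))
      s <- c(s, (b - a) / max(a, b))
    }
  }
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-pair ratio `(s_i + s_j) / d_ij`, where
#' `s` is the mean distance of members to their centroid and `d_ij` the
#' distance between centroids. Lower is better. Coincident centroids make
#' the ratio infinite; such pairs are flagged with an error.
#'
#' @inheritParams silhouette_index
#' @return Index value `>= 0`.
#' @export
davies_bouldin <- function(m, labels) {
  x <- if (inherits(m, "dataset_matrix")) m$values else as.matrix(m)
  idx <- .cluster_index(labels)
  k <- length(idx)
  if (k < 2) stop("Davies-Bouldin needs at least 2 clusters")
  cents <- vapply(idx, function(i) colMeans(x[i, , drop = FALSE]),
                  numeric(ncol(x)))
  centroids <- if (is.matrix(cents)) t(cents) else matrix(cents, ncol = 1)
  s <- vapply(seq_len(k), function(g)
    mean(sqrt(rowSums(sweep(x[idx[[g]], , drop = FALSE], 2,
                            centroids[g, ])^2))), 0)
  r <- numeric(k)
  for (g in seq_len(k)) {
    ratios <- vapply(setdiff(seq_len(k), g), function(h) {
      dij <- sqrt(sum((centroids[g, ] - centroids[h, ])^2))
      if (dij == 0) stop("coincident centroids for clusters ",
                         names(idx)[g], " and ", names(idx)[h])
      (s[g] + s[h]) / dij
    }, 0)
    r[g] <- max(ratios)
  }
  mean(r)
}

#' Dunn index
#'
#' Minimum between-cluster single-linkage distance divided by the maximum
#' within-cluster diameter. Higher is better; scale-invariant.
#'
#' @inheritParams silhouette_index
#' @return Index value `>= 0`.
#' @export
dunn_index <- function(m, labels) {
  x <- if (inherits(m, "dataset_matrix")) m$values else as.matrix(m)
  idx <- .cluster_index(labels)
  k <- length(idx)
  if (k < 2) stop("Dunn index needs at least 2 clusters")
  d <- as.matrix(stats::dist(x))
  diam <- max(vapply(idx, function(i)
    if (length(i) > 1) max(d[i, i]) else 0, 0))
  if (diam == 0) stop("all clusters are singletons: zero maximum diameter")
  sep <- min(vapply(seq_len(k - 1), function(g)
    min(vapply((g + 1):k, function(h) min(d[idx[[g]], idx[[h]]]), 0)), 0))
  sep / diam
}

## apply the configured noise convention to predicted labels before external
## scoring: noise as one extra cluster, or one singleton cluster per point
.apply_noise_convention <- function(pred, convention = c("own_cluster",
                                                         "singletons")) {
  convention <- match.arg(convention)
  noise <- pred == 0L
  if (!any(noise)) return(pred)
  mx <- max(pred)
  if (convention == "own_cluster") pred[noise] <- mx + 1L
  else pred[noise] <- mx + seq_len(sum(noise))
  pred
}

#' Evaluate a grid of algorithms over labelled datasets
#'
#' Runs each spec on each dataset, scores the result with the V-measure
#' against the true labels, and assembles the algorithms-by-datasets score
#' matrix with per-group total columns. Noise points are folded in under
#' the chosen convention before scoring (how noise entered external scores
#' is a genuine degree of freedom, so it is explicit and recorded).
#' Per-cell failures and anomalies degrade to annotations, never aborts:
#' `excess_noise` when more than 25% of points are noise, `could_not_reach_k`
#' when the found cluster count differs from the spec's target, `failed` on
#' error (score `NA`).
#'
#' @param specs list of [algorithm_spec()]s.
#' @param datasets list of labelled [dataset_matrix()]s (names become
#'   columns).
#' @param groups optional named list mapping group names to dataset names;
#'   each group contributes a total column.
#' @param noise_convention `"own_cluster"` (noise is one extra cluster) or
#'   `"singletons"` (each noise point its own cluster).
#' @param beta V-measure beta.
#' @return An object of class `evaluation_table`: `scores` (algorithms x
#'   datasets), `group_totals`, `annotations` (data frame), `noise_convention`.
#' @export
evaluate_grid <- function(specs, datasets, groups = NULL,
                          noise_convention = c("own_cluster", "singletons"),
                          beta = 1) {
  noise_convention <- match.arg(noise_convention)
  if (is.null(names(datasets)))
    names(datasets) <- vapply(datasets, `[[`, "", "name")
  alg <- vapply(specs, `[[`, "", "name")
  scores <- matrix(NA_real_, length(specs), length(datasets),
                   dimnames = list(alg, names(datasets)))
  ann <- data.frame(algorithm = character(), dataset = character(),
                    flag = character())
  note <- function(a, ds, flag)
    ann <<- rbind(ann, data.frame(algorithm = a, dataset = ds, flag = flag))
  for (j in seq_along(datasets)) {
    ds <- datasets[[j]]
    if (is.null(ds$labels)) stop("dataset '", names(datasets)[j],
                                 "' has no labels")
    for (i in seq_along(specs)) {
      res <- tryCatch(run_algorithm(specs[[i]], ds), error = identity)
      if (inherits(res, "error")) {
        note(alg[i], names(datasets)[j], "failed")
        next
      }
      noise_frac <- mean(res$labels == 0L)
      if (noise_frac > 0.25) note(alg[i], names(datasets)[j], "excess_noise")
      tk <- specs[[i]]$target_k
      if (!is.null(tk) && res$n_clusters_found != tk)
        note(alg[i], names(datasets)[j], "could_not_reach_k")
      pred <- .apply_noise_convention(res$labels, noise_convention)
      scores[i, j] <- v_measure(ds$labels, pred, beta = beta)$v
    }
  }
  group_totals <- NULL
  if (!is.null(groups)) {
    group_totals <- vapply(groups, function(cols)
      rowSums(scores[, cols, drop = FALSE]), numeric(length(specs)))
    if (is.null(dim(group_totals)))
      group_totals <- matrix(group_totals, nrow = length(specs),
                             dimnames = list(alg, names(groups)))
  }
  structure(list(scores = scores, group_totals = group_totals,
                 annotations = ann, noise_convention = noise_convention),
            class = "evaluation_table")
}

#' @export
print.evaluation_table <- function(x, digits = 2, ...) {
  cat("<evaluation_table> V-measure scores (noise convention:",
      x$noise_convention, ")\n")
  out <- round(x$scores, digits)
  if (!is.null(x$group_totals))
    out <- cbind(out, round(x$group_totals, digits))
  print(out)
  if (nrow(x$annotations)) {
    cat("annotations:\n")
    print(x$annotations, row.names = FALSE)
  }
  invisible(x)
}

#' Export an evaluation table as CSV
#'
#' Algorithms as rows, dataset columns followed by group-total columns;
#' annotations go to a JSON side-car when `annotations_path` is given.
#'
#' @param x an `evaluation_table`.
#' @param path CSV output path.
#' @param annotations_path optional JSON path for the annotations.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(x, path, annotations_path = NULL) {
  stopifnot(inherits(x, "evaluation_table"))
  out <- x$scores
  if (!is.null(x$group_totals)) out <- cbind(out, x$group_totals)
  utils::write.csv(data.frame(algorithm = rownames(out), out,
                              check.names = FALSE), path, row.names = FALSE)
  if (!is.null(annotations_path))
    jsonlite::write_json(x$annotations, annotations_path, dataframe = "rows")
  invisible(path)
}
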