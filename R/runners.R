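## Uniform execution contract over the 14 KB algorithms: a spec (name,
## hyperparameters, seed, target k) in, an integer label vector out, with 0
## as the noise sentinel. Internals of the algorithms live in algorithms.R;
## the contract here is only on the label vector.

#' Construct an algorithm run specification
#'
#' @param name a KB algorithm name (see [kb_names()]).
#' @param hyperparameters named list of hyperparameter overrides; anything
#'   not given falls back to data-driven defaults at run time.
#' @param seed integer seed; fixed for any non-deterministic algorithm so
#'   that identical spec + data imply identical labels.
#' @param target_k desired number of clusters; required by the
#'   k-parameterized algorithms.
#' @return An object of class `algorithm_spec`.
#' @examples
#' algorithm_spec("k-means", target_k = 3)
#' @export
algorithm_spec <- function(name, hyperparameters = list(), seed = 1L,
                           target_k = NULL) {
  if (!name %in% .runner_names())
    stop("unknown algorithm name: ", name, " (known: ",
         paste(.runner_names(), collapse = ", "), ")")
  structure(list(name = name, hyperparameters = hyperparameters,
                 seed = as.integer(seed), target_k = target_k),
            class = "algorithm_spec")
}

#' @export
print.algorithm_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = "=", collapse = ", ") else "defaults"
  cat("<algorithm_spec>", x$name, "| ", hp,
      if (!is.null(x$target_k)) paste("| k =", x$target_k),
      "| seed =", x$seed, "\n")
  invisible(x)
}

## hyperparameter with default: spec override wins
.hp <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

.need_k <- function(spec) {
  k <- spec$target_k
  if (is.null(k)) k <- spec$hyperparameters[["k"]]
  if (is.null(k)) stop(spec$name, " requires target_k")
  as.integer(k)
}

## data-driven default scale: mean distance to the 5th nearest neighbour
.nn5_scale <- function(x) {
  n <- nrow(x)
  sub <- x[seq(1, n, length.out = min(n, 300)), , drop = FALSE]
  d <- as.matrix(stats::dist(sub))
  mean(apply(d, 1, function(r) sort(r)[min(6, length(r))]))
}

.runner_registry <- function() list(
  "Hierarchical (Ward's)" = function(x, spec)
    stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"),
                  k = .need_k(spec)),
  "Hierarchical (Single Link)" = function(x, spec)
    stats::cutree(stats::hclust(stats::dist(x), method = "single"),
                  k = .need_k(spec)),
  "BIRCH" = function(x, spec)
    .run_birch(x, k = .need_k(spec),
               threshold = .hp(spec, "threshold", NULL),
               branching_factor = .hp(spec, "branching_factor", 50)),
  "k-means" = function(x, spec) {
    set.seed(spec$seed)
    as.integer(stats::kmeans(x, .need_k(spec), nstart = 10,
                             iter.max = 100)$cluster)
  },
  "k-means minibatch" = function(x, spec)
    .run_minibatch_kmeans(x, k = .need_k(spec), seed = spec$seed,
                          batch_size = .hp(spec, "batch_size", 100)),
  "PAM" = function(x, spec) {
    set.seed(spec$seed)
    as.integer(cluster::pam(x, k = .need_k(spec), cluster.only = TRUE,
                            pamonce = 5))
  },
  "Fuzzy C-Means" = function(x, spec)
    .run_fcm(x, k = .need_k(spec), seed = spec$seed,
             fuzzifier = .hp(spec, "fuzzifier", 2)),
  "DBSCAN" = function(x, spec)
    .run_dbscan(x, eps = .hp(spec, "eps", 2 * .nn5_scale(x)),
                min_samples = .hp(spec, "min_samples", 5)),
  "HDBSCAN" = function(x, spec)
    .run_hdbscan(x, min_cluster_size = .hp(spec, "min_cluster_size", 5),
                 min_samples = .hp(spec, "min_samples", 5)),
  "OPTICS" = function(x, spec)
    .run_optics(x, eps_cl = .hp(spec, "eps_cl", 2 * .nn5_scale(x)),
                min_samples = .hp(spec, "min_samples", 5)),
  "Mean Shift" = function(x, spec)
    .run_meanshift(x, bandwidth = .hp(spec, "bandwidth",
                                      stats::quantile(stats::dist(x), 0.3))),
  "Spectral Clustering" = function(x, spec)
    .run_spectral(x, k = .need_k(spec), seed = spec$seed,
                  n_neighbors = .hp(spec, "n_neighbors", 10)),
  "Affinity Propagation" = function(x, spec)
    .run_affprop(x, seed = spec$seed,
                 damping = .hp(spec, "damping", 0.9),
                 preference = .hp(spec, "preference", NULL)),
  "Gaussian Mixture Model" = function(x, spec)
    .run_gmm(x, k = .need_k(spec), seed = spec$seed,
             n_init = .hp(spec, "n_init", 1),
             max_iter = .hp(spec, "max_iter", 100),
             tol = .hp(spec, "tol", 1e-3))
)

.runner_names <- function() names(.runner_registry())

#' Execute a clustering algorithm under the runner contract
#'
#' Runs the named algorithm on a preprocessed dataset and returns a hard
#' labelling (fuzzy/probabilistic algorithms are reduced by maximum
#' membership). Density-based algorithms may mark points as noise with the
#' reserved sentinel `0`; the sentinel is preserved and its handling is the
#' evaluation module's decision. Identical spec + data + seed give identical
#' labels.
#'
#' @param spec an [algorithm_spec()].
#' @param m a [dataset_matrix()] or numeric matrix.
#' @return A list of class `run_result`: `labels` (integer, `0` = noise),
#'   `n_clusters_found` (distinct non-noise labels), `spec`.
#' @export
run_algorithm <- function(spec, m) {
  stopifnot(inherits(spec, "algorithm_spec"))
  x <- if (inherits(m, "dataset_matrix")) m$values else as.matrix(m)
  fn <- .runner_registry()[[spec$name]]
  labels <- tryCatch(as.integer(fn(x, spec)),
                     error = function(e)
                       stop("algorithm '", spec$name, "' failed: ",
                            conditionMessage(e), call. = FALSE))
  stopifnot(length(labels) == nrow(x))
  structure(list(labels = labels,
                 n_clusters_found = length(unique(labels[labels > 0L])),
                 spec = spec),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", x$spec$name, "->", x$n_clusters_found, "clusters")
  if (any(x$labels == 0L)) cat(",", sum(x$labels == 0L), "noise points")
  cat("\n")
  invisible(x)
}

#' Tune a hyperparameter to reach a target cluster count
#'
#' Finds a value of one numeric hyperparameter (neighbourhood radius,
#' minimum cluster size, bandwidth, ...) at which the algorithm yields
#' exactly `k` non-noise clusters, by bisection under the assumption that
#' the count responds monotonically over `bounds`; when bisection fails to
#' hit `k` the bounds are swept with a grid (up to 60 runs in total) and
#' the closest achievable count wins, flagged as inexact. The returned spec
#' never yields a count farther from `k` than the initial spec did.
#'
#' @param spec an [algorithm_spec()] providing all other hyperparameters.
#' @param m the dataset.
#' @param k target number of clusters, at most `n_samples`.
#' @param tunable name of the hyperparameter to tune.
#' @param bounds length-2 numeric interval to search.
#' @param integer_valued round candidate values to integers (e.g. for
#'   minimum cluster sizes).
#' @param max_evals total run budget (default 60).
#' @return An `algorithm_spec` with the tuned value set and attributes
#'   `achieved_k` and `inexact`.
#' @export
tune_to_k <- function(spec, m, k, tunable, bounds, integer_valued = FALSE,
                      max_evals = 60) {
  stopifnot(inherits(spec, "algorithm_spec"), length(bounds) == 2)
  x <- if (inherits(m, "dataset_matrix")) m$values else as.matrix(m)
  if (k > nrow(x)) stop("k = ", k, " exceeds the number of samples")
  evals <- 0
  count_at <- function(v) {
    if (integer_valued) v <- round(v)
    s <- spec
    s$hyperparameters[[tunable]] <- v
    evals <<- evals + 1
    run_algorithm(s, x)$n_clusters_found
  }
  finish <- function(v, count) {
    if (integer_valued) v <- round(v)
    out <- spec
    out$hyperparameters[[tunable]] <- v
    out$target_k <- k
    attr(out, "achieved_k") <- count
    attr(out, "inexact") <- count != k
    out
  }
  ## initial value, if any, anchors the never-worse guarantee
  init_v <- spec$hyperparameters[[tunable]]
  init_count <- if (!is.null(init_v)) count_at(init_v) else NA_integer_
  if (!is.na(init_count) && init_count == k) return(finish(init_v, init_count))

  lo <- min(bounds); hi <- max(bounds)
  c_lo <- count_at(lo); c_hi <- count_at(hi)
  best_v <- lo; best_c <- c_lo
  note <- function(v, cnt) {
    if (abs(cnt - k) < abs(best_c - k)) { best_v <<- v; best_c <<- cnt }
  }
  note(hi, c_hi)
  if (c_lo == k) return(finish(lo, c_lo))
  if (c_hi == k) return(finish(hi, c_hi))

  if (c_lo != c_hi && min(c_lo, c_hi) <= k && k <= max(c_lo, c_hi)) {
    ## bisection on the (assumed monotone) step response
    increasing <- c_hi > c_lo
    a <- lo; b <- hi
    while (evals < max_evals * 2 / 3 && (if (integer_valued)
      round(b) - round(a) > 1 else (b - a) > 1e-9 * (abs(hi) + 1))) {
      mid <- (a + b) / 2
      cm <- count_at(mid)
      note(mid, cm)
      if (cm == k) return(finish(mid, cm))
      if ((cm < k) == increasing) a <- mid else b <- mid
    }
  }
  ## fall back to a grid sweep over the remaining budget
  grid <- seq(lo, hi, length.out = max(2, max_evals - evals))
  if (integer_valued) grid <- unique(round(grid))
  for (v in grid) {
    cnt <- count_at(v)
    note(v, cnt)
    if (cnt == k) return(finish(v, cnt))
  }
  ## closest achievable; never worse than the initial spec
  if (!is.na(init_count) && abs(init_count - k) < abs(best_c - k))
    return(finish(init_v, init_count))
  finish(best_v, best_c)
}
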