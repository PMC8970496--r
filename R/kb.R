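## Knowledge base of candidate clustering algorithms: per-algorithm support
## for the evaluation characteristics, parameter burden, determinism and a
## symbolic time-complexity class. The default KB ships as
## inst/extdata/table3.json and covers 14 algorithms across five families.

#' Evaluation characteristic identifiers
#'
#' The closed set of 11 characteristics used throughout the workflow: two
#' dataset characteristics (`small_datasets`, `high_dimensions`), five
#' cluster-structure characteristics (`non_spherical_shape`,
#' `variable_cluster_density`, `single_point_cluster`, `uneven_cluster_size`,
#' `robust_noise_outliers`), and four algorithm-side characteristics
#' (`multimodal_hierarchical`, `parameter_simplicity`, `deterministic`,
#' `efficiency`). All but `parameter_simplicity` and `efficiency` are
#' yes/no/unknown support columns; those two are handled as hard constraints
#' (see [filter_constraints()]).
#'
#' @param boolean_only if `TRUE`, return only the nine yes/no/unknown
#'   characteristics that can be queried as soft requirements.
#' @return Character vector of characteristic ids.
#' @export
characteristic_ids <- function(boolean_only = FALSE) {
  ids <- c("small_datasets", "high_dimensions", "non_spherical_shape",
           "variable_cluster_density", "single_point_cluster",
           "uneven_cluster_size", "robust_noise_outliers",
           "multimodal_hierarchical", "parameter_simplicity",
           "deterministic", "efficiency")
  if (boolean_only) setdiff(ids, c("parameter_simplicity", "efficiency")) else ids
}

## the 8 support-map characteristics (deterministic is stored separately)
.support_ids <- function() setdiff(characteristic_ids(boolean_only = TRUE),
                                   "deterministic")

.assert_characteristic <- function(c) {
  if (!(is.character(c) && length(c) == 1L && c %in% characteristic_ids()))
    stop("unknown characteristic id: ", paste(c, collapse = ", "))
  invisible(c)
}

#' Rank a symbolic time-complexity expression
#'
#' Complexity entries are symbolic products over `n` (objects), `k`
#' (clusters), `d` (dimensions), `i` (iterations) and `log n`, written like
#' `"n^2 log n"`, `"n k d i"`, `"n^3"`. They are compared under a total
#' "growth order in n" ranking in which `k`, `d`, `i` are treated as
#' data-independent factors: the exponent of `n` dominates, then a `log n`
#' factor outranks a single auxiliary symbol but is outranked by several,
#' giving `n < n log n < n k d i < n^2 < n^2 i < n^2 log n < n^3`.
#'
#' @param expression complexity string.
#' @return A numeric rank; larger means slower growth. Errors on symbols
#'   outside `n`, `k`, `d`, `i`, `log`.
#' @examples
#' complexity_rank("n log n") < complexity_rank("n k d i")
#' complexity_rank("n^2 i") > complexity_rank("n^2")
#' @export
complexity_rank <- function(expression) {
  s <- tolower(gsub("[*·]", " ", expression))
  s <- gsub("\\s+", " ", trimws(s))
  if (s == "") stop("empty complexity expression")
  ## tokens like "n", "n^2", "log", "k^2"
  toks <- strsplit(s, " ")[[1]]
  n_exp <- 0; aux <- 0; has_log <- FALSE
  i <- 1
  while (i <= length(toks)) {
    t <- toks[i]
    if (t == "log") {
      ## consumes following "n"
      if (i == length(toks) || toks[i + 1] != "n")
        stop("malformed log factor in complexity: ", expression)
      has_log <- TRUE
      i <- i + 2
      next
    }
    mm <- regmatches(t, regexec("^([nkdi])(\\^([0-9]+))?$", t))[[1]]
    if (length(mm) == 0) stop("unknown symbol in complexity '", expression,
                              "': ", t)
    sym <- mm[2]
    e <- if (mm[4] == "") 1L else as.integer(mm[4])
    if (sym == "n") n_exp <- n_exp + e else aux <- aux + e
    i <- i + 1
  }
  if (has_log) aux <- aux + 1.5
  n_exp * 10 + min(aux, 9)
}

.parse_support <- function(x) {
  ## accepts "yes"/"no"/"unknown" or list(level=, caveat=); NULL -> unknown
  if (is.null(x)) return(list(level = "unknown", caveat = NULL))
  if (is.character(x)) x <- list(level = x)
  lv <- tolower(x$level)
  if (lv %in% c("y", "yes")) lv <- "yes"
  else if (lv %in% c("n", "no")) lv <- "no"
  else if (lv %in% c("", "unknown", "na")) lv <- "unknown"
  else stop("support level must be yes/no/unknown, got: ", x$level)
  list(level = lv, caveat = x$caveat)
}

#' Construct an algorithm profile
#'
#' One row of the comparative matrix: an algorithm's support for each
#' yes/no characteristic, its required parameters, determinism, and
#' time-complexity class. Missing support cells default to `"unknown"`,
#' which is deliberately distinct from `"no"`: a knowledge gap is surfaced,
#' never scored as a violation.
#'
#' @param name algorithm name (unique within a KB).
#' @param family one of `"hierarchical"`, `"partition"`, `"density"`,
#'   `"graph/spectral"`, `"model-based"`.
#' @param support named list over the eight support characteristics; each
#'   entry `"yes"`/`"no"`/`"unknown"` or `list(level=, caveat=)`.
#' @param parameters character vector of required parameter names.
#' @param deterministic support level for deterministic behaviour.
#' @param complexity complexity string (see [complexity_rank()]), or
#'   `list(level=, caveat=)` to attach a qualifier.
#' @return An object of class `algorithm_profile`.
#' @export
algorithm_profile <- function(name, family, support = list(),
                              parameters = character(),
                              deterministic = "unknown",
                              complexity = "n^2") {
  complexity_caveat <- NULL
  if (is.list(complexity)) {
    complexity_caveat <- complexity$caveat
    complexity <- complexity$level
  }
  family <- match.arg(family, c("hierarchical", "partition", "density",
                                "graph/spectral", "model-based"))
  bad <- setdiff(names(support), .support_ids())
  if (length(bad)) stop("unknown characteristic key in support: ",
                        paste(bad, collapse = ", "))
  sup <- lapply(.support_ids(), function(id) .parse_support(support[[id]]))
  names(sup) <- .support_ids()
  complexity_rank(complexity)  # validate eagerly
  parameters <- as.character(parameters)
  structure(list(name = name, family = family, support = sup,
                 parameters = parameters,
                 k_only = identical(sort(parameters), "k"),
                 deterministic = .parse_support(deterministic),
                 complexity = complexity,
                 complexity_caveat = complexity_caveat),
            class = "algorithm_profile")
}

#' Load an algorithm knowledge base
#'
#' Reads a JSON KB file: an array of objects with keys `name`, `family`,
#' `support` (characteristic to `"yes"`/`"no"`/`"unknown"`, caveats allowed
#' as `{"level": ..., "caveat": ...}`), `parameters` (list of names),
#' `deterministic`, and `complexity` (string such as `"n^2 log n"`).
#' Missing support cells become `"unknown"`. With no `path`, loads the
#' built-in default KB of 14 algorithms.
#'
#' @param path KB file path, or `NULL` for the packaged default.
#' @return An object of class `algorithm_kb`: an ordered list of
#'   [algorithm_profile()]s. Row order is preserved and used for
#'   deterministic tie-breaking downstream.
#' @examples
#' kb <- load_kb()
#' length(kb$profiles)  # 14
#' @export
load_kb <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table3.json", package = "clustselect",
                        mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  profiles <- lapply(raw, function(row) {
    if (is.null(row$name)) stop("KB row without a name")
    algorithm_profile(name = row$name, family = row$family,
                      support = if (is.null(row$support)) list() else row$support,
                      parameters = unlist(row$parameters),
                      deterministic = if (is.null(row$deterministic)) "unknown"
                                      else row$deterministic,
                      complexity = row$complexity)
  })
  nm <- vapply(profiles, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate algorithm name in KB: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(list(profiles = profiles), class = "algorithm_kb")
}

#' @export
print.algorithm_kb <- function(x, ...) {
  cat("<algorithm_kb> with", length(x$profiles), "profiles:\n")
  for (p in x$profiles)
    cat(sprintf("  %-28s %-14s params={%s} O(%s)\n", p$name, p$family,
                paste(p$parameters, collapse = ","), p$complexity))
  invisible(x)
}

#' Algorithm names in KB order
#' @param kb an `algorithm_kb`.
#' @return Character vector of names.
#' @export
kb_names <- function(kb) vapply(kb$profiles, `[[`, "", "name")

.kb_profile <- function(kb, name) {
  i <- match(name, kb_names(kb))
  if (is.na(i)) stop("unknown algorithm name: ", name)
  kb$profiles[[i]]
}

.profile_support <- function(p, c) {
  if (c == "deterministic") p$deterministic else p$support[[c]]
}

#' Serialize a knowledge base to JSON
#'
#' Inverse of [load_kb()]: `load_kb(write_kb(kb, path))` reparses to an
#' equal KB.
#'
#' @param kb an `algorithm_kb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  enc_sup <- function(s)
    if (is.null(s$caveat)) s$level else list(level = s$level, caveat = s$caveat)
  rows <- lapply(kb$profiles, function(p) {
    list(name = p$name, family = p$family,
         support = lapply(p$support, enc_sup),
         parameters = as.list(p$parameters),
         deterministic = enc_sup(p$deterministic),
         complexity = if (is.null(p$complexity_caveat)) p$complexity
                      else list(level = p$complexity, caveat = p$complexity_caveat))
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Algorithms supporting a characteristic
#'
#' Returns exactly the algorithms whose support level for a yes/no
#' characteristic is `"yes"`. Unknown cells are excluded (they are neither
#' support nor violation); use [kb_support_matrix()] to see them.
#'
#' @param kb an `algorithm_kb`.
#' @param c a yes/no characteristic id (not `parameter_simplicity` or
#'   `efficiency`, which are constraints, not support columns).
#' @return Character vector of algorithm names, in KB order.
#' @examples
#' query_support(load_kb(), "high_dimensions")
#' @export
query_support <- function(kb, c) {
  .assert_characteristic(c)
  if (c %in% c("parameter_simplicity", "efficiency"))
    stop("'", c, "' is not a yes/no support characteristic; ",
         "use filter_constraints(k_only=, max_complexity=)")
  nm <- kb_names(kb)
  lv <- vapply(kb$profiles, function(p) .profile_support(p, c)$level, "")
  nm[lv == "yes"]
}

#' Filter algorithms by hard constraints
#'
#' Intersection of algorithms satisfying each given constraint: requiring
#' only the cluster count `k` as a parameter, and/or a maximum
#' time-complexity class under the [complexity_rank()] ordering.
#'
#' @param kb an `algorithm_kb`.
#' @param k_only if `TRUE`, keep algorithms whose parameter set is exactly
#'   `{k}`; if `FALSE`, keep the complement.
#' @param max_complexity complexity string; keep algorithms whose class ranks
#'   at or below it.
#' @return Character vector of algorithm names, in KB order.
#' @examples
#' filter_constraints(load_kb(), k_only = TRUE)
#' filter_constraints(load_kb(), max_complexity = "n^2")
#' @export
filter_constraints <- function(kb, k_only = NULL, max_complexity = NULL) {
  if (is.null(k_only) && is.null(max_complexity))
    stop("at least one constraint must be given")
  keep <- rep(TRUE, length(kb$profiles))
  if (!is.null(k_only))
    keep <- keep & (vapply(kb$profiles, `[[`, TRUE, "k_only") == k_only)
  if (!is.null(max_complexity)) {
    lim <- complexity_rank(max_complexity)
    keep <- keep & vapply(kb$profiles,
                          function(p) complexity_rank(p$complexity) <= lim, TRUE)
  }
  kb_names(kb)[keep]
}

#' Render the KB as a support matrix
#'
#' Algorithms as rows, the nine yes/no characteristics as columns, cells
#' `"yes"`/`"no"`/`"unknown"`, plus `parameters` and `complexity` columns —
#' the comparative-matrix view used for qualitative down-selection.
#'
#' @param kb an `algorithm_kb`.
#' @return A character matrix with row names the algorithm names.
#' @export
kb_support_matrix <- function(kb) {
  ids <- characteristic_ids(boolean_only = TRUE)
  mat <- t(vapply(kb$profiles, function(p)
    vapply(ids, function(c) .profile_support(p, c)$level, ""), character(length(ids))))
  rownames(mat) <- kb_names(kb)
  cbind(mat,
        parameters = vapply(kb$profiles,
                            function(p) paste(p$parameters, collapse = ","), ""),
        complexity = vapply(kb$profiles, `[[`, "", "complexity"))
}
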