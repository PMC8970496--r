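## End-to-end orchestration: preprocess -> characterize -> match/down-select
## -> evaluate the selected subset -> recommend.

#' Run the full selection workflow on one dataset
#'
#' Executes the four stages in order: preprocessing (EMSC for spectra,
#' standardization for multivariate data), characterization of the dataset
#' and its cluster structure, qualitative matching and down-selection
#' against the knowledge base, and quantitative V-measure evaluation of the
#' selected subset only (never of an algorithm that failed the hard
#' constraints). The recommendation is the selected algorithm with the
#' highest V-measure; ties are all reported.
#'
#' @param data a labelled [dataset_matrix()].
#' @param requirements a [requirement_set()], a preset name from
#'   [scenario_presets()], or `"auto"` to derive the data/cluster
#'   requirements from the measured characteristics.
#' @param k number of clusters for k-parameterized algorithms; defaults to
#'   the number of labelled classes.
#' @param preprocess_method see [preprocess()].
#' @param kb knowledge base; defaults to the built-in one.
#' @param thresholds see [characterize_thresholds()].
#' @param seed integer seed used for every stochastic algorithm.
#' @param noise_convention see [evaluate_grid()].
#' @param out_dir optional directory; when given, writes
#'   `characterization.json`, `selection.csv`, `evaluation.csv`,
#'   `annotations.json`, `manifest.json` and `summary.md` into it.
#' @return An object of class `clustsel_pipeline` with elements
#'   `characteristics`, `structure`, `requirements`, `selection`,
#'   `evaluation`, `recommended`, `seed`.
#' @export
run_pipeline <- function(data, requirements, k = NULL,
                         preprocess_method = "auto", kb = load_kb(),
                         thresholds = characterize_thresholds(),
                         seed = 1L,
                         noise_convention = "own_cluster",
                         out_dir = NULL) {
  stopifnot(inherits(data, "dataset_matrix"))
  if (is.null(data$labels))
    stop("stage 'evaluate': the pipeline needs labelled data for external scoring")
  pp <- .stage("preprocess", preprocess(data, method = preprocess_method))
  dc <- .stage("characterize", characterize_dataset(pp, thresholds))
  cs <- .stage("characterize", characterize_clusters(pp, thresholds = thresholds))
  if (is.null(k)) k <- cs$n_clusters

  if (is.character(requirements) && length(requirements) == 1) {
    requirements <- if (requirements == "auto") {
      marks <- derive_requirement_profile(dc, cs)
      requirement_set(required = names(marks)[marks])
    } else scenario_presets(requirements)
  }
  stopifnot(inherits(requirements, "requirement_set"))

  sel <- .stage("select", select_algorithms(kb, requirements))
  if (length(sel$selected) == 0)
    stop("stage 'select': no algorithm satisfied the requirements")
  specs <- lapply(sel$selected, function(nm)
    algorithm_spec(nm, seed = seed, target_k = k))
  ev <- .stage("evaluate",
               evaluate_grid(specs, stats::setNames(list(pp), data$name),
                             noise_convention = noise_convention))
  v <- ev$scores[, 1]
  best <- max(v, na.rm = TRUE)
  recommended <- rownames(ev$scores)[!is.na(v) & v >= best - 1e-12]
  out <- structure(list(characteristics = dc, structure = cs,
                        requirements = requirements, selection = sel,
                        evaluation = ev, recommended = recommended,
                        k = k, seed = seed, dataset = data$name),
                   class = "clustsel_pipeline")
  if (!is.null(out_dir)) .write_pipeline_reports(out, out_dir, thresholds)
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' @export
print.clustsel_pipeline <- function(x, ...) {
  cat("<clustsel_pipeline>", x$dataset, "| k =", x$k, "| seed =", x$seed, "\n")
  cat("selected:", paste(x$selection$selected, collapse = ", "), "\n")
  cat("recommended:", paste(x$recommended, collapse = ", "),
      sprintf("(V = %.3f)\n", max(x$evaluation$scores[, 1], na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.clustsel_pipeline <- function(object, ...) {
  print(object$characteristics)
  print(object$structure)
  print(object$selection)
  print(object$evaluation)
  cat("recommended:", paste(object$recommended, collapse = ", "), "\n")
  invisible(object)
}

.write_pipeline_reports <- function(x, out_dir, thresholds) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(dataset = x$dataset,
         characteristics = unclass(x$characteristics),
         structure = unclass(x$structure)[c(
           "n_clusters", "balance_ratio", "has_single_point_cluster",
           "density_variation_ratio", "max_elongation", "outlier_fraction")],
         flags = as.list(x$structure$flags)),
    file.path(out_dir, "characterization.json"), auto_unbox = TRUE,
    digits = NA)
  selection_table(x$selection, file.path(out_dir, "selection.csv"))
  write_evaluation_csv(x$evaluation, file.path(out_dir, "evaluation.csv"),
                       file.path(out_dir, "annotations.json"))
  jsonlite::write_json(
    list(seed = x$seed, k = x$k, thresholds = thresholds,
         noise_convention = x$evaluation$noise_convention,
         selected = x$selection$selected, recommended = x$recommended),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  md <- c(sprintf("# Selection report: %s", x$dataset), "",
          sprintf("- clusters evaluated at k = %d (seed %d)", x$k, x$seed),
          sprintf("- selected: %s", paste(x$selection$selected, collapse = ", ")),
          sprintf("- recommended: %s (V = %.3f)",
                  paste(x$recommended, collapse = ", "),
                  max(x$evaluation$scores[, 1], na.rm = TRUE)))
  writeLines(md, file.path(out_dir, "summary.md"))
  invisible(out_dir)
}
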