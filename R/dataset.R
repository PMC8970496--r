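#' Construct a dataset matrix
#'
#' The universal input container for the selection workflow: a numeric
#' sample-by-feature matrix with optional integer class labels and an optional
#' feature coordinate axis (wavenumbers in cm^-1 for spectra). Label value
#' `0` is reserved for noise/outlier points throughout the package.
#'
#' @param values numeric matrix, samples as rows.
#' @param labels optional integer vector of class labels, one per sample.
#'   `0` marks noise/outliers; positive integers are class ids.
#' @param axis optional numeric vector of feature coordinates (e.g. a
#'   wavenumber grid), length `ncol(values)`. Its presence routes the dataset
#'   to spectral preprocessing (EMSC) rather than standardization.
#' @param name character label used in reports.
#' @return An object of class `dataset_matrix`: a list with elements
#'   `values`, `labels`, `axis`, `name`.
#' @examples
#' m <- dataset_matrix(matrix(rnorm(20), 5, 4), labels = c(1, 1, 2, 2, 2))
#' dim(m$values)
#' @export
dataset_matrix <- function(values, labels = NULL, axis = NULL, name = "dataset") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("dataset contains missing values")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values))
      stop("labels length (", length(labels), ") != number of samples (",
           nrow(values), ")")
    if (anyNA(labels)) stop("labels contain NA")
    if (any(labels < 0L)) stop("labels must be >= 0 (0 is the noise sentinel)")
    if (!any(labels > 0L)) stop("labels must cover at least one class")
  }
  if (!is.null(axis)) {
    axis <- as.numeric(axis)
    if (length(axis) != ncol(values))
      stop("axis length (", length(axis), ") != number of features (",
           ncol(values), ")")
  }
  structure(list(values = values, labels = labels, axis = axis,
                 name = as.character(name)[1]),
            class = "dataset_matrix")
}

#' @export
print.dataset_matrix <- function(x, ...) {
  cat("<dataset_matrix> ", x$name, ": ", nrow(x$values), " samples x ",
      ncol(x$values), " features", sep = "")
  if (!is.null(x$labels)) {
    k <- length(unique(x$labels[x$labels > 0L]))
    cat(", ", k, " class", if (k != 1) "es", sep = "")
    if (any(x$labels == 0L))
      cat(" (+", sum(x$labels == 0L), " noise/outlier points)", sep = "")
  }
  if (!is.null(x$axis))
    cat(", axis ", format(min(x$axis)), "..", format(max(x$axis)), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.dataset_matrix <- function(x) dim(x$values)

#' Read a dataset matrix from CSV
#'
#' Reads a samples-as-rows CSV. A column named `label` (or the name given in
#' `label_column`) is split off as class labels; if `axis_header = TRUE` the
#' column names of the remaining feature columns are parsed as a numeric
#' wavenumber axis.
#'
#' @param path CSV file path.
#' @param label_column name of the label column, if any.
#' @param axis_header parse feature column names as a numeric axis.
#' @param name dataset name; defaults to the file name.
#' @return A [dataset_matrix()].
#' @export
read_dataset_csv <- function(path, label_column = "label",
                             axis_header = FALSE, name = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- NULL
  if (label_column %in% names(df)) {
    labels <- df[[label_column]]
    df[[label_column]] <- NULL
  }
  values <- as.matrix(df)
  axis <- NULL
  if (axis_header) {
    axis <- suppressWarnings(as.numeric(colnames(values)))
    if (anyNA(axis))
      stop("axis_header = TRUE but feature column names are not all numeric")
  }
  if (is.null(name)) name <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  dataset_matrix(values, labels = labels, axis = axis, name = name)
}

#' Write a dataset matrix to CSV
#'
#' Inverse of [read_dataset_csv()]: features as columns (named by the axis
#' when present), plus a `label` column when labels are attached.
#'
#' @param m a [dataset_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(m, path) {
  stopifnot(inherits(m, "dataset_matrix"))
  values <- m$values
  if (!is.null(m$axis)) colnames(values) <- as.character(m$axis)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  df <- as.data.frame(values, check.names = FALSE)
  if (!is.null(m$labels)) df$label <- m$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Classic benchmark datasets
#'
#' `classic_dataset("iris")` returns Fisher's Iris data (150 x 4, 3 classes)
#' from the `datasets` package; `classic_dataset("wine")` returns the UCI Wine
#' recognition data (178 x 13, 3 classes) shipped with this package as a
#' plain-text fixture. Both are returned unscaled; apply [standardize()] where
#' the features have heterogeneous units (Wine), and leave data on a shared
#' physical unit (Iris, all cm) raw.
#'
#' @param name `"iris"` or `"wine"`.
#' @return A labelled [dataset_matrix()].
#' @export
classic_dataset <- function(name = c("iris", "wine")) {
  name <- match.arg(name)
  if (name == "iris") {
    dataset_matrix(as.matrix(datasets::iris[, 1:4]),
                   labels = as.integer(datasets::iris$Species),
                   name = "iris")
  } else {
    path <- system.file("extdata", "wine.csv", package = "clustselect",
                        mustWork = TRUE)
    read_dataset_csv(path, name = "wine")
  }
}
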