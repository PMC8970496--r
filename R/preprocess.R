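## Spectral preprocessing: extended multiplicative signal correction (EMSC)
## for data with a wavenumber axis, plain centring/scaling for multivariate
## data.

#' Extended multiplicative signal correction
#'
#' Fits each spectrum `x` by ordinary least squares as
#' `x ~ a * 1 + b * m + sum_j d_j * p_j(lambda) + sum_k g_k * q_k`
#' where `m` is a reference spectrum (default: the dataset mean), `p_j` are
#' polynomials in the wavenumber axis rescaled to `[-1, 1]` (numerical
#' conditioning), and `q_k` are optional interferent spectra. The corrected
#' spectrum removes the additive, polynomial-baseline and interferent
#' contributions and divides out the multiplicative scatter factor `b`:
#' `(x - a - sum d_j p_j - sum g_k q_k) / b`.
#'
#' A spectrum with `|b|` below `b_tol` cannot be corrected (the division is
#' degenerate); it is returned uncorrected and flagged.
#'
#' @param spectra a [dataset_matrix()] with a wavenumber `axis`, or a plain
#'   matrix (rows are spectra) in which case an index axis is assumed.
#' @param reference reference spectrum; defaults to the column mean.
#' @param polynomial_order baseline polynomial order, 0-6 (default 2:
#'   offset absorbed by the constant column, slope, curvature).
#' @param interferents optional matrix of interferent spectra, one per row.
#' @param b_tol tolerance below which the multiplicative coefficient is
#'   treated as degenerate.
#' @return A [dataset_matrix()] of corrected spectra with attributes
#'   `emsc_coefficients` (one row per spectrum: `a`, `b`, `d1..`, `g1..`)
#'   and `emsc_degenerate` (logical per spectrum).
#' @examples
#' wn <- seq(600, 1800, length.out = 200)
#' ref <- exp(-((wn - 1200) / 60)^2)
#' x <- rbind(2 * ref + 3, ref)
#' out <- emsc_fit_correct(dataset_matrix(x, axis = wn), reference = ref)
#' max(abs(out$values[1, ] - ref)) < 1e-10
#' @export
emsc_fit_correct <- function(spectra, reference = NULL, polynomial_order = 2,
                             interferents = NULL, b_tol = 1e-8) {
  m <- if (inherits(spectra, "dataset_matrix")) spectra
       else dataset_matrix(spectra, axis = seq_len(ncol(as.matrix(spectra))))
  x <- m$values
  p <- ncol(x)
  if (p < 2) stop("need at least 2 wavelength points")
  axis <- if (!is.null(m$axis)) m$axis else seq_len(p)
  if (is.null(reference)) reference <- colMeans(x)
  if (length(reference) != p) stop("reference length != number of features")
  if (polynomial_order < 0 || polynomial_order > 6)
    stop("polynomial_order must be in 0..6")

  lam <- if (diff(range(axis)) > 0)
    2 * (axis - min(axis)) / diff(range(axis)) - 1 else rep(0, p)
  ## design: intercept, reference, lambda^1..order, interferents
  design <- cbind(1, reference)
  if (polynomial_order >= 1)
    design <- cbind(design, outer(lam, seq_len(polynomial_order), `^`))
  if (!is.null(interferents)) {
    interferents <- as.matrix(interferents)
    if (ncol(interferents) != p) stop("interferent length != number of features")
    design <- cbind(design, t(interferents))
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("rank-deficient EMSC design matrix (collinear reference/baseline/interferents)")

  coefs <- t(qr.coef(qrd, t(x)))  # n x ncol(design)
  n_int <- if (is.null(interferents)) 0 else nrow(interferents)
  colnames(coefs) <- c("a", "b",
                       if (polynomial_order >= 1) paste0("d", seq_len(polynomial_order)),
                       if (n_int > 0) paste0("g", seq_len(n_int)))
  b <- coefs[, "b"]
  degenerate <- abs(b) < b_tol
  ## remove everything except the reference contribution, divide by b
  removed <- coefs[, -2, drop = FALSE] %*% t(design[, -2, drop = FALSE])
  corrected <- (x - removed) / ifelse(degenerate, 1, b)
  corrected[degenerate, ] <- x[degenerate, ]
  if (any(degenerate))
    warning(sum(degenerate), " spectra had |b| < ", b_tol,
            " and were left uncorrected (flagged)")
  out <- dataset_matrix(corrected, labels = m$labels, axis = m$axis,
                        name = paste0(m$name, "_emsc"))
  attr(out, "emsc_coefficients") <- coefs
  attr(out, "emsc_degenerate") <- degenerate
  out
}

#' Centre and scale a multivariate dataset
#'
#' Transforms each feature to mean 0 and standard deviation 1 — the standard
#' preprocessing for multivariate (non-spectral) data with heterogeneous
#' units. Zero-variance features are mapped to all-zeros with a warning.
#'
#' @param m a [dataset_matrix()] or matrix with at least 2 samples.
#' @return A [dataset_matrix()] of the same shape.
#' @export
standardize <- function(m) {
  dm <- if (inherits(m, "dataset_matrix")) m else dataset_matrix(m)
  x <- dm$values
  if (nrow(x) < 2) stop("standardize needs at least 2 samples")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) mapped to zeros")
    sdv[zero] <- 1
  }
  z <- sweep(sweep(x, 2, mu), 2, sdv, `/`)
  z[, zero] <- 0
  dataset_matrix(z, labels = dm$labels, axis = dm$axis, name = dm$name)
}

#' Dispatch preprocessing by data type
#'
#' Spectra (datasets carrying a wavenumber axis) are EMSC-corrected;
#' multivariate data are standardized; `"none"` passes through.
#'
#' @param m a [dataset_matrix()].
#' @param method `"auto"` (axis present ? emsc : standardize), `"emsc"`,
#'   `"standardize"`, or `"none"`.
#' @param ... passed to [emsc_fit_correct()].
#' @return A preprocessed [dataset_matrix()].
#' @export
preprocess <- function(m, method = c("auto", "emsc", "standardize", "none"),
                       ...) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (!is.null(m$axis)) "emsc" else "standardize"
  switch(method,
         emsc = emsc_fit_correct(m, ...),
         standardize = standardize(m),
         none = m)
}
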