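wn <- seq(600, 1800, length.out = 300)
ref <- exp(-((wn - 1000) / 40)^2) + 0.6 * exp(-((wn - 1500) / 80)^2)
lam <- 2 * (wn - min(wn)) / diff(range(wn)) - 1

test_that("EMSC exactly recovers spectra in the span of the design", {
  # x = reference itself: a=0, b=1, all baseline terms 0
  out <- emsc_fit_correct(dataset_matrix(rbind(ref, ref), axis = wn),
                          reference = ref)
  expect_lt(max(abs(out$values[1, ] - ref)), 1e-10)

  # affine distortion
  out <- emsc_fit_correct(dataset_matrix(rbind(2 * ref + 3), axis = wn),
                          reference = ref)
  expect_lt(max(abs(out$values[1, ] - ref)), 1e-10)
  co <- attr(out, "emsc_coefficients")
  expect_equal(unname(co[1, "b"]), 2, tolerance = 1e-9)
  expect_equal(unname(co[1, "a"]), 3, tolerance = 1e-8)

  # quadratic baseline, order-2 model; cross-checked against an independent
  # least-squares solve of the same 4-column design
  x <- 1.7 * ref + 0.5 * lam^2 - 0.2 * lam + 4
  out <- emsc_fit_correct(dataset_matrix(rbind(x), axis = wn),
                          reference = ref, polynomial_order = 2)
  expect_lt(max(abs(out$values[1, ] - ref)), 1e-8)
  design <- cbind(1, ref, lam, lam^2)
  beta <- solve(t(design) %*% design, t(design) %*% x)
  expect_equal(unname(attr(out, "emsc_coefficients")[1, c("a", "b", "d1", "d2")]),
               unname(beta[c(1, 2, 3, 4)]), tolerance = 1e-7)

  # exactness holds for any spectrum in the design span, orders 0..4
  for (ord in 0:4) {
    set.seed(ord + 1)
    coef <- runif(ord + 2, -1, 2)
    xi <- coef[1] + coef[2] * ref
    if (ord >= 1) for (j in seq_len(ord)) xi <- xi + runif(1, -1, 1) * lam^j
    o <- emsc_fit_correct(dataset_matrix(rbind(xi), axis = wn),
                          reference = ref, polynomial_order = ord)
    if (abs(coef[2]) > 1e-6)
      expect_lt(max(abs(o$values[1, ] - ref)), 1e-7)
  }
})

test_that("EMSC removes interferent contributions", {
  interf <- exp(-((wn - 1200) / 30)^2)
  x <- 1.3 * ref + 0.8 * interf + 0.2
  out <- emsc_fit_correct(dataset_matrix(rbind(x), axis = wn),
                          reference = ref, interferents = rbind(interf))
  expect_lt(max(abs(out$values[1, ] - ref)), 1e-8)
  expect_equal(unname(attr(out, "emsc_coefficients")[1, "g1"]), 0.8,
               tolerance = 1e-7)
})

test_that("EMSC is idempotent and flags degenerate scatter coefficients", {
  spec <- spectra_spec(class_sizes = c(10, 10), wavenumbers = wn, seed = 4)
  m <- make_spectra(spec)
  once <- emsc_fit_correct(m, reference = colMeans(m$values))
  twice <- emsc_fit_correct(once, reference = colMeans(m$values))
  expect_lt(max(abs(twice$values - once$values)), 1e-8)

  # a pure-baseline spectrum has b ~ 0: flagged, not divided
  flat <- rbind(ref, 0 * ref + 2)
  expect_warning(
    out <- emsc_fit_correct(dataset_matrix(flat, axis = wn), reference = ref),
    "uncorrected")
  expect_true(attr(out, "emsc_degenerate")[2])
})

test_that("EMSC reduces within-class variance on scatter-distorted spectra", {
  wcv <- function(m) {
    mean(vapply(unique(m$labels), function(g)
      mean(apply(m$values[m$labels == g, , drop = FALSE], 2, var)), 0))
  }
  worse <- 0
  for (s in 1:20) {
    m <- make_spectra(spectra_spec(class_sizes = c(15, 15),
                                   wavenumbers = seq(600, 1800, by = 8),
                                   scatter_range = c(0.6, 1.5),
                                   baseline_range = c(-0.5, 0.5), seed = s))
    corrected <- emsc_fit_correct(m)
    if (wcv(corrected) >= wcv(m)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("standardize centres, scales, warns on constants, is idempotent", {
  set.seed(7)
  x <- cbind(matrix(rnorm(60, sd = 9), 20, 3), 5)
  expect_warning(z <- standardize(dataset_matrix(x)), "zero-variance")
  expect_lt(max(abs(colMeans(z$values))), 1e-12)
  expect_lt(max(abs(apply(z$values[, 1:3], 2, sd) - 1)), 1e-12)
  expect_true(all(z$values[, 4] == 0))
  expect_warning(z2 <- standardize(z), "zero-variance")
  expect_equal(z2$values, z$values, tolerance = 1e-12)
  expect_error(standardize(dataset_matrix(matrix(1, 1, 3))), "at least 2")
})

test_that("preprocess dispatches on the wavenumber axis", {
  spectra <- make_spectra(spectra_spec(class_sizes = c(5, 5),
                                       wavenumbers = wn, seed = 2))
  expect_match(preprocess(spectra)$name, "emsc")
  plain <- dataset_matrix(matrix(rnorm(40), 10, 4))
  expect_equal(colMeans(preprocess(plain)$values), rep(0, 4),
               tolerance = 1e-12)
  expect_identical(preprocess(plain, "none"), plain)
})
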