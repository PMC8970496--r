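test_that("dataset-level flags follow the size and dimensionality thresholds", {
  m <- function(n, p) dataset_matrix(matrix(rnorm(n * p), n, p))
  dc <- characterize_dataset(m(150, 4))
  expect_true(dc$small_dataset)
  expect_false(dc$high_dimensional)
  dc <- characterize_dataset(m(801, 60))   # stands in for wide omics data
  expect_true(dc$high_dimensional)
  expect_true(dc$small_dataset)            # 801 samples is still "small"
  dc <- characterize_dataset(m(1200, 60))
  expect_false(dc$small_dataset)
  dc <- characterize_dataset(m(5000, 10))
  expect_false(dc$small_dataset)
  expect_false(dc$high_dimensional)
  expect_error(characterize_dataset(dataset_matrix(matrix(0, 0, 4))), "empty")
})

test_that("project_pca agrees with an SVD oracle and partitions variance", {
  set.seed(42)
  x <- matrix(rnorm(80 * 5), 80, 5) %*% diag(c(5, 3, 1, 0.5, 0.1))
  p <- project_pca(dataset_matrix(x), q = 5)
  # independent oracle: singular value decomposition of the centred matrix
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  scores_oracle <- sv$u %*% diag(sv$d)
  for (j in 1:5)  # columns match up to sign
    expect_lt(min(max(abs(p$scores[, j] - scores_oracle[, j])),
                  max(abs(p$scores[, j] + scores_oracle[, j]))), 1e-8)
  expect_equal(p$explained_fraction, sv$d^2 / sum(sv$d^2), tolerance = 1e-10)
  expect_true(all(diff(p$explained_fraction) <= 1e-12))
  expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-10)

  # rank-1 matrix: all variance on the first axis
  r1 <- outer(rnorm(10), c(1, 2, 3))
  expect_equal(project_pca(dataset_matrix(r1), q = 1)$explained_fraction, 1,
               tolerance = 1e-12)
  expect_error(project_pca(dataset_matrix(r1), q = 4), "exceeds")
})

test_that("cluster structure measures recover the generating specification", {
  # two equal, well-separated isotropic clusters: no flags
  m <- make_blobs(n_per = 30, seed = 3)
  cs <- characterize_clusters(m)
  expect_equal(cs$n_clusters, 2)
  expect_equal(cs$balance_ratio, 1)
  expect_false(cs$has_single_point_cluster)
  expect_false(any(cs$flags))

  # singleton class
  m <- make_clusters(cluster_spec(sizes = c(30, 30, 1), seed = 5))
  cs <- characterize_clusters(m)
  expect_true(cs$has_single_point_cluster)
  expect_true(cs$flags[["single_point_cluster"]])
  expect_equal(unname(cs$sizes), c(30L, 30L, 1L))

  # anisotropy: covariance diag(100, 1) gives projected axis ratio ~ 10
  m <- make_clusters(cluster_spec(sizes = 200, n_features = 2,
                                  covariances = list(diag(c(100, 1))),
                                  seed = 11))
  cs <- characterize_clusters(m)
  expect_gt(cs$max_elongation, 7)
  expect_lt(cs$max_elongation, 13)
  expect_true(cs$flags[["non_spherical_shape"]])
})

test_that("characteristics are invariant to sample order and label renaming", {
  m <- make_clusters(cluster_spec(sizes = c(40, 20, 10), seed = 9,
                                  density_scales = c(1, 1, 4)))
  cs <- characterize_clusters(m)
  set.seed(1)
  perm <- sample(nrow(m$values))
  m2 <- dataset_matrix(m$values[perm, ], labels = m$labels[perm])
  cs2 <- characterize_clusters(m2)
  for (f in c("balance_ratio", "density_variation_ratio", "max_elongation",
              "outlier_fraction", "flags"))
    expect_equal(cs2[[f]], cs[[f]])

  relabel <- c(3L, 1L, 2L)[m$labels]
  cs3 <- characterize_clusters(dataset_matrix(m$values, labels = relabel))
  expect_equal(cs3$flags, cs$flags)
  expect_equal(sort(unname(cs3$sizes)), sort(unname(cs$sizes)))
})

test_that("unlabelled structure estimation matches labelled characterization", {
  m <- make_blobs(n_per = 25, k = 3, seed = 13)
  truth <- characterize_clusters(m)
  est <- estimate_structure_unlabelled(dataset_matrix(m$values), k = 3)
  expect_true(est$estimated)
  expect_equal(est$flags, truth$flags)
  expect_equal(sort(unname(est$sizes)), sort(unname(truth$sizes)))

  one <- estimate_structure_unlabelled(dataset_matrix(m$values), k = 1)
  expect_equal(one$balance_ratio, 1)
  all_singletons <- estimate_structure_unlabelled(dataset_matrix(m$values),
                                                  k = nrow(m$values))
  expect_true(all_singletons$has_single_point_cluster)
  expect_error(estimate_structure_unlabelled(dataset_matrix(m$values),
                                             k = nrow(m$values) + 1),
               "exceeds")
})

test_that("requirement profiles derive from the measured flags", {
  # gene-expression-like: balanced spherical very-wide data
  m <- make_archetype("gene_like", seed = 2, n_features = 300)
  dc <- characterize_dataset(m)
  cs <- characterize_clusters(m)
  marks <- derive_requirement_profile(dc, cs)
  expect_true(marks[["high_dimensions"]])
  expect_false(any(marks[c("non_spherical_shape", "variable_cluster_density",
                           "single_point_cluster", "uneven_cluster_size")]))

  # balanced spherical low-dimensional data: nothing marked except smallness
  m <- make_blobs(n_per = 40, k = 3, seed = 21)
  marks <- derive_requirement_profile(characterize_dataset(m),
                                      characterize_clusters(m))
  expect_false(any(marks[setdiff(names(marks), "small_datasets")]))

  # robustness is never requested alongside a single-point cluster
  m <- make_clusters(cluster_spec(sizes = c(40, 1), n_outliers = 5, seed = 8))
  marks <- derive_requirement_profile(characterize_dataset(m),
                                      characterize_clusters(m))
  expect_true(marks[["single_point_cluster"]])
  expect_false(marks[["robust_noise_outliers"]])
})

test_that("generator-specified structure is recovered across seeds", {
  # effect sizes at 2x each detection threshold; >= 90% of 20 seeds recover
  hits <- list(balance = 0, singleton = 0, density = 0, elongation = 0)
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    m <- make_clusters(cluster_spec(
      sizes = c(40, 10, 1),                       # balance 0.25 = 0.5/2
      n_features = 2, separation = 40,
      density_scales = c(1, 4, 1),                # density ratio ~ 4 = 2*2
      covariances = list(diag(c(16, 1)), NULL, NULL),  # axis ratio ~ 4
      seed = 1000 + s))
    cs <- characterize_clusters(m)
    hits$balance <- hits$balance + cs$flags[["uneven_cluster_size"]]
    hits$singleton <- hits$singleton + cs$flags[["single_point_cluster"]]
    hits$density <- hits$density + cs$flags[["variable_cluster_density"]]
    hits$elongation <- hits$elongation + cs$flags[["non_spherical_shape"]]
  }
  for (nm in names(hits))
    expect_gte(hits[[nm]], 0.9 * n_seeds)
})
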