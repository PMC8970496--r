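test_that("contingency tables count class-cluster co-occurrences", {
  tab <- contingency(c(0, 0, 1, 1), c(0, 0, 1, 2))
  expect_equal(unname(tab), rbind(c(2, 0, 0), c(0, 1, 1)))
  expect_error(contingency(1:3, 1:4), "length")
  expect_error(contingency(integer(0), integer(0)), "empty")
  set.seed(1)
  perm <- sample(4)
  expect_equal(contingency(c(0, 0, 1, 1)[perm], c(0, 0, 1, 2)[perm]), tab)
})

test_that("homogeneity, completeness and V-measure match hand computations", {
  # every cluster pure
  expect_equal(homogeneity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # one cluster over two equal classes carries no class information
  expect_equal(homogeneity(c(1, 1, 2, 2), rep(1, 4)), 0)
  # frozen hand computation: 1 - (3/4) H(1/3, 2/3) / H(1/2, 1/2)
  expect_equal(homogeneity(c(0, 0, 1, 1), c(0, 1, 1, 1)), 0.311278,
               tolerance = 1e-6)

  expect_equal(completeness(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # every point its own cluster, 2 equal classes of 2: c = 1 - ln2/ln4
  expect_equal(completeness(c(1, 1, 2, 2), 1:4), 0.5)
  # duality
  t <- c(1, 1, 2, 3); p <- c(2, 1, 1, 1)
  expect_equal(completeness(t, p), homogeneity(p, t))

  vm <- v_measure(c(0, 0, 1, 1), c(0, 0, 1, 2))
  expect_equal(vm$h, 1)
  expect_equal(vm$c, 2 / 3, tolerance = 1e-12)
  expect_equal(vm$v, 0.8, tolerance = 1e-12)

  expect_equal(v_measure(rep(1:3, each = 5), rep(1:3, each = 5))$v, 1)
  expect_equal(v_measure(rep(1:2, each = 5), rep(1, 10))$v, 0)
  expect_error(v_measure(1:2, 1:2, beta = 0), "positive")
})

test_that("V-measure equals the brute-force entropy oracle on random pairs", {
  set.seed(2024)
  for (rep in 1:300) {
    n <- sample(2:30, 1)
    true <- sample.int(sample(1:5, 1), n, replace = TRUE)
    pred <- sample.int(sample(1:5, 1), n, replace = TRUE)
    beta <- sample(c(0.5, 1, 2), 1)
    got <- v_measure(true, pred, beta = beta)
    want <- oracle_v_measure(true, pred, beta = beta)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$v, want$v, tolerance = 1e-12)
  }
})

test_that("V-measure symmetry and permutation invariance at beta = 1", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:25, 1)
    true <- sample.int(4, n, replace = TRUE)
    pred <- sample.int(4, n, replace = TRUE)
    expect_equal(v_measure(true, pred)$v, v_measure(pred, true)$v,
                 tolerance = 1e-12)
    relab <- sample(4)[pred]
    expect_equal(v_measure(true, relab)$v, v_measure(true, pred)$v,
                 tolerance = 1e-12)
    v <- v_measure(true, pred)
    expect_lte(v$v, max(v$h, v$c) + 1e-12)
  }
})

test_that("silhouette matches hand computation and an independent package", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  lab <- c(1, 1, 2, 2)
  # by hand: outer points (10.5-1)/10.5, inner points (9.5-1)/9.5
  hand <- mean(c(9.5 / 10.5, 8.5 / 9.5, 8.5 / 9.5, 9.5 / 10.5))
  expect_equal(silhouette_index(x, lab), hand, tolerance = 1e-12)
  expect_equal(hand, 0.8997494, tolerance = 1e-7)
  # independent implementation agrees
  expect_equal(silhouette_index(x, lab),
               mean(cluster::silhouette(lab, dist(x))[, "sil_width"]),
               tolerance = 1e-12)

  m <- make_blobs(n_per = 20, seed = 31)
  expect_gt(silhouette_index(m$values, m$labels), 0.9)

  # random labels on a single blob: no structure, silhouette ~ 0
  set.seed(5)
  one <- matrix(rnorm(120), 60, 2)
  sils <- replicate(100, silhouette_index(one, sample(1:2, 60, replace = TRUE)))
  expect_lt(abs(mean(sils)), 0.05)
  expect_error(silhouette_index(one, rep(1, 60)), "2 clusters")
})

test_that("Davies-Bouldin index matches hand computation", {
  x <- matrix(c(0, 2, 10, 12), ncol = 1)
  expect_equal(davies_bouldin(x, c(1, 1, 2, 2)), 0.2, tolerance = 1e-12)
  # duplicating every point leaves centroids and spreads unchanged
  expect_equal(davies_bouldin(rbind(x, x), rep(c(1, 1, 2, 2), 2)), 0.2,
               tolerance = 1e-12)
  # shrinking clusters toward their centroids drives the index to 0
  shrink <- matrix(c(0.9, 1.1, 10.9, 11.1), ncol = 1)
  expect_lt(davies_bouldin(shrink, c(1, 1, 2, 2)),
            davies_bouldin(x, c(1, 1, 2, 2)))
  expect_error(davies_bouldin(rbind(x, x[1:2, , drop = FALSE] + 10),
                              rep(1:3, each = 2)),
               "coincident")
})

test_that("Dunn index matches hand computation and is scale-invariant", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  expect_equal(dunn_index(x, c(1, 1, 2, 2)), 9)
  expect_equal(dunn_index(x * 7, c(1, 1, 2, 2)), 9, tolerance = 1e-12)
  touching <- matrix(c(0, 1, 1, 2), ncol = 1)
  expect_equal(dunn_index(touching, c(1, 1, 2, 2)), 0)
  expect_error(dunn_index(x, 1:4), "singleton")
})

test_that("evaluation grid scores, annotates and totals by group", {
  d1 <- make_blobs(n_per = 20, k = 3, seed = 41)
  d2 <- make_blobs(n_per = 15, k = 3, seed = 42)
  specs <- list(algorithm_spec("Hierarchical (Ward's)", target_k = 3),
                algorithm_spec("k-means", seed = 7, target_k = 3))
  ev <- evaluate_grid(specs, list(a = d1, b = d2),
                      groups = list(all = c("a", "b")))
  expect_equal(dim(ev$scores), c(2, 2))
  # perfectly separated blobs: every capable algorithm scores 1.0
  expect_true(all(ev$scores == 1))
  expect_equal(unname(ev$group_totals[, "all"]), unname(rowSums(ev$scores)))
  # identical seeds => identical grids
  ev2 <- evaluate_grid(specs, list(a = d1, b = d2),
                       groups = list(all = c("a", "b")))
  expect_identical(ev, ev2)
})

test_that("noise conventions and per-cell failure annotations", {
  d <- make_blobs(n_per = 20, k = 2, seed = 43)
  # a spec that cannot reach k: ward at k=5 on 2 blobs
  specs <- list(algorithm_spec("DBSCAN",
                               hyperparameters = list(eps = 1e-6)),
                algorithm_spec("Hierarchical (Ward's)", target_k = 5))
  ev <- evaluate_grid(specs, list(d = d))
  expect_true("excess_noise" %in%
                ev$annotations$flag[ev$annotations$algorithm == "DBSCAN"])
  expect_false(anyNA(ev$scores))
  # all-noise DBSCAN under the own-cluster convention: one big cluster, v = 0
  expect_equal(ev$scores["DBSCAN", "d"], 0)
  # under the singleton convention every noise point is its own cluster
  ev_s <- evaluate_grid(specs[1], list(d = d),
                        noise_convention = "singletons")
  expect_gt(ev_s$scores[1, 1], 0)
})
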