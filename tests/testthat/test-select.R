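kb <- load_kb()

test_that("matching scores algorithms against soft requirements", {
  rep1 <- match_algorithms(kb, requirement_set(required = "high_dimensions"))
  scores <- vapply(rep1, `[[`, 0, "score")
  expect_equal(sum(scores == 1), 4)
  expect_setequal(vapply(rep1, `[[`, "", "algorithm")[scores == 1],
                  query_support(kb, "high_dimensions"))

  # zero weights: scores vanish but the characteristic sets stay populated
  req0 <- requirement_set(required = c("small_datasets", "high_dimensions"),
                          weights = c(small_datasets = 0, high_dimensions = 0))
  rep0 <- match_algorithms(kb, req0)
  expect_true(all(vapply(rep0, `[[`, 0, "score") == 0))
  expect_true(all(vapply(rep0, function(r)
    length(c(r$satisfied, r$violated, r$unknown)), 0L) == 2))

  expect_error(requirement_set(required = "parameter_simplicity"),
               "hard")
})

test_that("unknown support is reported, never counted as violation", {
  rep <- match_algorithms(kb, requirement_set(required = "variable_cluster_density"))
  birch <- rep[[match("BIRCH", vapply(rep, `[[`, "", "algorithm"))]]
  expect_true("variable_cluster_density" %in% birch$unknown)
  expect_false("variable_cluster_density" %in% birch$violated)
  expect_equal(birch$score, 0)
})

test_that("the explosives profile puts Affinity Propagation on top", {
  rep <- match_algorithms(kb, scenario_presets("explosives"))
  scores <- vapply(rep, `[[`, 0, "score")
  names(scores) <- vapply(rep, `[[`, "", "algorithm")
  # hand count over the comparative matrix: 6 of 7 required characteristics
  expect_equal(unname(scores["Affinity Propagation"]), 6)
  expect_true(all(scores[setdiff(names(scores), "Affinity Propagation")] <
                    scores["Affinity Propagation"]))
})

test_that("down-selection rules and the four scenario presets", {
  # classic-ML: hard k-only constraint, no soft requirements
  sel <- select_algorithms(kb, scenario_presets("classic_ml"))
  expect_setequal(sel$selected,
                  c("Hierarchical (Ward's)", "Hierarchical (Single Link)",
                    "k-means", "PAM", "Fuzzy C-Means",
                    "Gaussian Mixture Model"))
  # gene expression: high dimensions + complexity cap
  sel <- select_algorithms(kb, scenario_presets("gene_expression"))
  expect_setequal(sel$selected, c("BIRCH", "k-means minibatch"))

  # every algorithm the qualitative stage picked for the spectroscopy
  # scenarios clears the majority bar and the hard constraints
  for (case in list(
    list(preset = "explosives",
         picked = c("Hierarchical (Ward's)", "Hierarchical (Single Link)",
                    "HDBSCAN", "Affinity Propagation")),
    list(preset = "public_spectroscopy",
         picked = c("Hierarchical (Ward's)", "HDBSCAN", "OPTICS",
                    "Gaussian Mixture Model")))) {
    rep <- match_algorithms(kb, scenario_presets(case$preset))
    for (alg in case$picked) {
      r <- rep[[match(alg, vapply(rep, `[[`, "", "algorithm"))]]
      expect_gt(r$score, r$max_score / 2)
      expect_true(r$passed_hard_constraints)
    }
    expect_true(all(case$picked %in%
                      down_select(rep, rule = "majority")$selected))
  }

  expect_error(down_select(match_algorithms(kb, scenario_presets("explosives")),
                           rule = "top_m", m = 0), "m > 0")
  expect_error(scenario_presets("nope"), "unknown preset")
})

test_that("ranking is deterministic with KB-order tie-breaks", {
  req <- requirement_set(required = "small_datasets")
  s1 <- select_algorithms(kb, req)
  s2 <- select_algorithms(kb, req)
  expect_identical(vapply(s1$ranked, `[[`, "", "algorithm"),
                   vapply(s2$ranked, `[[`, "", "algorithm"))
  # all tied at score 1 except the two small_datasets = no rows:
  # ties resolve to KB row order
  tied <- vapply(s1$ranked, `[[`, "", "algorithm")
  expect_identical(tied[1:2], c("Hierarchical (Ward's)",
                                "Hierarchical (Single Link)"))
})

test_that("adding a requirement never helps an algorithm that violates it", {
  base <- requirement_set(required = "small_datasets")
  extra <- requirement_set(required = c("small_datasets", "high_dimensions"))
  rb <- match_algorithms(kb, base)
  re <- match_algorithms(kb, extra)
  for (i in seq_along(rb)) {
    if ("high_dimensions" %in% re[[i]]$violated) {
      frac_b <- rb[[i]]$score / rb[[i]]$max_score
      frac_e <- re[[i]]$score / re[[i]]$max_score
      expect_lte(frac_e, frac_b)
    }
  }
})

test_that("selection results export to CSV", {
  sel <- select_algorithms(kb, scenario_presets("gene_expression"))
  tmp <- tempfile(fileext = ".csv")
  selection_table(sel, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), 14)
  expect_setequal(df$algorithm[df$selected], c("BIRCH", "k-means minibatch"))
})
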