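test_that("a single-configuration grid reproduces plain cross-validation bit-for-bit", {
  co <- generate_cohort(cohort_spec(n = 240, prevalence = 0.15, seed = 31))
  cfg <- network_config(depth = 1, width = 8, lambda = 0.1, mapping = "zero",
                        max_epochs = 30, patience = 15, seed = 5)
  plan <- stratified_kfold(co$labels, 3, seed = 7)
  cv <- cross_validate(co, cfg, plan)
  grid1 <- tibble::tibble(depth = 1, width = 8, regularization = 0.1,
                          bypass = FALSE)
  ng <- nested_grid_search(co, grid1, plan, inner_k = 3, config = cfg)
  expect_identical(ng$folds$scores, cv$folds$scores)
  expect_identical(tidy(ng), tidy(cv))
  expect_identical(glance(ng)[-1], glance(cv)[-1])
})

test_that("nested selection prefers a trained configuration over a sabotaged one", {
  co <- make_separable_cohort(n = 300, d = 12, margin = 0.5,
                              prevalence = 0.2, seed = 41)
  cfg <- network_config(depth = 1, width = 6, lambda = 0.1, mapping = "semi",
                        max_epochs = 80, patience = 40, seed = 3)
  # row 2 is crippled: a single epoch at zero learning rate never trains
  grid <- tibble::tibble(depth = c(1, 1), width = c(6, 6),
                         regularization = c(0.1, 0.1), bypass = FALSE,
                         max_epochs = c(80, 1), learning_rate = c(1e-3, 0))
  ng <- nested_grid_search(co, grid, stratified_kfold(co$labels, 3, seed = 2),
                           inner_k = 3, config = cfg)
  inner <- ng$inner
  for (f in unique(inner$fold)) {
    sc <- inner$inner_pr_auc[inner$fold == f]
    expect_gt(sc[1], sc[2])
  }
  expect_true(all(ng$folds$pr_auc > 0.9))
})

test_that("every grid configuration evaluated comes from the declared grid", {
  grid <- hyper_grid()
  expect_equal(nrow(grid), 48)
  small <- hyper_grid(depth = 1:2, width = 5, regularization = c(0.01, 0.1),
                      bypass = FALSE)
  co <- make_separable_cohort(n = 150, d = 10, margin = 0.5,
                              prevalence = 0.2, seed = 17)
  cfg <- network_config(depth = 1, width = 5, mapping = "sym",
                        max_epochs = 15, patience = 8, seed = 1)
  ng <- nested_grid_search(co, small, stratified_kfold(co$labels, 3, seed = 1),
                           inner_k = 3, config = cfg)
  chosen <- dplyr::distinct(ng$folds[, c("depth", "width", "regularization",
                                         "bypass")])
  expect_true(all(apply(chosen, 1, function(r) {
    any(small$depth == r[["depth"]] & small$width == r[["width"]] &
          small$regularization == r[["regularization"]] &
          small$bypass == r[["bypass"]])
  })))
})

test_that("preprocessing, inner selection and early stopping never see outer held-out rows", {
  co <- generate_cohort(cohort_spec(n = 180, prevalence = 0.2, seed = 51))
  cfg <- network_config(depth = 1, width = 6, lambda = 0.1, mapping = "semi",
                        max_epochs = 10, patience = 5, seed = 9)
  plan <- stratified_kfold(co$labels, 3, seed = 11)
  grid <- tibble::tibble(depth = c(1, 2), width = 6, regularization = 0.1,
                         bypass = FALSE)
  audit <- new.env()
  ng <- nested_grid_search(co, grid, plan, inner_k = 3, config = cfg,
                           audit = audit)
  # every fit (inner evaluations and outer retrains) logs the rows it used
  # for preprocessing statistics, gradient updates and early stopping, and
  # the rows it was forbidden to touch (its own test rows and, for inner
  # fits, the outer held-out rows)
  n_fits <- plan$k * (nrow(grid) * 3 + 1)
  expect_length(audit$log, n_fits)
  for (rec in audit$log) {
    consumed <- c(rec$stats_rows, rec$train_rows, rec$early_stop_rows)
    expect_length(intersect(consumed, rec$forbidden), 0)
    expect_length(intersect(consumed, rec$test_rows), 0)
    # early-stopping rows come out of the training partition
    expect_length(setdiff(rec$early_stop_rows, rec$stats_rows), 0)
    # gradient rows and monitor rows are disjoint
    expect_length(intersect(rec$train_rows, rec$early_stop_rows), 0)
  }
  # outer retrains (one per fold) trained on the full outer-training set
  retrains <- audit$log[vapply(audit$log, function(r)
    identical(r$forbidden, r$test_rows), TRUE)]
  expect_length(retrains, plan$k)
  for (rec in retrains) {
    expect_setequal(rec$stats_rows, setdiff(seq_along(co$labels), rec$test_rows))
  }
})

test_that("scenario runs share folds so method scores are index-aligned", {
  co <- generate_cohort(cohort_spec(n = 200, prevalence = 0.2, seed = 61))
  sc <- run_scenarios(co$features, co$targets,
                      subsets = list(character(0), "Schiller"),
                      methods = c("baseline", "zero"), k = 3,
                      config = network_config(depth = 1, width = 8,
                                              lambda = 0.1, max_epochs = 15,
                                              patience = 8),
                      seed = 13)
  expect_equal(nrow(sc$summary), 4)
  expect_equal(nrow(sc$folds), 4 * 3)
  # within a subset both methods scored identical held-out label vectors
  for (s in unique(sc$folds$subset)) {
    sub <- sc$folds[sc$folds$subset == s, ]
    for (f in unique(sub$fold)) {
      labs <- sub$labels[sub$fold == f]
      expect_identical(labs[[1]], labs[[2]])
    }
  }
  # 8 subsets x 4 methods would give 32 cells; the subset lattice is complete
  expect_length(all_subsets(), 8)
  expect_length(unique(vapply(all_subsets(), paste, "", collapse = "+")), 8)
})

test_that("observing an informative screening outcome does not hurt selection PR-AUC", {
  co <- generate_cohort(cohort_spec(n = 260, prevalence = 0.2,
                                    effect_sizes = c(1, 1, 1), seed = 71))
  cfg <- network_config(depth = 1, width = 8, lambda = 0.1, mapping = "semi",
                        max_epochs = 40, patience = 20)
  sc <- run_scenarios(co$features, co$targets,
                      subsets = list(character(0), "Schiller"),
                      methods = "semi", k = 3, config = cfg, seed = 17)
  m0 <- sc$summary$mean_pr_auc[sc$summary$subset == ""]
  m1 <- sc$summary$mean_pr_auc[sc$summary$subset == "S"]
  # Schiller is simulated as a high-sensitivity test of the outcome, so
  # observing it should raise PR-AUC well beyond fold noise
  expect_gt(m1, m0)
})
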