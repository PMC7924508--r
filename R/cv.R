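#' Hyper-parameter grid for model selection
#'
#' Cartesian product of network depth, width, regularization weight and
#' bypass usage (defaults: depth 1–6, width \{10, 20\}, regularization
#' \{0.01, 0.1\}, bypass \{false, true\} — 48 configurations). The mapping is
#' fixed per experiment, not part of the grid.
#'
#' @param depth,width,regularization,bypass Option vectors.
#' @return Tibble with one row per configuration.
#' @export
hyper_grid <- function(depth = 1:6, width = c(10, 20),
                       regularization = c(0.01, 0.1),
                       bypass = c(FALSE, TRUE)) {
  tidyr::expand_grid(depth = depth, width = width,
                     regularization = regularization, bypass = bypass)
}

# Instantiate one grid row on top of the base configuration. The canonical
# grid columns are depth/width/regularization/bypass; any extra column whose
# name matches a network_config() argument (e.g. max_epochs) overrides too.
apply_grid_row <- function(config, row) {
  args <- unclass(config)
  args$lambda <- row$regularization %||% args$lambda
  for (nm in intersect(names(row), names(args))) args[[nm]] <- row[[nm]]
  do.call(network_config, args)
}

# Fit on train_idx (preprocessing statistics fitted there only), score on
# test_idx. The audit environment receives, per fit, the global row ids
# consumed for statistics, gradient updates and early stopping, plus the row
# ids this fit was forbidden to touch (the outer held-out set).
fit_fold <- function(cohort, train_idx, test_idx, config, seed, audit = NULL,
                     forbidden = test_idx) {
  tr <- subset_cohort(cohort, train_idx)
  te <- subset_cohort(cohort, test_idx)
  pp <- preprocess_features(tr$features)
  tr$features <- pp$table
  cfg <- config
  cfg$seed <- as.integer(seed)
  local_audit <- if (!is.null(audit)) new.env()
  model <- train_embedder(tr, cfg, row_ids = train_idx, audit = local_audit)
  if (!is.null(audit)) {
    audit$log <- c(audit$log, list(list(
      stats_rows = train_idx,
      train_rows = local_audit$train_rows,
      early_stop_rows = local_audit$early_stop_rows,
      test_rows = test_idx, forbidden = forbidden)))
    audit$stats_rows <- c(audit$stats_rows, train_idx)
    audit$train_rows <- c(audit$train_rows, local_audit$train_rows)
    audit$early_stop_rows <- c(audit$early_stop_rows,
                               local_audit$early_stop_rows)
  }
  model$preprocessing <- pp$stats
  te_pp <- preprocess_features(te$features, stats = pp$stats)$table
  scores <- predict_proba(model, te_pp)
  y_te <- te$labels
  list(pr_auc = pr_auc(scores, y_te), log_loss = logistic_loss(scores, y_te),
       scores = scores, labels = y_te, model = model)
}

new_cv_result <- function(folds, method, subset_label = "") {
  structure(list(folds = folds, method = method, subset = subset_label),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance.cv_result(x)
  cat("<cv_result> method=", x$method,
      if (nzchar(x$subset)) paste0(" subset=", x$subset) else "",
      ": ", nrow(x$folds), " folds\n", sep = "")
  cat("  PR-AUC mean ", signif(g$mean_pr_auc, 4), " (sd ",
      signif(g$sd_pr_auc, 3), "), pooled ", signif(g$pooled_pr_auc, 4),
      "; log loss mean ", signif(g$mean_log_loss, 4), "\n", sep = "")
  invisible(x)
}

#' Plain stratified cross-validation of one configuration
#'
#' For every fold of the plan: fit imputation/scaling statistics and the
#' network on the training records only, score the held-out records by PR-AUC
#' and logistic loss. The per-fold retrain seed is derived deterministically
#' from `config$seed` and the fold index.
#'
#' @param cohort A `labeled_cohort` (features may still contain missing
#'   values; preprocessing is refitted per training fold).
#' @param config A [network_config()].
#' @param plan A [stratified_kfold()] plan over the cohort labels.
#' @param audit Optional environment collecting the leakage audit trail.
#' @return A `cv_result`: per-fold tibble (chosen config, metrics, held-out
#'   scores and labels as list columns) with mean and pooled aggregates via
#'   [glance()].
#' @export
cross_validate <- function(cohort, config, plan, audit = NULL) {
  folds <- purrr::map_dfr(seq_len(plan$k), function(f) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    fit <- fit_fold(cohort, train_idx, test_idx, config,
                    seed = derive_seed(config$seed, 1000L + f), audit = audit)
    tibble::tibble(fold = f, depth = config$depth, width = config$width,
                   regularization = config$lambda, bypass = config$bypass,
                   pr_auc = fit$pr_auc, log_loss = fit$log_loss,
                   n_test = length(test_idx),
                   scores = list(fit$scores), labels = list(fit$labels))
  })
  new_cv_result(folds, method = config$mapping)
}

#' Nested cross-validated grid search
#'
#' For each outer fold, every grid configuration is scored by its mean PR-AUC
#' over `inner_k` stratified folds of the outer-training records (statistics
#' and early stopping confined to the inner training partitions); the winner
#' — ties broken toward the simplest model: smaller depth, then width, then
#' no bypass, then smaller regularization — is retrained on the entire
#' outer-training set and scored on the outer held-out records. The retrain
#' seed depends only on the global seed and the fold, so a one-row grid
#' reproduces [cross_validate()] exactly.
#'
#' @inheritParams cross_validate
#' @param grid A [hyper_grid()] tibble.
#' @param plan Outer [stratified_kfold()] plan.
#' @param inner_k Inner fold count (default 3).
#' @return A `cv_result` whose per-fold rows carry the selected
#'   configuration, plus an `inner` attribute with all inner-CV scores.
#' @export
nested_grid_search <- function(cohort, grid, plan, inner_k = 3, config,
                               audit = NULL) {
  if (nrow(grid) == 0) abort("The grid is empty.")
  seed0 <- config$seed
  inner_log <- list()
  folds <- purrr::map_dfr(seq_len(plan$k), function(f) {
    test_idx <- which(plan$assignment == f)
    train_idx <- which(plan$assignment != f)
    y_tr <- cohort$labels[train_idx]
    inner_plan <- stratified_kfold(y_tr, inner_k,
                                   seed = derive_seed(seed0, 3000L + f))
    inner_scores <- purrr::map_dbl(seq_len(nrow(grid)), function(g) {
      cfg_g <- apply_grid_row(config, grid[g, ])
      mean(purrr::map_dbl(seq_len(inner_k), function(j) {
        i_test <- train_idx[inner_plan$assignment == j]
        i_train <- train_idx[inner_plan$assignment != j]
        fit <- fit_fold(cohort, i_train, i_test, cfg_g,
                        seed = derive_seed(seed0, 2000L + f, g, j),
                        audit = audit, forbidden = c(i_test, test_idx))
        fit$pr_auc
      }))
    })
    pick <- order(-inner_scores, grid$depth, grid$width, grid$bypass,
                  grid$regularization)[1]
    inner_log[[f]] <<- tibble::tibble(fold = f, grid_row = seq_len(nrow(grid)),
                                      inner_pr_auc = inner_scores)
    best_cfg <- apply_grid_row(config, grid[pick, ])
    fit <- fit_fold(cohort, train_idx, test_idx, best_cfg,
                    seed = derive_seed(seed0, 1000L + f), audit = audit)
    tibble::tibble(fold = f, depth = best_cfg$depth, width = best_cfg$width,
                   regularization = best_cfg$lambda, bypass = best_cfg$bypass,
                   pr_auc = fit$pr_auc, log_loss = fit$log_loss,
                   n_test = length(test_idx),
                   scores = list(fit$scores), labels = list(fit$labels))
  })
  out <- new_cv_result(folds, method = config$mapping)
  out$inner <- dplyr::bind_rows(inner_log)
  out
}

#' All observability subsets of a set of screening tests
#'
#' @param tests Character vector of screening outcome columns.
#' @return List of all subsets (including the empty one).
#' @export
all_subsets <- function(tests = c("Cytology", "Hinselmann", "Schiller")) {
  out <- list(character(0))
  for (t in tests) out <- c(out, lapply(out, function(s) c(s, t)))
  out[order(lengths(out))]
}

subset_label <- function(subset) {
  paste(substr(subset, 1, 1), collapse = "")
}

method_mapping <- function(method) {
  switch(method, baseline = "baseline", semi = "semi", sym = "sym",
         zero = "zero", unsupervised = "unsupervised",
         abort(paste0("Unknown method: ", method)))
}

#' Run the observability-scenario matrix
#'
#' Evaluates every (observability subset, method) cell: the subset's
#' screening outcomes are appended as input features, and each method
#' (baseline feed-forward classifier, semi-supervised, symmetry- and
#' zero-mapping embeddings) is cross-validated on one shared fold plan per
#' target, so fold-wise scores are index-aligned and paired comparisons
#' ([paired_t_test()]) are valid.
#'
#' @param features A `feature_table` of record features.
#' @param targets Data frame of binary outcome columns.
#' @param target_name The label column (default `"Biopsy"`).
#' @param subsets List of observability subsets (default: all 8 subsets of
#'   Cytology/Hinselmann/Schiller).
#' @param methods Character vector among `"baseline"`, `"semi"`, `"sym"`,
#'   `"zero"`, `"unsupervised"`.
#' @param k Outer fold count (default 10).
#' @param config Base [network_config()] (mapping is overridden per method).
#' @param grid Optional [hyper_grid()]; when supplied each cell runs
#'   [nested_grid_search()] with `inner_k` inner folds, otherwise plain
#'   [cross_validate()] of `config`.
#' @param inner_k Inner fold count for the nested search.
#' @param seed Seed for the shared fold plan and all derived stage seeds.
#' @return A `scenario_result`: list with `folds` (tibble: subset, method,
#'   fold, chosen config, metrics) and `summary` (one row per cell with mean
#'   and pooled metrics).
#' @export
run_scenarios <- function(features, targets, target_name = "Biopsy",
                          subsets = all_subsets(),
                          methods = c("baseline", "semi", "sym", "zero"),
                          k = 10, config = network_config(), grid = NULL,
                          inner_k = 3, seed = 1L) {
  plan <- stratified_kfold(targets[[target_name]], k, seed = seed)
  cells <- list()
  for (s in subsets) {
    cohort <- assemble_cohort(features, targets, target_name, s)
    lab <- subset_label(s)
    for (m in methods) {
      cfg <- config
      cfg$mapping <- method_mapping(m)
      if (cfg$mapping == "baseline") cfg$lambda <- 0
      if (cfg$mapping == "unsupervised") cfg$class_weight <- 0
      cfg$seed <- derive_seed(seed, nchar(lab), match(m, methods))
      res <- if (is.null(grid)) {
        cross_validate(cohort, cfg, plan)
      } else {
        nested_grid_search(cohort, grid, plan, inner_k = inner_k, config = cfg)
      }
      cells[[length(cells) + 1L]] <-
        dplyr::mutate(res$folds, subset = lab, method = m, .before = 1)
    }
  }
  folds <- dplyr::bind_rows(cells)
  summary <- folds |>
    dplyr::group_by(.data$subset, .data$method) |>
    dplyr::summarise(
      mean_pr_auc = mean(.data$pr_auc), sd_pr_auc = sd(.data$pr_auc),
      mean_log_loss = mean(.data$log_loss), sd_log_loss = sd(.data$log_loss),
      pooled_pr_auc = pr_auc(unlist(.data$scores), unlist(.data$labels)),
      pooled_log_loss = logistic_loss(unlist(.data$scores), unlist(.data$labels)),
      .groups = "drop")
  structure(list(folds = folds, summary = summary, k = plan$k, seed = seed),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", length(unique(x$folds$subset)), " subsets x ",
      length(unique(x$folds$method)), " methods, k=", x$k, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write scenario metrics as TSV
#'
#' One row per (subset, method, fold) plus an aggregate block, formatted
#' deterministically so identical runs produce byte-identical files.
#'
#' @param result A `scenario_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scenario_tsv <- function(result, path) {
  per_fold <- result$folds |>
    dplyr::select(!dplyr::any_of(c("scores", "labels"))) |>
    dplyr::mutate(block = "fold", .before = 1)
  agg <- result$summary |> dplyr::mutate(block = "aggregate", .before = 1)
  fmt <- function(df) {
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                          ~ sprintf("%.12g", .x)))
    df
  }
  out <- dplyr::bind_rows(fmt(per_fold), fmt(agg))
  readr::write_tsv(out, path, progress = FALSE, na = "")
  invisible(path)
}
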