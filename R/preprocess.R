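#' Mean-impute missing feature values
#'
#' Fills every remaining `NA` cell with the per-feature arithmetic mean. In
#' training mode (`means = NULL`) the means are computed from the table's
#' non-missing entries and returned so that test folds reuse the *training*
#' statistics — recomputing them on pooled data would leak held-out
#' information into preprocessing.
#'
#' @param table A `feature_table` from [encode_features()].
#' @param means Named numeric vector of per-feature means to apply (test
#'   mode), or `NULL` to fit them (training mode).
#' @return List with `table` (no missing values left; the missing mask and
#'   answered flags untouched) and `means` (the statistics used).
#' @export
impute_train_mean <- function(table, means = NULL) {
  v <- table$values
  if (is.null(means)) {
    means <- colMeans(v, na.rm = TRUE)
    dead <- which(!is.finite(means))
    if (length(dead) > 0) {
      abort(paste0("Cannot impute: feature '", colnames(v)[dead[1]],
                   "' is entirely missing in the training data."))
    }
  } else {
    if (!all(colnames(v) %in% names(means))) {
      abort("Supplied means do not cover every feature.")
    }
    means <- means[colnames(v)]
  }
  na_idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(na_idx) > 0) v[na_idx] <- means[na_idx[, 2]]
  out <- table
  out$values <- v
  list(table = out, means = means)
}

#' Scale features to the unit interval
#'
#' Min–max normalization to [0,1]. In training mode (`bounds = NULL`) the
#' per-feature minima and maxima are taken from the data and returned for
#' reuse; in test mode the stored bounds are applied and the result clipped
#' into [0,1], so a test value outside the training range never escapes the
#' unit interval. A constant feature maps to 0 (sparse cohort folds routinely
#' produce constant columns, so this is not an error).
#'
#' @param table A `feature_table` with no missing values (impute first).
#' @param bounds List with numeric vectors `min` and `max` (test mode), or
#'   `NULL` to fit them (training mode).
#' @return List with `table` (all values in [0,1]) and `bounds`.
#' @export
normalize_unit_interval <- function(table, bounds = NULL) {
  v <- table$values
  if (anyNA(v)) abort("Normalize after imputation: the table still has missing values.")
  if (is.null(bounds)) {
    bounds <- list(min = apply(v, 2, min), max = apply(v, 2, max))
  } else {
    if (length(bounds$min) != ncol(v) || length(bounds$max) != ncol(v)) {
      abort("Supplied bounds do not cover every feature.")
    }
  }
  rng <- bounds$max - bounds$min
  scale <- ifelse(rng > 0, 1 / rng, 0)  # constant feature -> 0
  v <- sweep(sweep(v, 2, bounds$min, "-"), 2, scale, "*")
  v <- pmin(pmax(v, 0), 1)
  out <- table
  out$values <- v
  list(table = out, bounds = bounds)
}

#' Impute and scale in one step with reusable statistics
#'
#' Convenience wrapper chaining [impute_train_mean()] and
#' [normalize_unit_interval()]. Fit the statistics on a training fold
#' (`stats = NULL`) and pass the returned `stats` when transforming held-out
#' records.
#'
#' @param table A `feature_table`.
#' @param stats List with `means` and `bounds` from a previous call, or `NULL`.
#' @return List with `table` (fully numeric, in [0,1]) and `stats`.
#' @export
preprocess_features <- function(table, stats = NULL) {
  imp <- impute_train_mean(table, stats$means)
  nrm <- normalize_unit_interval(imp$table, stats$bounds)
  list(table = nrm$table, stats = list(means = imp$means, bounds = nrm$bounds))
}

new_labeled_cohort <- function(features, labels, target_name, subset = character()) {
  labels <- as.integer(labels)
  stopifnot(inherits(features, "feature_table"))
  if (length(labels) != features$n) abort("Label length does not match record count.")
  if (!all(labels %in% c(0L, 1L))) abort("Labels must be binary 0/1.")
  structure(list(features = features, labels = labels,
                 target_name = target_name, subset = subset),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("<labeled_cohort> target '", x$target_name, "': ",
      sum(x$labels), "/", length(x$labels), " positives",
      if (length(x$subset)) paste0("; observed tests: ",
                                   paste(x$subset, collapse = "+")) else "",
      "\n", sep = "")
  print(x$features)
  invisible(x)
}

#' Attach a label and observable screening outcomes to a feature table
#'
#' Builds the modelling cohort for one screening scenario: the chosen target
#' column becomes the binary label, and the outcomes in `subset` (e.g. any of
#' Cytology, Hinselmann, Schiller) are appended to the features as extra
#' binary inputs — emulating a clinic where those test results are already on
#' the chart when the biopsy outcome is predicted. With the empty subset only
#' the record features are used. Requesting the target itself as an input is
#' label leakage and errors.
#'
#' @param table A `feature_table` of record features (any preprocessing state).
#' @param targets Data frame of binary outcome columns, one row per record.
#' @param target_name Which column of `targets` is the label.
#' @param subset Character vector of `targets` columns to append as observed
#'   inputs (default none). These are treated as never-missing.
#' @return A `labeled_cohort`.
#' @export
assemble_cohort <- function(table, targets, target_name, subset = character()) {
  targets <- as.data.frame(targets, check.names = FALSE)
  if (!target_name %in% names(targets)) {
    abort(paste0("Target '", target_name, "' not found among target columns."))
  }
  if (target_name %in% subset) {
    abort(paste0("Configuration error: target '", target_name,
                 "' cannot also be an input feature (label leakage)."))
  }
  missing_sub <- setdiff(subset, names(targets))
  if (length(missing_sub) > 0) {
    abort(paste0("Observability subset column(s) not found: ",
                 paste(missing_sub, collapse = ", ")))
  }
  if (nrow(targets) != table$n) abort("Targets row count does not match the table.")
  y <- targets[[target_name]]
  if (anyNA(y)) abort(paste0("Target '", target_name, "' has missing values."))
  ft <- table
  for (s in subset) {
    v <- as.numeric(targets[[s]])
    if (anyNA(v)) abort(paste0("Screening outcome '", s,
                               "' has missing values; observed inputs must be complete."))
    if (!is_binary01(v)) abort(paste0("Screening outcome '", s, "' must be binary 0/1."))
    ft$values <- cbind(ft$values, v)
    colnames(ft$values)[ncol(ft$values)] <- s
    ft$missing_mask <- cbind(ft$missing_mask, rep(FALSE, ft$n))
    colnames(ft$missing_mask) <- colnames(ft$values)
    ft$answered_flags <- c(ft$answered_flags, FALSE)
  }
  ft$feature_names <- colnames(ft$values)
  ft$d <- ncol(ft$values)
  new_labeled_cohort(ft, y, target_name, subset)
}

subset_cohort <- function(cohort, idx) {
  ft <- cohort$features
  ft$values <- ft$values[idx, , drop = FALSE]
  ft$missing_mask <- ft$missing_mask[idx, , drop = FALSE]
  ft$n <- length(idx)
  new_labeled_cohort(ft, cohort$labels[idx], cohort$target_name, cohort$subset)
}

#' Write an encoded feature table as TSV
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(table, path) {
  df <- as.data.frame(table$values, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
  invisible(path)
}
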