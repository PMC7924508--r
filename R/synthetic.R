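#' Specify a synthetic risk cohort
#'
#' Describes a cohort generator that mimics the statistical shape of
#' questionnaire-style risk-factor data: skewed non-negative numeric answers,
#' yes/no indicators, small categorical variables with one risk-elevated
#' level, a rare positive outcome, and refusals ("?") on answerable questions.
#' Labels follow a logistic model on a sparse set of active features with
#' non-negative effects, so every signal feature is positively associated
#' with the outcome (0 = absence of the risk pattern); the intercept is
#' calibrated so the expected positive rate equals `prevalence`.
#'
#' @param n Number of records.
#' @param d_numeric,d_boolean,d_categorical Counts of numeric (answerable
#'   integer), boolean (answerable yes/no) and categorical features.
#' @param prevalence Target positive rate in (0,1).
#' @param active_features Integer indices (into the
#'   `d_numeric + d_boolean + d_categorical` underlying features) that carry
#'   signal.
#' @param effect_sizes Non-negative log-odds weights, one per active feature.
#' @param refusal_rate Probability that a record withholds an answerable
#'   feature. `refusal_rate_pos` lets refusal be missing-not-at-random
#'   (refusal is itself a risk-associated behaviour); defaults to the same
#'   rate.
#' @param refusal_rate_pos Refusal probability for positive-label records.
#' @param noise_scale Dispersion multiplier for the non-signal variation.
#' @param seed Integer seed; the generator is deterministic given the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 500, d_numeric = 8, d_boolean = 6, d_categorical = 2,
                        prevalence = 0.1,
                        active_features = c(1L, 2L, 9L),
                        effect_sizes = c(2.5, 2.0, 1.5),
                        refusal_rate = 0.08, refusal_rate_pos = NULL,
                        noise_scale = 1, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must be in (0,1).")
  if (any(effect_sizes < 0)) abort("effect_sizes must be non-negative.")
  d_total <- d_numeric + d_boolean + d_categorical
  if (length(active_features) != length(effect_sizes)) {
    abort("active_features and effect_sizes must have the same length.")
  }
  if (length(active_features) > 0 &&
      (min(active_features) < 1 || max(active_features) > d_total)) {
    abort("active_features must index the underlying feature set.")
  }
  structure(list(n = as.integer(n), d_numeric = as.integer(d_numeric),
                 d_boolean = as.integer(d_boolean),
                 d_categorical = as.integer(d_categorical),
                 prevalence = prevalence,
                 active_features = as.integer(active_features),
                 effect_sizes = as.numeric(effect_sizes),
                 refusal_rate = refusal_rate,
                 refusal_rate_pos = refusal_rate_pos %||% refusal_rate,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic labeled cohort
#'
#' Draws a cohort per the spec (see [cohort_spec()]). The returned cohort
#' holds the *encoded but unscaled* feature table (refusals as missing
#' values), so cross-validation can fit imputation/normalization statistics
#' per training fold; run [preprocess_features()] before training directly.
#' Screening-test outcome columns (`Cytology`, `Hinselmann`, `Schiller`) are
#' simulated as noisy tests of the outcome with increasing sensitivity, and
#' `Biopsy` is the outcome itself, so observability scenarios can be built
#' with [assemble_cohort()].
#'
#' @param spec A [cohort_spec()].
#' @return A `labeled_cohort` with extra fields `raw` (the raw tibble in the
#'   CSV dialect), `schema`, `targets` (screening/biopsy tibble) and `truth`
#'   (generating parameters for recovery tests).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n
  d_num <- spec$d_numeric; d_bool <- spec$d_boolean; d_cat <- spec$d_categorical
  # Underlying normalized signals in [0,1], one per feature
  sig <- matrix(0, n, d_num + d_bool + d_cat)
  raw <- list()
  types <- character(0); names_ <- character(0); levels_ <- list()

  # numeric answerable questions: right-skewed counts on an integer scale
  for (j in seq_len(d_num)) {
    z <- stats::rbeta(n, 1.3, 1.3 + 2.2 * spec$noise_scale)
    top <- sample(8:30, 1)
    raw_v <- round(z * top)
    sig[, j] <- z
    nm <- paste0("num", j)
    raw[[nm]] <- as.numeric(raw_v)
    names_ <- c(names_, nm); types <- c(types, "bool_integer")
  }
  # boolean answerable questions
  for (j in seq_len(d_bool)) {
    p <- runif(1, 0.1, 0.5)
    v <- rbinom(n, 1, p)
    sig[, d_num + j] <- v
    nm <- paste0("bool", j)
    raw[[nm]] <- as.numeric(v)
    names_ <- c(names_, nm); types <- c(types, "bool_boolean")
  }
  # categoricals with 3-5 levels, the last level risk-elevated
  for (j in seq_len(d_cat)) {
    k <- sample(3:5, 1)
    lev <- paste0("L", seq_len(k))
    pr <- c(rep(0.8 / (k - 1), k - 1), 0.2)
    v <- sample(lev, n, replace = TRUE, prob = pr)
    sig[, d_num + d_bool + j] <- as.numeric(v == lev[k])
    nm <- paste0("cat", j)
    raw[[nm]] <- v
    names_ <- c(names_, nm); types <- c(types, "categorical")
    levels_[[nm]] <- lev
  }

  # logistic outcome with calibrated intercept
  eta <- rep(0, n)
  for (i in seq_along(spec$active_features)) {
    eta <- eta + spec$effect_sizes[i] * sig[, spec$active_features[i]]
  }
  f <- function(b0) mean(plogis(b0 + eta)) - spec$prevalence
  if (f(-40) > 0 || f(40) < 0) {
    abort("Calibration error: target prevalence unreachable for this effect configuration.")
  }
  b0 <- uniroot(f, c(-40, 40), tol = 1e-10)$root
  y <- rbinom(n, 1, plogis(b0 + eta))

  # refusals on answerable questions (possibly label-dependent)
  rr <- ifelse(y == 1, spec$refusal_rate_pos, spec$refusal_rate)
  for (j in which(types %in% c("bool_integer", "bool_boolean"))) {
    refuse <- runif(n) < rr
    raw[[names_[j]]][refuse] <- NA
  }

  raw_tbl <- tibble::as_tibble(raw)
  schema <- feature_schema(names_, types, levels_)
  ft <- encode_features(raw_tbl, schema)

  sens <- c(Cytology = 0.65, Hinselmann = 0.75, Schiller = 0.85)
  fpr <- c(Cytology = 0.06, Hinselmann = 0.05, Schiller = 0.04)
  targets <- tibble::tibble(
    Cytology = rbinom(n, 1, ifelse(y == 1, sens[1], fpr[1])),
    Hinselmann = rbinom(n, 1, ifelse(y == 1, sens[2], fpr[2])),
    Schiller = rbinom(n, 1, ifelse(y == 1, sens[3], fpr[3])),
    Biopsy = y
  )

  cohort <- new_labeled_cohort(ft, y, "Biopsy")
  cohort$raw <- raw_tbl
  cohort$schema <- schema
  cohort$targets <- targets
  cohort$truth <- list(intercept = b0, active_features = spec$active_features,
                       effect_sizes = spec$effect_sizes, spec = spec)
  cohort
}

#' Generate a linearly separable cohort
#'
#' Builds a cohort whose classes are separated with a stated geometric margin
#' along the first feature: positives have `x1 >= 0.5 + margin/2`, negatives
#' `x1 <= 0.5 - margin/2`, remaining features are uniform noise. The class
#' split is stratified, so the cohort has exactly `round(prevalence * n)`
#' positives. Used to check that every training method recovers a separable
#' signal (near-perfect PR-AUC).
#'
#' @param n Records. @param d Feature count (>= 1).
#' @param margin Positive gap between the class intervals (< 1).
#' @param prevalence Positive rate.
#' @param seed Integer seed.
#' @return A `labeled_cohort` whose features are already in [0,1] with no
#'   missing values.
#' @export
make_separable_cohort <- function(n = 500, d = 20, margin = 0.5,
                                  prevalence = 0.1, seed = 1L) {
  if (margin <= 0 || margin >= 1) abort("margin must be in (0,1).")
  withr::with_seed(seed, {
    n_pos <- round(prevalence * n)
    if (n_pos < 1 || n_pos >= n) abort("prevalence leaves a class empty.")
    y <- c(rep(1L, n_pos), rep(0L, n - n_pos))
    x1 <- ifelse(y == 1,
                 runif(n, 0.5 + margin / 2, 1),
                 runif(n, 0, 0.5 - margin / 2))
    x <- cbind(x1, if (d > 1) matrix(runif(n * (d - 1)), n, d - 1))
    ord <- sample.int(n)
    x <- x[ord, , drop = FALSE]; y <- y[ord]
    colnames(x) <- paste0("f", seq_len(d))
    ft <- new_feature_table(x, matrix(FALSE, n, d, dimnames = dimnames(x)),
                            rep(FALSE, d))
    cohort <- new_labeled_cohort(ft, y, "synthetic")
    cohort$truth <- list(direction = c(1, rep(0, d - 1)), threshold = 0.5,
                         margin = margin)
    cohort
  })
}

#' Write a synthetic cohort in the CSV questionnaire dialect
#'
#' Serializes the raw records with `"?"` as the missing marker plus the
#' screening/biopsy target columns, and optionally a sidecar YAML of the
#' ground-truth generating parameters for recovery tests.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param path Output CSV path.
#' @param truth_path Optional path for the ground-truth YAML sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path, truth_path = NULL) {
  if (is.null(cohort$raw)) abort("Cohort has no raw records to serialize.")
  df <- cohort$raw
  for (nm in names(df)) {
    v <- as.character(df[[nm]])
    v[is.na(v)] <- "?"
    df[[nm]] <- v
  }
  df <- dplyr::bind_cols(df, cohort$targets)
  readr::write_csv(df, path, progress = FALSE)
  if (!is.null(truth_path)) {
    tr <- cohort$truth
    yaml::write_yaml(list(intercept = tr$intercept,
                          active_features = as.integer(tr$active_features),
                          effect_sizes = tr$effect_sizes,
                          spec = unclass(tr$spec)), truth_path)
  }
  invisible(path)
}
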