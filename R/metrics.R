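#' Stratified k-fold plan
#'
#' Partitions the records into `k` folds with per-fold class counts balanced
#' to within one: indices of each class are shuffled and dealt round-robin.
#' Deterministic given the seed.
#'
#' @param labels Binary label vector.
#' @param k Fold count (`2 <= k <=` minority-class count).
#' @param seed Integer seed.
#' @return A `fold_plan`: list with `k`, per-record `assignment`,
#'   `stratified = TRUE`, `seed`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  labels <- as.integer(labels)
  n <- length(labels)
  minority <- min(table(factor(labels, levels = c(0, 1))))
  if (k < 2) abort("k must be at least 2 (no held-out set otherwise).")
  if (k > minority) {
    abort(paste0("k = ", k, " exceeds the minority-class count (", minority,
                 "); choose a smaller k."))
  }
  assignment <- integer(n)
  withr::with_seed(seed, {
    for (cls in c(0L, 1L)) {
      members <- sample(which(labels == cls))
      assignment[members] <- rep_len(seq_len(k), length(members))
    }
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 stratified = TRUE, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Area under the precision-recall curve (average precision)
#'
#' The average-precision step convention: records are ranked by score, equal
#' scores are grouped into one threshold, and the area is the sum over
#' thresholds of precision times the recall increment. No linear
#' interpolation is used (interpolating PR curves is optimistically biased).
#' With all scores equal the curve degenerates to a single point and the
#' value is the prevalence.
#'
#' @param scores Real-valued scores (higher = more positive).
#' @param labels Binary labels; both classes must be present.
#' @return Value in [0,1].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores/labels length mismatch.")
  n_pos <- sum(labels == 1)
  if (n_pos == 0 || n_pos == length(labels)) {
    abort("pr_auc needs both classes present.")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group ties: cumulative counts at the last row of each distinct score
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  pp <- last
  precision <- tp / pp
  recall <- tp / n_pos
  sum(precision * diff(c(0, recall)))
}

#' Logistic (cross-entropy) loss of probability scores
#'
#' `-mean(y log p + (1 - y) log(1 - p))` with probabilities clipped at
#' `eps = 1e-7`.
#'
#' @param scores Probabilities in [0,1].
#' @param labels Binary labels.
#' @param eps Clipping floor.
#' @return Non-negative scalar.
#' @export
logistic_loss <- function(scores, labels, eps = 1e-7) {
  if (length(scores) != length(labels)) abort("scores/labels length mismatch.")
  p <- clip01(scores, eps)
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Paired Student's t-test on per-fold metrics
#'
#' Classical two-sided paired t-test on the per-fold differences
#' (`df = k - 1`), for comparing two methods evaluated on the same fold plan.
#' Degenerate cases are resolved rather than failing: identical vectors give
#' `t = 0`, `p = 1`; a constant non-zero difference has zero variance and is
#' reported as trivially significant (`p = 0`) with an infinite statistic.
#'
#' @param metric_a,metric_b Equal-length (>= 2) per-fold metric vectors from
#'   the same fold plan.
#' @param conf_level Confidence level (default 0.95); the comparison is
#'   flagged `significant` when `p < 1 - conf_level`.
#' @return One-row tibble: `estimate` (mean difference a - b), `statistic`,
#'   `df`, `p_value`, `significant`.
#' @export
paired_t_test <- function(metric_a, metric_b, conf_level = 0.95) {
  if (length(metric_a) != length(metric_b)) abort("Vectors must be paired.")
  k <- length(metric_a)
  if (k < 2) abort("Need at least two folds (no degrees of freedom).")
  d <- metric_a - metric_b
  alpha <- 1 - conf_level
  if (sd(d) == 0) {
    if (all(d == 0)) {
      res <- tibble::tibble(estimate = 0, statistic = 0, df = k - 1,
                            p_value = 1, significant = FALSE)
    } else {
      res <- tibble::tibble(estimate = mean(d),
                            statistic = sign(mean(d)) * Inf, df = k - 1,
                            p_value = 0, significant = TRUE)
    }
    return(res)
  }
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  tibble::tibble(estimate = unname(tt$estimate),
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 significant = tt$p.value < alpha)
}
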