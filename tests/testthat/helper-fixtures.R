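# Shared fixtures and independent oracles used across the suite.

# A tiny questionnaire schema exercising every column type.
tiny_schema <- function() {
  feature_schema(
    c("Age", "Partners", "Smokes", "STDdx"),
    c("integer", "bool_integer", "bool_boolean", "categorical"),
    levels = list(STDdx = c("none", "hpv", "other"))
  )
}

tiny_raw <- function() {
  tibble::tibble(
    Age = c(20, 35, 50, 27),
    Partners = c(2, NA, 5, 1),
    Smokes = c(0, 1, NA, 0),
    STDdx = c("none", "hpv", "other", NA)
  )
}

tiny_targets <- function() {
  tibble::tibble(Cytology = c(0, 1, 1, 0), Hinselmann = c(0, 1, 0, 0),
                 Schiller = c(0, 1, 1, 0), Biopsy = c(0, 1, 1, 0))
}

# Feature table straight from a numeric matrix in [0,1].
matrix_feature_table <- function(X) {
  colnames(X) <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  riskembed:::new_feature_table(
    X, matrix(FALSE, nrow(X), ncol(X), dimnames = dimnames(X)),
    rep(FALSE, ncol(X)))
}

matrix_cohort <- function(X, y) {
  riskembed:::new_labeled_cohort(matrix_feature_table(X), y, "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force average precision: enumerate every distinct score as a
# threshold, classify by score >= threshold, accumulate precision times
# recall increment from the smallest recall up.
ap_bruteforce <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    precision <- tp / sum(pred)
    recall <- tp / n_pos
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# Textbook paired t statistic and two-sided p.
paired_t_oracle <- function(a, b) {
  d <- a - b
  k <- length(d)
  t <- mean(d) / (sd(d) / sqrt(k))
  list(t = t, p = 2 * stats::pt(-abs(t), df = k - 1))
}

# Perceptron separability oracle: returns TRUE if it finds a separating
# hyperplane within the iteration budget.
perceptron_separable <- function(X, y, max_iter = 2000) {
  Xa <- cbind(1, X)
  s <- ifelse(y == 1, 1, -1)
  w <- rep(0, ncol(Xa))
  for (it in seq_len(max_iter)) {
    margins <- s * drop(Xa %*% w)
    wrong <- which(margins <= 0)
    if (length(wrong) == 0) return(TRUE)
    i <- wrong[1]
    w <- w + s[i] * Xa[i, ]
  }
  FALSE
}

# A hand-built embedder with a single linear encoder layer (PReLU slope 1)
# and known weights; decoder/classifier minimal but shape-consistent.
linear_encoder_model <- function(W, bypass = FALSE) {
  d <- nrow(W); m <- ncol(W)
  cfg <- network_config(depth = 0, width = m, lambda = 0, l1_weight = 0,
                        bypass = bypass, mapping = "baseline",
                        corruption_rate = 0, seed = 1L)
  params <- list(
    enc = list(list(W = W, b = rep(0, m), a = 1)),
    dec = NULL,
    cls = list(W = matrix(0, m + if (bypass) d else 0, 2), b = c(0, 0))
  )
  structure(list(params = params, config = cfg,
                 history = tibble::tibble(epoch = 1, train_total = 0,
                                          train_classification = 0,
                                          train_reconstruction = 0,
                                          train_l1 = 0, val_objective = 0),
                 best_epoch = 1L, d = d,
                 feature_names = paste0("f", seq_len(d)),
                 preprocessing = NULL),
            class = "trained_embedder")
}

# Small fast training configuration used wherever a real fit is needed.
fast_config <- function(mapping = "semi", ...) {
  network_config(depth = 1, width = 5, lambda = 0.1, mapping = mapping,
                 max_epochs = 60, patience = 25, seed = 42L, ...)
}
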