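#' Train a supervised embedding network
#'
#' Minimizes the joint loss by mini-batch RMSProp with denoising corruption:
#' each batch is corrupted (at most one feature zeroed per record), the
#' network sees the corrupted records, and the reconstruction target is built
#' from the clean ones. After every epoch the full joint loss is evaluated
#' without corruption on a validation set — supplied, or a stratified
#' `val_fraction` split of the training records — and training stops once
#' `patience` epochs pass without improvement; the returned parameters are
#' those of the best validation epoch. Fully deterministic given
#' `config$seed`.
#'
#' @param cohort A `labeled_cohort` whose features are preprocessed (finite,
#'   in [0,1]) and contain both classes.
#' @param config A [network_config()].
#' @param validation Optional `labeled_cohort` for early-stopping monitoring.
#' @param row_ids Optional identifiers for the cohort rows, used only for the
#'   leakage audit trail.
#' @param audit Optional environment; when supplied, the identifiers of the
#'   rows used for gradient updates and for the early-stopping monitor are
#'   appended to `audit$train_rows` / `audit$early_stop_rows`.
#' @return A `trained_embedder` with fields `params`, `config`, `history`
#'   (per-epoch tibble of loss components), `best_epoch`, `d`,
#'   `feature_names`, and optionally `preprocessing` statistics attached by
#'   cross-validation helpers.
#' @export
train_embedder <- function(cohort, config, validation = NULL,
                           row_ids = NULL, audit = NULL) {
  stopifnot(inherits(cohort, "labeled_cohort"), inherits(config, "network_config"))
  X <- cohort$features$values
  y <- cohort$labels
  if (anyNA(X) || !all(is.finite(X))) {
    abort("Features must be finite; run preprocess_features() first.")
  }
  if (min(X) < -1e-12 || max(X) > 1 + 1e-12) {
    abort("Features must lie in [0,1]; run preprocess_features() first.")
  }
  if (length(unique(y)) < 2) abort("Training needs records of both classes.")
  row_ids <- row_ids %||% seq_len(nrow(X))

  withr::with_seed(config$seed, {
    n <- nrow(X); d <- ncol(X)
    if (is.null(validation)) {
      val_idx <- stratified_holdout(y, config$val_fraction)
      Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]
      tr_idx <- setdiff(seq_len(n), val_idx)
    } else {
      Xv <- validation$features$values; yv <- validation$labels
      val_idx <- integer(0)
      tr_idx <- seq_len(n)
    }
    if (!is.null(audit)) {
      audit$train_rows <- c(audit$train_rows, row_ids[tr_idx])
      audit$early_stop_rows <- c(audit$early_stop_rows,
                                 if (length(val_idx)) row_ids[val_idx])
    }
    Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
    nt <- nrow(Xt)

    params <- init_embedder_params(config, d)
    cache <- zero_like(params)
    best <- list(objective = Inf, epoch = 0L, params = params)
    hist <- vector("list", config$max_epochs)

    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(nt)
      starts <- seq(1L, nt, by = config$batch_size)
      comp <- c(total = 0, classification = 0, reconstruction = 0, l1 = 0)
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, nt)]
        Xb <- Xt[idx, , drop = FALSE]
        cb <- corrupt_batch(Xb, config$corruption_rate)
        bg <- joint_grad(params, config, cb$corrupted, yt[idx], x_clean = Xb)
        if (!is.finite(bg$loss$total)) {
          abort(paste0("Divergence: non-finite loss at epoch ", epoch, "."))
        }
        upd <- rmsprop_update(params, bg$grads, cache, config)
        params <- upd$p; cache <- upd$c
        comp <- comp + unlist(bg$loss) * length(idx)
      }
      comp <- comp / nt
      vl <- joint_loss(params, config, Xv, yv)
      if (!is.finite(vl$total)) {
        abort(paste0("Divergence: non-finite validation loss at epoch ", epoch, "."))
      }
      hist[[epoch]] <- c(epoch = epoch, comp, val_objective = vl$total)
      if (vl$total < best$objective) {
        best <- list(objective = vl$total, epoch = epoch, params = params)
      }
      if (epoch - best$epoch >= config$patience) break
    }
    history <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
    names(history) <- c("epoch", "train_total", "train_classification",
                        "train_reconstruction", "train_l1", "val_objective")
    structure(list(params = best$params, config = config, history = history,
                   best_epoch = best$epoch, d = d,
                   feature_names = colnames(X),
                   preprocessing = NULL),
              class = "trained_embedder")
  })
}

# Stratified holdout of about `fraction` of the indices, at least one per
# class, used as the early-stopping monitor set.
stratified_holdout <- function(y, fraction) {
  idx <- integer(0)
  for (cls in unique(y)) {
    members <- which(y == cls)
    k <- max(1L, round(fraction * length(members)))
    k <- min(k, length(members) - 1L)
    idx <- c(idx, sample(members, k))
  }
  sort(idx)
}

#' @export
print.trained_embedder <- function(x, ...) {
  cfg <- x$config
  cat("<trained_embedder> mapping=", cfg$mapping, " depth=", cfg$depth,
      " width=", cfg$width, " lambda=", cfg$lambda,
      if (cfg$bypass) " +bypass" else "", "\n", sep = "")
  cat("  input d=", x$d, "; best epoch ", x$best_epoch, "/",
      nrow(x$history), " (val objective ",
      signif(min(x$history$val_objective), 5), ")\n", sep = "")
  invisible(x)
}

resolve_features <- function(features) {
  if (inherits(features, "labeled_cohort")) features <- features$features
  if (inherits(features, "feature_table")) return(features$values)
  as.matrix(features)
}

#' Positive-class probabilities from a trained model
#'
#' Runs the network without corruption and returns the softmax positive-class
#' coordinate per record.
#'
#' @param model A `trained_embedder`.
#' @param features A `feature_table`, `labeled_cohort`, matrix or data frame
#'   with the training dimensionality.
#' @return Numeric vector of probabilities in [0,1].
#' @export
predict_proba <- function(model, features) {
  X <- resolve_features(features)
  if (ncol(X) != model$d) {
    abort(paste0("Feature dimensionality ", ncol(X),
                 " does not match the trained model (", model$d, ")."))
  }
  fwd <- forward_pass(model$params, model$config, X)
  unname(fwd$P[, 2])
}

#' @export
predict.trained_embedder <- function(object, newdata, ...) {
  predict_proba(object, newdata)
}

#' Embed records into the learned low-dimensional space
#'
#' Applies the encoder (no corruption) and returns the `n x m` embedding.
#'
#' @inheritParams predict_proba
#' @return Numeric matrix with `width` columns.
#' @export
embed_cohort <- function(model, features) {
  X <- resolve_features(features)
  if (ncol(X) != model$d) {
    abort(paste0("Feature dimensionality ", ncol(X),
                 " does not match the trained model (", model$d, ")."))
  }
  fwd <- forward_pass(model$params, model$config, X)
  H <- fwd$H
  colnames(H) <- paste0("e", seq_len(ncol(H)))
  H
}

#' Decode records through the full autoencoder
#'
#' Encoder then decoder, no corruption; errors for a baseline model (which
#' has no decoder).
#'
#' @inheritParams predict_proba
#' @return Numeric `n x d` matrix of decoded records.
#' @export
decode_cohort <- function(model, features) {
  if (is.null(model$params$dec)) abort("This model has no decoder (baseline).")
  X <- resolve_features(features)
  fwd <- forward_pass(model$params, model$config, X)
  fwd$Xhat
}

embedder_container_version <- "riskembed-model-1"

#' Serialize / restore a trained model
#'
#' Writes the named parameter arrays, configuration, preprocessing statistics
#' and training history as versioned JSON; reading fails loudly when the
#' container version does not match.
#'
#' @param model A `trained_embedder`.
#' @param path File path.
#' @return `path` (write) or the restored `trained_embedder` (read).
#' @export
write_embedder <- function(model, path) {
  obj <- list(version = embedder_container_version,
              config = unclass(model$config),
              d = model$d, best_epoch = model$best_epoch,
              feature_names = model$feature_names,
              params = model$params,
              preprocessing = model$preprocessing,
              history = as.data.frame(model$history))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' @rdname write_embedder
#' @export
read_embedder <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  if (!identical(obj$version, embedder_container_version)) {
    abort(paste0("Unsupported model container version: ",
                 obj$version %||% "<missing>"))
  }
  cfg <- obj$config
  config <- network_config(depth = cfg$depth, width = cfg$width,
                           lambda = cfg$lambda, l1_weight = cfg$l1_weight,
                           bypass = cfg$bypass, mapping = cfg$mapping,
                           corruption_rate = cfg$corruption_rate,
                           max_epochs = cfg$max_epochs, patience = cfg$patience,
                           batch_size = cfg$batch_size,
                           learning_rate = cfg$learning_rate,
                           rmsprop_decay = cfg$rmsprop_decay,
                           rmsprop_eps = cfg$rmsprop_eps,
                           val_fraction = cfg$val_fraction,
                           class_weight = cfg$class_weight, seed = cfg$seed)
  fix_layer <- function(l) {
    l$W <- as.matrix(l$W); l$b <- as.numeric(l$b)
    if (!is.null(l$a)) l$a <- as.numeric(l$a)
    l
  }
  params <- list(enc = lapply(obj$params$enc, fix_layer),
                 dec = if (!is.null(obj$params$dec))
                   lapply(obj$params$dec, fix_layer),
                 cls = fix_layer(obj$params$cls))
  structure(list(params = params, config = config,
                 history = tibble::as_tibble(obj$history),
                 best_epoch = obj$best_epoch, d = obj$d,
                 feature_names = obj$feature_names,
                 preprocessing = obj$preprocessing),
            class = "trained_embedder")
}
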