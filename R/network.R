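#' Configure a supervised embedding network
#'
#' One configuration object covers the whole model family: a denoising
#' encoder (`depth` PReLU hidden layers of `width` units, then a `width`-unit
#' embedding), a mirrored decoder with linear output, and a softmax classifier
#' head on the embedding (optionally concatenated with the input when
#' `bypass = TRUE`). The training objective is
#'
#'   `class_weight * L_c + lambda * L_recon + l1_weight * mean|embedding|`
#'
#' where `L_c` is categorical cross-entropy and `L_recon` is the mean squared
#' reconstruction error against a mapping-dependent target:
#'
#' * `"semi"` — identity target (reconstruction as a regularizer);
#' * `"sym"` — symmetry mapping: the target is `x` for positives, `-x` for
#'   negatives, pushing the classes to opposite half-spaces;
#' * `"zero"` — zero mapping: the target is `x` for positives and the zero
#'   vector for negatives, so healthy records decode toward the origin
#'   (absence of risk patterns);
#' * `"unsupervised"` — identity target with `class_weight = 0`: a pure
#'   denoising autoencoder whose embedding never sees the labels;
#' * `"baseline"` — no decoder, `lambda = 0`: a plain feed-forward softmax
#'   classifier with the same corruption, activations and optimizer.
#'
#' @param depth Hidden layers per branch (`>= 1` for trained models; `0` is
#'   accepted and yields a single-layer encoder, useful for closed-form
#'   analyses).
#' @param width Units per hidden layer; also the embedding size `m`. Must stay
#'   below the input dimensionality for a genuine bottleneck when
#'   `bypass = FALSE`.
#' @param lambda Non-negative reconstruction trade-off weight.
#' @param l1_weight Non-negative sparsity penalty on the mean absolute
#'   embedding activation (default `1e-4`).
#' @param bypass Concatenate the (corrupted) input with the embedding as
#'   classifier input.
#' @param mapping One of `"semi"`, `"sym"`, `"zero"`, `"unsupervised"`,
#'   `"baseline"`.
#' @param corruption_rate Probability in [0,1] that a training record has one
#'   uniformly chosen feature zeroed (at most one per record).
#' @param max_epochs,patience Epoch cap (default 500) and early-stopping
#'   patience in epochs without validation improvement (default 100).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate,rmsprop_decay,rmsprop_eps RMSProp step size, squared-
#'   gradient decay and numerical floor.
#' @param val_fraction Fraction of the training records held out (stratified)
#'   to monitor the early-stopping objective when no validation cohort is
#'   supplied.
#' @param class_weight Weight on the classification loss; defaults to 0 for
#'   `"unsupervised"` and 1 otherwise.
#' @param seed Integer seed controlling initialization, batching and
#'   corruption.
#' @return A `network_config` list.
#' @export
network_config <- function(depth = 1, width = 10, lambda = 0.1,
                           l1_weight = 1e-4, bypass = FALSE,
                           mapping = c("semi", "sym", "zero",
                                       "unsupervised", "baseline"),
                           corruption_rate = 0.5,
                           max_epochs = 500, patience = 100, batch_size = 32,
                           learning_rate = 1e-3, rmsprop_decay = 0.9,
                           rmsprop_eps = 1e-8, val_fraction = 0.1,
                           class_weight = NULL, seed = 1L) {
  mapping <- match.arg(mapping)
  if (depth < 0 || width < 1) abort("depth must be >= 0 and width >= 1.")
  if (lambda < 0) abort("lambda must be non-negative.")
  if (l1_weight < 0) abort("l1_weight must be non-negative.")
  if (corruption_rate < 0 || corruption_rate > 1) {
    abort("corruption_rate must be in [0,1].")
  }
  if (mapping == "baseline") lambda <- 0
  if (is.null(class_weight)) {
    class_weight <- if (mapping == "unsupervised") 0 else 1
  }
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 lambda = lambda, l1_weight = l1_weight, bypass = bypass,
                 mapping = mapping, corruption_rate = corruption_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 rmsprop_decay = rmsprop_decay, rmsprop_eps = rmsprop_eps,
                 val_fraction = val_fraction, class_weight = class_weight,
                 seed = as.integer(seed)),
            class = "network_config")
}

has_decoder <- function(config) config$mapping != "baseline"

prelu <- function(Z, a) pmax(Z, 0) + a * pmin(Z, 0)
dprelu <- function(Z, a) (Z > 0) + a * (Z <= 0)

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# He-style variance-scaled initialization; PReLU slopes start at 0.25.
init_embedder_params <- function(config, d) {
  if (!config$bypass && config$width >= d) {
    abort(paste0("width (", config$width, ") must be below the input ",
                 "dimensionality (", d, ") for a bottleneck without bypass."))
  }
  layer <- function(din, dout, slope = TRUE) {
    l <- list(W = matrix(rnorm(din * dout, sd = sqrt(2 / din)), din, dout),
              b = rep(0, dout))
    if (slope) l$a <- 0.25
    l
  }
  enc_in <- c(d, rep(config$width, config$depth))
  enc <- lapply(seq_len(config$depth + 1L),
                function(i) layer(enc_in[i], config$width))
  dec <- NULL
  if (has_decoder(config)) {
    dec <- c(lapply(seq_len(config$depth),
                    function(i) layer(config$width, config$width)),
             list(layer(config$width, d, slope = FALSE)))
  }
  cls_in <- config$width + if (config$bypass) d else 0L
  list(enc = enc, dec = dec, cls = layer(cls_in, 2L, slope = FALSE))
}

# Forward pass; X is n x d with rows as records. Returns all intermediates
# needed by backprop. Corruption is applied by the caller (training loop),
# never here, so inference is deterministic.
forward_pass <- function(params, config, X) {
  n <- nrow(X)
  A <- X
  enc_Z <- vector("list", length(params$enc))
  enc_A <- vector("list", length(params$enc))
  for (i in seq_along(params$enc)) {
    l <- params$enc[[i]]
    Z <- A %*% l$W + matrix(l$b, n, length(l$b), byrow = TRUE)
    A <- prelu(Z, l$a)
    enc_Z[[i]] <- Z; enc_A[[i]] <- A
  }
  H <- A
  dec_Z <- NULL; dec_A <- NULL; Xhat <- NULL
  if (!is.null(params$dec)) {
    nd <- length(params$dec)
    dec_Z <- vector("list", nd); dec_A <- vector("list", nd)
    B <- H
    for (j in seq_len(nd)) {
      l <- params$dec[[j]]
      Z <- B %*% l$W + matrix(l$b, n, length(l$b), byrow = TRUE)
      B <- if (j < nd) prelu(Z, l$a) else Z  # linear output layer
      dec_Z[[j]] <- Z; dec_A[[j]] <- B
    }
    Xhat <- B
  }
  U <- if (config$bypass) cbind(H, X) else H
  S <- U %*% params$cls$W + matrix(params$cls$b, n, 2, byrow = TRUE)
  P <- softmax_rows(S)
  list(X = X, enc_Z = enc_Z, enc_A = enc_A, H = H,
       dec_Z = dec_Z, dec_A = dec_A, Xhat = Xhat, U = U, S = S, P = P)
}

#' Corrupt a batch by dropping at most one feature per record
#'
#' The denoising corruption: independently for each record, with probability
#' `rate` one uniformly chosen feature is set to zero; otherwise the record is
#' untouched. A corrupted record therefore never differs from its original in
#' more than one coordinate. Uses the current RNG state (seed it with
#' `withr::with_seed()` for reproducibility).
#'
#' @param batch Numeric matrix, records in rows.
#' @param rate Probability in [0,1].
#' @return List with `original`, `corrupted`, and `dropped_index` (per-record
#'   feature index, `NA` where untouched).
#' @export
corrupt_batch <- function(batch, rate) {
  if (rate < 0 || rate > 1) abort("rate must be in [0,1].")
  n <- nrow(batch); d <- ncol(batch)
  dropped <- rep(NA_integer_, n)
  if (rate > 0 && n > 0) {
    hit <- runif(n) < rate
    if (any(hit)) {
      dropped[hit] <- sample.int(d, sum(hit), replace = TRUE)
      corrupted <- batch
      corrupted[cbind(which(hit), dropped[hit])] <- 0
      return(list(original = batch, corrupted = corrupted,
                  dropped_index = dropped))
    }
  }
  list(original = batch, corrupted = batch, dropped_index = dropped)
}

#' Label-dependent reconstruction targets
#'
#' `sym_map()` returns `x` for positives and `-x` for negatives (elementwise
#' negation), placing the two classes in opposite half-spaces of the decoded
#' space. `zero_map()` returns `x` for positives and the zero vector for
#' negatives, so a healthy record decodes to "no risk patterns at all".
#'
#' @param x Numeric vector or matrix (records in rows).
#' @param y Binary label(s); a scalar or one per row.
#' @return The mapped target, same shape as `x`.
#' @export
sym_map <- function(x, y) {
  s <- ifelse(as.numeric(y) == 1, 1, -1)
  if (is.matrix(x)) x * s else x * s[1]
}

#' @rdname sym_map
#' @export
zero_map <- function(x, y) {
  s <- as.numeric(as.numeric(y) == 1)
  if (is.matrix(x)) x * s else x * s[1]
}

mapping_target <- function(X, y, mapping) {
  switch(mapping,
         semi = X, unsupervised = X,
         sym = sym_map(X, y),
         zero = zero_map(X, y),
         baseline = NULL)
}

#' Mean summed-squared reconstruction error
#'
#' The reconstruction loss: the mean over records of the summed squared
#' coordinate errors between the decoded output and its target (the record
#' itself, or a label-dependent mapping of it).
#'
#' @param decoded,target Numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(decoded, target) {
  if (!identical(dim(decoded), dim(target))) abort("Shape mismatch.")
  sum((decoded - target)^2) / nrow(decoded)
}

#' Mean categorical cross-entropy
#'
#' @param predicted Matrix of class-probability rows (negative, positive);
#'   each row must sum to 1 within `1e-6`.
#' @param y Binary labels (1 = positive).
#' @param eps Probability clipping floor (default `1e-7`).
#' @return Non-negative scalar.
#' @export
classification_loss <- function(predicted, y, eps = 1e-7) {
  if (any(abs(rowSums(predicted) - 1) > 1e-6)) {
    abort("Probability rows must sum to 1.")
  }
  p_true <- predicted[cbind(seq_len(nrow(predicted)), as.integer(y) + 1L)]
  -mean(log(pmin(pmax(p_true, eps), 1)))
}

#' Joint loss of the supervised embedding objective
#'
#' Evaluates `class_weight * L_c + lambda * L_recon + l1_weight * L1` on one
#' batch, returning the components separately for logging. `x_input` is what
#' the network sees (possibly corrupted during training); `x_clean` is the
#' basis of the reconstruction target, so denoising semantics (reconstruct
#' the clean record from its corrupted version) come for free.
#'
#' @param params Parameter list (as inside a fitted model, `$params`).
#' @param config A [network_config()].
#' @param x_input Input matrix fed to the network.
#' @param y Binary labels.
#' @param x_clean Clean records used to build the reconstruction target
#'   (defaults to `x_input`).
#' @return List with `total`, `classification`, `reconstruction`, `l1`.
#' @export
joint_loss <- function(params, config, x_input, y, x_clean = x_input) {
  fwd <- forward_pass(params, config, x_input)
  joint_loss_from_forward(fwd, config, y, x_clean)
}

joint_loss_from_forward <- function(fwd, config, y, x_clean) {
  L_c <- classification_loss(fwd$P, y)
  L_r <- 0
  if (!is.null(fwd$Xhat)) {
    target <- mapping_target(x_clean, y, config$mapping)
    L_r <- reconstruction_loss(fwd$Xhat, target)
  }
  L_1 <- mean(abs(fwd$H))
  list(total = config$class_weight * L_c + config$lambda * L_r +
         config$l1_weight * L_1,
       classification = L_c, reconstruction = L_r, l1 = L_1)
}

# Analytic gradient of the joint loss w.r.t. every parameter (weights,
# biases, PReLU slopes). Returns (loss components, gradient tree mirroring
# the parameter tree). Verified against central finite differences.
joint_grad <- function(params, config, x_input, y, x_clean = x_input) {
  n <- nrow(x_input)
  m <- config$width
  fwd <- forward_pass(params, config, x_input)
  loss <- joint_loss_from_forward(fwd, config, y, x_clean)

  grads <- list(enc = vector("list", length(params$enc)), dec = NULL,
                cls = list())
  # classifier head: softmax + cross-entropy
  Y1 <- cbind(1 - y, y)
  dS <- config$class_weight * (fwd$P - Y1) / n
  grads$cls$W <- t(fwd$U) %*% dS
  grads$cls$b <- colSums(dS)
  dU <- dS %*% t(params$cls$W)
  dH <- dU[, seq_len(m), drop = FALSE]

  # decoder branch
  if (!is.null(params$dec)) {
    nd <- length(params$dec)
    grads$dec <- vector("list", nd)
    target <- mapping_target(x_clean, y, config$mapping)
    dA <- (2 * config$lambda / n) * (fwd$Xhat - target)
    for (j in rev(seq_len(nd))) {
      l <- params$dec[[j]]
      ga <- NULL
      if (j < nd) {  # PReLU layer
        Z <- fwd$dec_Z[[j]]
        dZ <- dA * dprelu(Z, l$a)
        ga <- sum(dA * pmin(Z, 0))
      } else {       # linear output layer
        dZ <- dA
      }
      A_prev <- if (j > 1) fwd$dec_A[[j - 1]] else fwd$H
      # field order must mirror the parameter tree (W, b[, a])
      g <- list(W = t(A_prev) %*% dZ, b = colSums(dZ))
      if (!is.null(ga)) g$a <- ga
      grads$dec[[j]] <- g
      dA <- dZ %*% t(l$W)
    }
    dH <- dH + dA
  }

  # sparsity penalty on the embedding
  dH <- dH + config$l1_weight * sign(fwd$H) / (n * m)

  # encoder
  dA <- dH
  for (i in rev(seq_along(params$enc))) {
    l <- params$enc[[i]]
    Z <- fwd$enc_Z[[i]]
    dZ <- dA * dprelu(Z, l$a)
    ga <- sum(dA * pmin(Z, 0))
    A_prev <- if (i > 1) fwd$enc_A[[i - 1]] else x_input
    grads$enc[[i]] <- list(W = t(A_prev) %*% dZ, b = colSums(dZ), a = ga)
    dA <- dZ %*% t(l$W)
  }
  list(loss = loss, grads = grads)
}

# Flatten / restore the parameter tree; used by the finite-difference checks
# and by determinism comparisons.
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  i <- 0L
  walk <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.list(x)) return(lapply(x, walk))
    k <- length(x)
    out <- flat[(i + 1L):(i + k)]
    i <<- i + k
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  walk(skeleton)
}

# RMSProp update step over matching parameter/gradient/cache trees.
rmsprop_update <- function(params, grads, cache, config) {
  rho <- config$rmsprop_decay; lr <- config$learning_rate
  eps <- config$rmsprop_eps
  walk <- function(p, g, c) {
    if (is.list(p)) {
      out_p <- p; out_c <- c
      for (k in seq_along(p)) {
        if (is.null(p[[k]])) next
        r <- walk(p[[k]], g[[k]], c[[k]])
        out_p[[k]] <- r$p; out_c[[k]] <- r$c
      }
      return(list(p = out_p, c = out_c))
    }
    c2 <- rho * c + (1 - rho) * g^2
    list(p = p - lr * g / (sqrt(c2) + eps), c = c2)
  }
  walk(params, grads, cache)
}

zero_like <- function(params) {
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    x * 0
  }
  walk(params)
}
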