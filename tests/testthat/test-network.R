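test_that("corruption drops at most one feature per record and respects the rate", {
  X <- matrix(runif(200 * 6), 200, 6)
  withr::with_seed(1, {
    cb <- corrupt_batch(X, 0)
    expect_identical(cb$corrupted, X)
    expect_true(all(is.na(cb$dropped_index)))
    # rate 1, d = 1: every row becomes 0
    X1 <- matrix(runif(50), 50, 1)
    cb1 <- corrupt_batch(X1, 1)
    expect_true(all(cb1$corrupted == 0))
    # any rate: per-row Hamming distance <= 1
    cb2 <- corrupt_batch(X, 0.7)
    expect_true(all(rowSums(cb2$corrupted != X) <= 1))
    hit <- !is.na(cb2$dropped_index)
    expect_true(all(cb2$corrupted[cbind(which(hit), cb2$dropped_index[hit])] == 0))
  })
})

test_that("symmetry and zero mappings follow their definitions", {
  expect_equal(sym_map(c(0.2, 0.5), 1), c(0.2, 0.5))
  expect_equal(sym_map(c(0.2, 0.5), 0), c(-0.2, -0.5))
  expect_equal(sym_map(c(0, 0), 0), c(0, 0))
  expect_equal(zero_map(c(0.3, 0.7), 1), c(0.3, 0.7))
  expect_equal(zero_map(c(0.3, 0.7), 0), c(0, 0))
  expect_equal(zero_map(c(0, 0), 1), c(0, 0))
  # matrix forms map row-wise by label
  X <- matrix(1:6 / 10, 3, 2)
  y <- c(1, 0, 1)
  expect_equal(sym_map(X, y), X * c(1, -1, 1))
  expect_equal(zero_map(X, y), X * c(1, 0, 1))
})

test_that("reconstruction and classification losses match their closed forms", {
  expect_equal(reconstruction_loss(matrix(1:4, 2), matrix(1:4, 2)), 0)
  expect_equal(reconstruction_loss(matrix(c(0, 0), 1), matrix(c(1, 0), 1)), 1)
  # brute-force mean-of-row-sums oracle on a random batch
  set.seed(3)
  A <- matrix(rnorm(20), 5, 4); B <- matrix(rnorm(20), 5, 4)
  oracle <- mean(vapply(1:5, function(i) sum((A[i, ] - B[i, ])^2), 0))
  expect_equal(reconstruction_loss(A, B), oracle)
  expect_error(reconstruction_loss(A, B[, 1:3]), "mismatch")

  P <- matrix(0.5, 4, 2)
  expect_equal(classification_loss(P, c(0, 1, 1, 0)), log(2))
  Psure <- cbind(c(1, 0), c(0, 1))
  expect_lt(classification_loss(Psure, c(0, 1)), 1e-6)
  set.seed(4)
  p1 <- runif(10, 0.05, 0.95)
  Pr <- cbind(1 - p1, p1); yr <- rbinom(10, 1, 0.5)
  oracle <- -mean(log(ifelse(yr == 1, p1, 1 - p1)))
  expect_equal(classification_loss(Pr, yr), oracle)
  expect_error(classification_loss(cbind(p1, p1), yr), "sum to 1")
})

test_that("joint loss decomposes additively and degenerates to the classification loss", {
  set.seed(5)
  d <- 7; n <- 12
  X <- matrix(runif(n * d), n, d)
  y <- rbinom(n, 1, 0.4); y[1] <- 1; y[2] <- 0
  cfg0 <- network_config(depth = 1, width = 4, lambda = 0, l1_weight = 0,
                         mapping = "semi", seed = 2)
  params <- withr::with_seed(2, riskembed:::init_embedder_params(cfg0, d))
  jl <- joint_loss(params, cfg0, X, y)
  fwd <- riskembed:::forward_pass(params, cfg0, X)
  expect_equal(jl$total, classification_loss(fwd$P, y))
  # lambda = 1: joint equals L_c + L_r computed by separate calls
  cfg1 <- network_config(depth = 1, width = 4, lambda = 1, l1_weight = 0,
                         mapping = "semi", seed = 2)
  jl1 <- joint_loss(params, cfg1, X, y)
  expect_equal(jl1$total,
               classification_loss(fwd$P, y) + reconstruction_loss(fwd$Xhat, X))
  # full decomposition to machine precision, including the L1 term
  cfg2 <- network_config(depth = 1, width = 4, lambda = 0.3, l1_weight = 0.01,
                         mapping = "zero", seed = 2)
  jl2 <- joint_loss(params, cfg2, X, y)
  expect_identical(jl2$total,
                   jl2$classification + 0.3 * jl2$reconstruction + 0.01 * jl2$l1)
  expect_equal(jl2$reconstruction,
               reconstruction_loss(fwd$Xhat, zero_map(X, y)))
  # with all-positive labels every mapping's target collapses to the identity
  yp <- rep(1L, n)
  for (mp in c("sym", "zero")) {
    cfgm <- network_config(depth = 1, width = 4, lambda = 1, l1_weight = 0,
                           mapping = mp, seed = 2)
    expect_equal(joint_loss(params, cfgm, X, yp)$reconstruction,
                 reconstruction_loss(fwd$Xhat, X))
  }
})

test_that("analytic gradients match central finite differences for every mapping", {
  set.seed(11)
  worst <- 0
  for (mp in c("semi", "sym", "zero", "unsupervised", "baseline")) {
    for (rep in 1:3) {
      d <- sample(4:8, 1)
      w <- sample(2:min(5, d - 1), 1)
      dep <- sample(0:2, 1)
      cfg <- network_config(depth = dep, width = w, lambda = runif(1, 0, 1),
                            l1_weight = 10^runif(1, -4, -2),
                            bypass = sample(c(TRUE, FALSE), 1), mapping = mp,
                            seed = 1)
      n <- 6
      X <- matrix(runif(n * d), n, d)
      y <- rbinom(n, 1, 0.5); y[1] <- 1; y[2] <- 0
      params <- withr::with_seed(rep, riskembed:::init_embedder_params(cfg, d))
      g <- riskembed:::joint_grad(params, cfg, X, y)
      flat <- riskembed:::flatten_params(params)
      gflat <- riskembed:::flatten_params(g$grads)
      h <- 1e-5
      num <- vapply(seq_along(flat), function(i) {
        up <- flat; up[i] <- up[i] + h
        dn <- flat; dn[i] <- dn[i] - h
        (joint_loss(riskembed:::unflatten_params(up, params), cfg, X, y)$total -
         joint_loss(riskembed:::unflatten_params(dn, params), cfg, X, y)$total) / (2 * h)
      }, 0)
      rel <- abs(num - gflat) / pmax(1e-6, abs(num) + abs(gflat))
      worst <- max(worst, max(rel))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("forward pass honors the bypass shape contract and is deterministic at inference", {
  d <- 30
  cfg <- network_config(depth = 1, width = 10, bypass = FALSE, seed = 1)
  params <- withr::with_seed(1, riskembed:::init_embedder_params(cfg, d))
  expect_equal(nrow(params$cls$W), 10)
  cfgb <- network_config(depth = 1, width = 10, bypass = TRUE, seed = 1)
  paramsb <- withr::with_seed(1, riskembed:::init_embedder_params(cfgb, d))
  expect_equal(nrow(paramsb$cls$W), 40)
  X <- matrix(runif(5 * d), 5, d)
  f1 <- riskembed:::forward_pass(paramsb, cfgb, X)
  f2 <- riskembed:::forward_pass(paramsb, cfgb, X)
  expect_identical(f1$P, f2$P)
  # a genuine bottleneck is enforced without bypass
  expect_error(riskembed:::init_embedder_params(
    network_config(depth = 1, width = 30, bypass = FALSE), d), "bottleneck")
})

test_that("training improves the objective, stops early and restores the best epoch", {
  co <- make_separable_cohort(n = 200, d = 10, margin = 0.5,
                              prevalence = 0.2, seed = 3)
  m <- train_embedder(co, fast_config("zero"))
  expect_lt(m$history$train_total[m$best_epoch], m$history$train_total[1])
  expect_equal(min(m$history$val_objective),
               m$history$val_objective[m$best_epoch])
  expect_lte(nrow(m$history), fast_config()$max_epochs)
  # single-class cohort errors
  bad <- co; bad$labels <- rep(0L, length(bad$labels))
  bad <- riskembed:::new_labeled_cohort(co$features, rep(0L, 200), "x")
  expect_error(train_embedder(bad, fast_config()), "both classes")
})

test_that("identical seeds give bit-identical trained parameters", {
  co <- make_separable_cohort(n = 150, d = 8, margin = 0.4,
                              prevalence = 0.2, seed = 6)
  cfg <- network_config(depth = 2, width = 4, lambda = 0.5, mapping = "sym",
                        max_epochs = 40, patience = 20, seed = 9)
  m1 <- train_embedder(co, cfg)
  m2 <- train_embedder(co, cfg)
  expect_identical(riskembed:::flatten_params(m1$params),
                   riskembed:::flatten_params(m2$params))
  expect_identical(m1$history, m2$history)
})

test_that("prediction and embedding obey their contracts on trained models", {
  co <- make_separable_cohort(n = 200, d = 10, margin = 0.5,
                              prevalence = 0.2, seed = 3)
  m <- train_embedder(co, fast_config("semi"))
  p <- predict_proba(m, co)
  expect_true(all(p >= 0 & p <= 1))
  fwd <- riskembed:::forward_pass(m$params, m$config, co$features$values)
  expect_equal(rowSums(fwd$P), rep(1, 200))
  # duplicated record -> identical probability
  X2 <- co$features$values[c(1, 1), ]
  expect_equal(predict_proba(m, X2)[1], predict_proba(m, X2)[2])
  # class-conditional mean probability higher for positives after training
  expect_gt(mean(p[co$labels == 1]), mean(p[co$labels == 0]))
  E <- embed_cohort(m, co)
  expect_equal(ncol(E), m$config$width)
  expect_equal(E[1, ], embed_cohort(m, co$features$values[1, , drop = FALSE])[1, ])
  expect_error(predict_proba(m, co$features$values[, 1:5]), "dimensionality")
})

test_that("a large L1 weight shrinks mean absolute embedding activation", {
  co <- make_separable_cohort(n = 200, d = 10, margin = 0.5,
                              prevalence = 0.2, seed = 8)
  m0 <- train_embedder(co, network_config(depth = 1, width = 5, lambda = 0.1,
                                          l1_weight = 0, max_epochs = 60,
                                          patience = 60, seed = 12))
  m1 <- train_embedder(co, network_config(depth = 1, width = 5, lambda = 0.1,
                                          l1_weight = 1, max_epochs = 60,
                                          patience = 60, seed = 12))
  expect_lt(mean(abs(embed_cohort(m1, co))), mean(abs(embed_cohort(m0, co))))
})

test_that("model serialization round-trips and rejects foreign containers", {
  co <- make_separable_cohort(n = 120, d = 8, margin = 0.4,
                              prevalence = 0.25, seed = 2)
  m <- train_embedder(co, network_config(depth = 1, width = 4, mapping = "zero",
                                         max_epochs = 20, patience = 10, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_embedder(m, path)
  m2 <- read_embedder(path)
  expect_equal(predict_proba(m2, co), predict_proba(m, co))
  expect_equal(riskembed:::flatten_params(m2$params),
               riskembed:::flatten_params(m$params))
  bad <- jsonlite::read_json(path)
  bad$version <- "riskembed-model-999"
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_embedder(path), "version")
})
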