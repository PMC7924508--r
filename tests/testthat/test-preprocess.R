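test_that("reading the questionnaire dialect records '?' as missing and rejects malformed cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Age,Partners,Smokes,STDdx,Biopsy",
               "20,2,0,none,0",
               "35,?,1,hpv,1",
               "50,5,?,other,1"), path)
  raw <- read_risk_csv(path, tiny_schema())
  expect_equal(nrow(raw), 3)
  expect_true(is.na(raw$Partners[2]))
  expect_true(is.na(raw$Smokes[3]))
  miss <- attr(raw, "missing")
  expect_identical(unname(miss[, "Partners"]), c(FALSE, TRUE, FALSE))
  expect_equal(raw$Biopsy, c(0, 1, 1))

  # empty data section under a valid header
  writeLines("Age,Partners,Smokes,STDdx,Biopsy", path)
  expect_equal(nrow(read_risk_csv(path, tiny_schema())), 0)

  # malformed numeric cell names row and column
  writeLines(c("Age,Partners,Smokes,STDdx,Biopsy",
               "abc,2,0,none,0"), path)
  expect_error(read_risk_csv(path, tiny_schema()), "Age.*row 1")

  # schema mismatch
  writeLines(c("Age,Smokes,STDdx,Biopsy", "20,0,none,0"), path)
  expect_error(read_risk_csv(path, tiny_schema()), "Partners")
})

test_that("encoding expands bool-crossed, categorical and plain columns in schema order", {
  ft <- encode_features(tiny_raw(), tiny_schema())
  expect_equal(ft$feature_names,
               c("Age", "Partners::answered", "Partners", "Smokes::answered",
                 "Smokes", "STDdx=none", "STDdx=hpv", "STDdx=other"))
  # refusal: answered flag 0 and value flagged missing
  expect_equal(unname(ft$values[, "Partners::answered"]), c(1, 0, 1, 1))
  expect_true(is.na(ft$values[2, "Partners"]))
  expect_true(ft$missing_mask[2, "Partners"])
  expect_false(ft$missing_mask[2, "Partners::answered"])
  # answered boolean keeps flag 1 and its value
  expect_equal(unname(ft$values[2, c("Smokes::answered", "Smokes")]), c(1, 1))
  # one-of-K: level 2 of 3 -> (0,1,0); missing cell -> all-zero block + mask
  expect_equal(unname(ft$values[2, 6:8]), c(0, 1, 0))
  expect_equal(unname(ft$values[4, 6:8]), c(0, 0, 0))
  expect_true(all(ft$missing_mask[4, 6:8]))
  expect_true(all(ft$answered_flags[c(2, 4)]))
  # level outside the declared set errors
  bad <- tiny_raw(); bad$STDdx[1] <- "unknown"
  expect_error(encode_features(bad, tiny_schema()), "outside the declared level set")
  # determinism
  expect_identical(encode_features(tiny_raw(), tiny_schema()),
                   encode_features(tiny_raw(), tiny_schema()))
})

test_that("mean imputation uses training statistics and refuses all-missing features", {
  ft <- encode_features(tiny_raw(), tiny_schema())
  imp <- impute_train_mean(ft)
  expect_false(anyNA(imp$table$values))
  # {2, 5, 1} observed -> mean 8/3 fills the refusal
  expect_equal(unname(imp$table$values[2, "Partners"]), mean(c(2, 5, 1)))
  expect_identical(imp$table$answered_flags, ft$answered_flags)
  # table with no missing entries: unchanged values, means still returned
  imp2 <- impute_train_mean(imp$table)
  expect_identical(imp2$table$values, imp$table$values)
  expect_true(all(is.finite(imp2$means)))
  # supplied means win over the table's own values (leakage avoidance)
  means <- imp$means
  means["Partners"] <- 0.4
  imp3 <- impute_train_mean(ft, means)
  expect_equal(unname(imp3$table$values[2, "Partners"]), 0.4)
  # a feature entirely missing in training mode errors with its name
  allmiss <- ft
  allmiss$values[, "Partners"] <- NA_real_
  expect_error(impute_train_mean(allmiss), "Partners")
})

test_that("unit-interval normalization scales, zeroes constants and clips test values", {
  # worked example: min 13, max 84, value 27 -> (27-13)/(84-13)
  X <- matrix(c(13, 84, 27, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("age", "const")))
  nt <- normalize_unit_interval(matrix_feature_table(X))
  expect_equal(unname(nt$table$values[3, "age"]), (27 - 13) / (84 - 13))
  expect_equal(round(unname(nt$table$values[3, "age"]), 3), 0.197)
  expect_equal(unname(nt$table$values[, "const"]), c(0, 0, 0))
  # test value above the training max clips to 1; the constant-feature rule
  # still sends the degenerate column to 0, keeping everything inside [0,1]
  Xte <- matrix(c(100, 7), ncol = 2, dimnames = list(NULL, c("age", "const")))
  te <- normalize_unit_interval(matrix_feature_table(Xte), bounds = nt$bounds)
  expect_equal(unname(te$table$values[1, ]), c(1, 0))
  expect_true(all(te$table$values >= 0 & te$table$values <= 1))
})

test_that("preprocessing invariants hold over randomized tables", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    raw <- tibble::tibble(
      Age = sample(13:84, n, replace = TRUE),
      Partners = ifelse(runif(n) < 0.2, NA, sample(0:10, n, replace = TRUE)),
      Smokes = ifelse(runif(n) < 0.2, NA, rbinom(n, 1, 0.3)),
      STDdx = ifelse(runif(n) < 0.1, NA,
                     sample(c("none", "hpv", "other"), n, replace = TRUE))
    )
    ft <- encode_features(raw, tiny_schema())
    pp <- preprocess_features(ft)
    expect_true(all(pp$table$values >= 0 & pp$table$values <= 1))
    # one-of-K blocks of non-missing rows sum to exactly 1
    block <- pp$table$values[, 6:8, drop = FALSE]
    nonmiss <- !ft$missing_mask[, 6]
    expect_true(all(rowSums(block[nonmiss, , drop = FALSE]) == 1))
    # training-statistic reuse is idempotent bit-for-bit
    again <- preprocess_features(ft, stats = pp$stats)
    expect_identical(again$table$values, pp$table$values)
  }
})

test_that("cohort assembly appends observed screening outcomes and blocks leakage", {
  ft <- preprocess_features(encode_features(tiny_raw(), tiny_schema()))$table
  d0 <- ft$d
  co0 <- assemble_cohort(ft, tiny_targets(), "Biopsy")
  expect_equal(co0$features$d, d0)
  expect_identical(co0$features$values[, seq_len(d0)], ft$values)
  co1 <- assemble_cohort(ft, tiny_targets(), "Biopsy", subset = "Schiller")
  expect_equal(co1$features$d, d0 + 1)
  co3 <- assemble_cohort(ft, tiny_targets(), "Biopsy",
                         subset = c("Cytology", "Hinselmann", "Schiller"))
  expect_equal(co3$features$d, d0 + 3)
  expect_equal(co3$labels, c(0L, 1L, 1L, 0L))
  expect_error(assemble_cohort(ft, tiny_targets(), "Biopsy", subset = "Biopsy"),
               "leakage")
  tg <- tiny_targets(); tg$Schiller[1] <- NA
  expect_error(assemble_cohort(ft, tg, "Biopsy", subset = "Schiller"),
               "missing")
})
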