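# The six model-building strategies and uniform shrinkage.

test_that("null strategy is the plain OLS / ML fit", {
  dl <- fix_linear_exact()
  expect_equal(strategy_null(dl)$coefficients, fit_ols(dl)$coefficients)
  dg <- fix_2x2()
  f <- strategy_null(dg)
  expect_equal(unname(f$coefficients), LOG_OR_2x2, tolerance = 1e-8)
  expect_equal(f$shrinkage_applied, 1)
})

test_that("uniform shrinkage scales slopes and re-estimates the intercept", {
  d <- fix_oudega_small(n = 250, seed = 21)
  m <- fit_logistic_ml(d)

  # gamma = 1 reproduces the original model (ML score equation fixes b0)
  m1 <- apply_uniform_shrinkage(m, 1, d)
  expect_equal(m1$intercept, m$intercept, tolerance = 1e-6)
  expect_equal(m1$coefficients, m$coefficients)

  # gamma = 0: flat model at the prevalence
  m0 <- apply_uniform_shrinkage(m, 0, d)
  expect_true(all(m0$coefficients == 0))
  expect_equal(m0$intercept, qlogis(mean(d$y)), tolerance = 1e-6)

  # gamma = 0.5, one predictor: intercept equals the 1-D offset-ML solution
  d1 <- fix_2x2()
  f1 <- fit_logistic_ml(d1)
  s1 <- apply_uniform_shrinkage(f1, 0.5, d1)
  expect_equal(unname(s1$coefficients), 0.5 * unname(f1$coefficients))
  off <- 0.5 * unname(f1$coefficients) * d1$X[, 1]
  b0_oracle <- optimize(function(b0) {
    p <- plogis(b0 + off)
    -sum(d1$y * log(p) + (1 - d1$y) * log(1 - p))
  }, c(-10, 10), tol = 1e-10)$minimum
  expect_equal(s1$intercept, b0_oracle, tolerance = 1e-5)

  # linear family: intercept = mean(y) - gamma * beta . colMeans(X)
  dl <- fix_linear_random(n = 40, p = 3, seed = 3)
  fl <- fit_ols(dl)
  sl <- apply_uniform_shrinkage(fl, 0.7, dl)
  expect_equal(sl$intercept,
               mean(dl$y) - sum(0.7 * fl$coefficients * colMeans(dl$X)),
               tolerance = 1e-10)
})

test_that("heuristic gamma equals (chi2 - p)/chi2 with chi2 from the deviance drop", {
  d <- fix_oudega_small(n = 500, seed = 23)
  res <- strategy_heuristic(d)
  # independent chi2 oracle via stats::glm deviances
  df <- data.frame(y = d$y, d$X)
  g1 <- glm(y ~ ., binomial, df)
  chi2 <- g1$null.deviance - g1$deviance
  expect_equal(res$report$gamma, (chi2 - d$p) / chi2, tolerance = 1e-6)
  expect_lt(res$report$gamma, 1)
  expect_length(res$report$per_round_gammas, 1)

  # linear family: chi2 = n log(SSE0/SSE1)
  dl <- fix_linear_random(n = 60, p = 4, seed = 4)
  resl <- strategy_heuristic(dl)
  l1 <- lm(y ~ ., data.frame(y = dl$y, dl$X))
  chi2l <- dl$n * log(sum((dl$y - mean(dl$y))^2) / sum(resid(l1)^2))
  expect_equal(resl$report$gamma, (chi2l - dl$p) / chi2l, tolerance = 1e-8)
})

test_that("heuristic gamma is frequently non-positive on pure-noise data", {
  # with no true effects E[chi2] ~ p, so (chi2 - p)/chi2 straddles zero
  set.seed(41)
  gammas <- replicate(40, {
    d <- sc_data(rbinom(100, 1, 0.3), matrix(rbinom(800, 1, 0.5), 100, 8),
                 "logistic")
    tryCatch(strategy_heuristic(d)$report$gamma, error = function(e) NA)
  })
  expect_gt(mean(gammas <= 0, na.rm = TRUE), 0.25)   # recorded raw, not clipped
})

test_that("shrunken strategy models have slopes gamma * (full-data null slopes)", {
  d <- fix_oudega_small(n = 300, seed = 29)
  null_fit <- strategy_null(d)
  for (nm in c("split", "cv", "boot")) {
    res <- fit_strategy(d, strategy_spec(nm, split_rounds = 20,
                                         cv_replicates = 3, boot_rounds = 20),
                        seed = 7)
    expect_equal(res$model$coefficients, res$gamma * null_fit$coefficients,
                 tolerance = 1e-12, info = nm)
    expect_equal(res$model$shrinkage_applied, res$gamma)
    expect_equal(res$gamma, mean(res$report$per_round_gammas, na.rm = TRUE))
  }
})

test_that("strategies are seed-deterministic and converge over rounds", {
  d <- fix_oudega_small(n = 400, seed = 33)
  for (nm in c("split", "cv", "boot")) {
    s <- strategy_spec(nm, split_rounds = 30, cv_replicates = 4, boot_rounds = 30)
    g1 <- fit_strategy(d, s, seed = 11)$gamma
    g2 <- fit_strategy(d, s, seed = 11)$gamma
    expect_identical(g1, g2, info = nm)
  }
  # doubling round counts moves the mean gamma by < 0.01
  g_small <- fit_strategy(d, strategy_spec("boot", boot_rounds = 150), seed = 2)$gamma
  g_big <- fit_strategy(d, strategy_spec("boot", boot_rounds = 300), seed = 2)$gamma
  expect_lt(abs(g_small - g_big), 0.01)
})

test_that("single-round bootstrap gamma equals that round's calibration slope", {
  d <- fix_oudega_small(n = 300, seed = 37)
  res <- strategy_boot(d, strategy_spec("boot", boot_rounds = 1), seed = 99)
  set.seed(99)
  idx <- sample.int(d$n, d$n, replace = TRUE)
  f <- fit_logistic_ml(sc_data(d$y[idx], d$X[idx, ], "logistic"))
  manual <- calibration_slope(linear_predictor(f, d), d$y, "logistic")
  expect_equal(res$report$gamma, as.numeric(manual), tolerance = 1e-10)
})

test_that("degenerate rounds are counted and excluded, not fatal", {
  # tiny event count: 50-50 splits often leave a portion separated or empty
  y <- c(rep(1, 8), rep(0, 52))
  set.seed(3)
  d <- sc_data(y, matrix(rbinom(60, 1, 0.5)), "logistic")
  res <- strategy_split(d, strategy_spec("split", split_fraction = 0.5,
                                         split_rounds = 50), seed = 5)
  expect_gt(res$report$n_failed_rounds, 0)
  expect_lt(res$report$n_failed_rounds, 50)
  expect_true(is.finite(res$report$gamma))
})

test_that("shrinkage reflects overfitting: small for sparse data, none at scale", {
  # strong signal, large n: gamma in (0.9, 1]
  d_big <- fix_oudega_small(n = 2000, seed = 43)
  g_big <- strategy_split(d_big, strategy_spec("split", split_rounds = 40),
                          seed = 8)$report$gamma
  expect_gt(g_big, 0.9)
  expect_lte(g_big, 1.05)

  # sparse EPV ~ 4: visible shrinkage
  d_sparse <- subsample_epv(fix_oudega_small(n = 1295, seed = 47), 4, seed = 2)
  g_sparse <- strategy_split(d_sparse, strategy_spec("split", split_rounds = 60),
                             seed = 8)$report$gamma
  expect_lt(g_sparse, 0.97)
})

test_that("cross-validation runs at the leave-one-out boundary", {
  d <- fix_linear_random(n = 25, p = 2, seed = 13)
  res <- strategy_cv(d, strategy_spec("cv", k_folds = 25, cv_replicates = 1),
                     seed = 4)
  expect_true(is.finite(res$report$gamma))
})

test_that("Firth strategy delegates and refuses linear data", {
  d <- fix_separated()
  f <- strategy_firth(d)
  expect_true(all(is.finite(c(f$intercept, f$coefficients))))
  expect_error(strategy_firth(fix_linear_exact()), "unsupported strategy")
})
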