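# Synthetic-data generators: Cholesky linear data, DVT-like logistic data,
# EPV subsampling and predictor subsets by explained variance.

test_that("linear generator honors shapes and the correlation structure", {
  cfg <- linear_sim_config(n_sample = 200, n_population = 1000, p = 20,
                           r2_target = 0.5, seed = 1)
  g <- gen_linear_cholesky(cfg)
  expect_equal(dim(g$population$X), c(1000, 20))
  expect_equal(g$sample$n, 200)
  expect_equal(g$population$family, "linear")

  # identity correlation: off-diagonal sample correlations near zero at scale
  big <- gen_linear_cholesky(linear_sim_config(n_sample = 10, n_population = 50000,
                                               p = 5, seed = 2))
  cors <- cor(big$population$X)
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.02)

  # a requested correlation is realized
  R <- matrix(0.6, 3, 3); diag(R) <- 1
  gc <- gen_linear_cholesky(linear_sim_config(n_sample = 10, n_population = 50000,
                                              p = 3, correlation = R, seed = 3))
  expect_lt(max(abs(cor(gc$population$X) - R)), 0.02)

  bad <- matrix(1, 2, 2)
  expect_error(gen_linear_cholesky(
    linear_sim_config(n_sample = 10, n_population = 100, p = 2,
                      correlation = bad, seed = 1)), "positive definite")
})

test_that("linear generator hits the target R-squared", {
  for (r2 in c(0.1, 0.5, 0.9)) {
    g <- gen_linear_cholesky(linear_sim_config(n_sample = 100, n_population = 100000,
                                               p = 20, r2_target = r2, seed = 4))
    # plug the true beta into the variance decomposition at n = 1e5
    var_signal <- stats::var(drop(g$population$X %*% g$beta))
    r2_true <- var_signal / (var_signal + g$sigma^2)
    expect_lt(abs(r2_true - r2), 0.005)
    # empirical R2 of the OLS fit
    f <- fit_ols(g$population)
    r2_emp <- 1 - sse(f, g$population) / sum((g$population$y - mean(g$population$y))^2)
    expect_lt(abs(r2_emp - r2), 0.01)
  }
})

test_that("DVT-like generator calibrates prevalence and predictor types", {
  # null betas: prevalence purely from the calibrated intercept
  cfg0 <- logistic_sim_config(n = 200000, p_binary = 8, betas = rep(0, 8),
                              target_outcome_prevalence = 0.223, seed = 5)
  d0 <- gen_logistic_dvt_like(cfg0)
  expect_lt(abs(mean(d0$y) - 0.223), 3 * sqrt(0.223 * 0.777 / 200000) + 0.002)

  # Oudega-like: event count within 3 binomial SD of 289
  d <- gen_logistic_dvt_like(oudega_like_config(seed = 6))
  expect_equal(d$n, 1295)
  expect_equal(d$p, 8)
  expect_true(all(d$X %in% c(0, 1)))
  expect_lt(abs(n_events(d) - 289), 3 * sqrt(289 * (1 - 289 / 1295)) + 1)

  # Deepvein-like: mixed predictor types
  dv <- gen_logistic_dvt_like(deepvein_like_config(seed = 7))
  expect_equal(dv$n, 929)
  expect_true(all(dv$X[, 1:4] %in% c(0, 1)))
  expect_false(all(dv$X[, 5:8] %in% c(0, 1)))

  expect_error(gen_logistic_dvt_like(
    logistic_sim_config(n = 100, p_binary = 2, betas = c(50, 50),
                        target_outcome_prevalence = 0.01, seed = 1)),
    "unreachable")
})

test_that("generators are seed-deterministic", {
  a <- gen_logistic_dvt_like(oudega_like_config(n = 300, seed = 11))
  b <- gen_logistic_dvt_like(oudega_like_config(n = 300, seed = 11))
  expect_identical(a$y, b$y)
  expect_identical(a$X, b$X)
  g1 <- gen_linear_cholesky(linear_sim_config(n_sample = 50, seed = 12))
  g2 <- gen_linear_cholesky(linear_sim_config(n_sample = 50, seed = 12))
  expect_identical(g1$sample$y, g2$sample$y)
})

test_that("EPV subsampling hits exact event counts and preserves prevalence", {
  d <- gen_logistic_dvt_like(oudega_like_config(seed = 13))
  sub <- subsample_epv(d, 4, p_model = 8, seed = 14)
  expect_equal(n_events(sub), 32)
  expect_lt(abs(n_events(sub) / sub$n - n_events(d) / d$n), 0.01)

  # strict row subset: every subsampled row exists in the original
  key <- function(x) apply(cbind(x$y, x$X), 1, paste, collapse = "|")
  expect_true(all(key(sub) %in% key(d)))
  expect_lt(sub$n, d$n)

  expect_error(subsample_epv(d, 200, p_model = 8, seed = 1), "only")
})

test_that("predictor subsets land in their Nagelkerke R2 bins", {
  # pure-noise predictors: low-R2 bins fill quickly
  set.seed(15)
  d <- sc_data(rbinom(500, 1, 0.25), matrix(rbinom(500 * 12, 1, 0.5), 500, 12),
               "logistic")
  bins <- list(c(0, 0.05))
  res <- subset_predictors_by_r2(d, pool_size = 12, draw_size = 8,
                                 r2_bins = bins, max_draws = 50, seed = 16)
  expect_false(is.null(res[[1]]))
  expect_equal(res[[1]]$p, 8)
  r2 <- nagelkerke_r2(fit_logistic_ml(res[[1]]), res[[1]])
  expect_gt(r2, 0)
  expect_lte(r2, 0.05)
  expect_equal(r2, attr(res[[1]], "nagelkerke_r2"), tolerance = 1e-10)

  # an unreachable bin is reported empty with a warning
  expect_warning(
    res2 <- subset_predictors_by_r2(d, 12, 8, list(c(0.8, 0.9)),
                                    max_draws = 10, seed = 17),
    "not filled")
  expect_null(res2[[1]])
})
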