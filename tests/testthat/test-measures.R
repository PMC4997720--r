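# Performance measures: SSE, -2LL, Nagelkerke R2, Brier, calibration.

mk_model <- function(intercept, coefficients, family) {
  stratcomp:::new_sc_fit(intercept, coefficients, family)
}

test_that("sse matches direct arithmetic", {
  d <- sc_data(c(1, 2, 3), matrix(c(0, 0, 0)), "linear")
  m_perfect <- mk_model(0, c(x = 0), "linear")
  d_fit <- fix_linear_exact()
  expect_equal(sse(fit_ols(d_fit), d_fit), 0, tolerance = 1e-16)
  # constant prediction at 1: 0 + 1 + 4
  expect_equal(sse(mk_model(1, c(x = 0), "linear"), d), 5)
  # prediction at mean: total sum of squares
  expect_equal(sse(mk_model(2, c(x = 0), "linear"), d),
               sum((c(1, 2, 3) - 2)^2))
})

test_that("minus2_log_likelihood matches hand arithmetic and stays finite", {
  # hand fixture y = (1, 0), p = (0.8, 0.4): -2(log 0.8 + log 0.6)
  expect_equal(stratcomp:::m2ll_from_prob(c(1, 0), c(0.8, 0.4)),
               -2 * (log(0.8) + log(0.6)), tolerance = 1e-10)
  # same fixture duplicated to satisfy the n >= p + 2 data invariant
  d <- sc_data(c(1, 0, 1, 0), matrix(qlogis(c(0.8, 0.4, 0.8, 0.4))), "logistic")
  m <- mk_model(0, c(x = 1), "logistic")   # p = (0.8, 0.4, 0.8, 0.4)
  expect_equal(minus2_log_likelihood(m, d), 2 * -2 * (log(0.8) + log(0.6)),
               tolerance = 1e-10)

  # p = 0.5 everywhere: 2 n log 2
  n <- 64
  d5 <- sc_data(rep(c(0, 1), n / 2), matrix(rnorm(n)), "logistic")
  expect_equal(minus2_log_likelihood(mk_model(0, c(x = 0), "logistic"), d5),
               2 * n * log(2), tolerance = 1e-10)

  # perfect (clipped) probabilities: essentially zero, never infinite
  dperf <- sc_data(c(1, 0, 1, 0), matrix(c(1e4, -1e4, 1e4, -1e4)), "logistic")
  mperf <- mk_model(0, c(x = 1), "logistic")
  val <- minus2_log_likelihood(mperf, dperf)
  expect_true(is.finite(val))
  expect_lt(val, 1e-9)
})

test_that("-2LL and Brier are invariant to row permutation", {
  d <- fix_oudega_small(n = 150, seed = 5)
  m <- fit_logistic_ml(d)
  set.seed(8)
  perm <- sample(d$n)
  dp <- sc_data(d$y[perm], d$X[perm, ], "logistic")
  expect_identical(minus2_log_likelihood(m, d), minus2_log_likelihood(m, dp))
  expect_identical(brier_score(m, d), brier_score(m, dp))
})

test_that("Nagelkerke R2 follows its defining formula and bounds", {
  d <- fix_oudega_small(n = 300, seed = 9)
  m1 <- fit_logistic_ml(d)
  # direct evaluation of the formula from likelihoods computed in the test
  p1 <- plogis(m1$intercept + drop(d$X %*% m1$coefficients))
  l1 <- sum(d$y * log(p1) + (1 - d$y) * log(1 - p1))
  l0 <- sum(d$y * log(mean(d$y)) + (1 - d$y) * log(1 - mean(d$y)))
  oracle <- (1 - exp(2 * (l0 - l1) / d$n)) / (1 - exp(2 * l0 / d$n))
  expect_equal(nagelkerke_r2(m1, d), oracle, tolerance = 1e-10)
  expect_gte(nagelkerke_r2(m1, d), 0)
  expect_lte(nagelkerke_r2(m1, d), 1)

  # intercept-only model scores exactly zero
  d0 <- sc_data(d$y, NULL, "logistic")
  m0 <- fit_logistic_ml(d0)
  m0_on_d <- mk_model(m0$intercept, setNames(rep(0, d$p), d$names), "logistic")
  expect_equal(nagelkerke_r2(m0_on_d, d), 0, tolerance = 1e-10)

  # near-perfect discrimination
  dsep <- sc_data(c(rep(1, 30), rep(0, 30)),
                  matrix(c(rep(4, 30), rep(-4, 30))), "logistic")
  msep <- mk_model(0, c(x = 3), "logistic")
  expect_gt(nagelkerke_r2(msep, dsep), 0.99)
})

test_that("Brier score matches arithmetic and its bounds", {
  d <- sc_data(c(1, 0, 1, 0), matrix(qlogis(c(0.8, 0.4, 0.8, 0.4))), "logistic")
  m <- mk_model(0, c(x = 1), "logistic")
  expect_equal(brier_score(m, d), (0.04 + 0.16) / 2, tolerance = 1e-12)
  # constant 0.5 prediction: 0.25 regardless of outcome
  d5 <- sc_data(c(1, 1, 0, 0, 1, 0), matrix(rnorm(6)), "logistic")
  expect_equal(brier_score(mk_model(0, c(x = 0), "logistic"), d5), 0.25)
})

test_that("calibration slope recovers the generating slope at scale", {
  set.seed(77)
  n <- 50000
  lp <- rnorm(n, -1, 1.2)
  y <- rbinom(n, 1, plogis(lp))
  s1 <- calibration_slope(lp, y, "logistic")
  expect_lt(abs(s1 - 1), 0.05)
  s2 <- calibration_slope(2 * lp, y, "logistic")
  expect_lt(abs(s2 - 0.5), 0.03)
  expect_error(calibration_slope(rep(1, 10), rbinom(10, 1, 0.5), "logistic"),
               "constant")

  # linear family: closed-form least-squares slope
  yl <- 2 * lp[1:1000] + rnorm(1000)
  expect_equal(as.numeric(calibration_slope(lp[1:1000], yl, "linear")),
               unname(coef(lm(yl ~ lp[1:1000]))[2]), tolerance = 1e-10)
})

test_that("calibration deciles partition the data and track observed risk", {
  d <- fix_oudega_small(n = 10000, seed = 13)
  m <- fit_logistic_ml(d)
  tab <- calibration_deciles(m, d)
  expect_equal(sum(tab$count), d$n)
  expect_lt(max(abs(tab$mean_predicted - tab$observed_rate)), 0.05)

  # constant predictions collapse to a single group at the prevalence
  m0 <- mk_model(qlogis(mean(d$y)), setNames(rep(0, d$p), d$names), "logistic")
  expect_warning(tab0 <- calibration_deciles(m0, d), "distinct groups")
  expect_equal(nrow(tab0), 1L)
  expect_equal(tab0$observed_rate, mean(d$y))
  expect_equal(tab0$count, d$n)
})
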