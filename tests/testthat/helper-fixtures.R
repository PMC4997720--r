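# Fixtures built in code; all randomness under fixed seeds.

# 2x2 logistic design: x = 1 -> 30/50 events, x = 0 -> 10/50 events.
# ML coefficient equals the contingency-table log odds ratio.
fix_2x2 <- function() {
  y <- c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40))
  x <- c(rep(1, 50), rep(0, 50))
  sc_data(y, matrix(x, dimnames = list(NULL, "x")), "logistic")
}
LOG_OR_2x2 <- log((30 / 20) / (10 / 40))

# complete separation: x = 0 -> 10 non-events, x = 1 -> 10 events
fix_separated <- function() {
  sc_data(c(rep(0, 10), rep(1, 10)),
          matrix(c(rep(0, 10), rep(1, 10)), dimnames = list(NULL, "x")),
          "logistic")
}

# quasi-separation-prone: the two events in the x = 0 arm disappear from a
# sizeable share of bootstrap resamples, leaving quasi-separated samples
fix_quasi_separable <- function() {
  y <- c(1, 1, rep(0, 23), rep(1, 12), rep(0, 3))
  x <- c(rep(0, 25), rep(1, 15))
  sc_data(y, matrix(x, dimnames = list(NULL, "x")), "logistic")
}

# small noiseless linear fixture: y = 1 + 2 x1
fix_linear_exact <- function(n = 12) {
  x <- seq_len(n)
  sc_data(1 + 2 * x, matrix(x, dimnames = list(NULL, "x1")), "linear")
}

fix_linear_random <- function(n = 10, p = 2, seed = 31) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  sc_data(y, X, "linear")
}

fix_oudega_small <- function(n = 400, seed = 101) {
  gen_logistic_dvt_like(oudega_like_config(n = n, seed = seed))
}

# independent Firth oracle: direct numeric maximization of the penalized
# log-likelihood (never calls the package's IRLS path)
firth_oracle <- function(X, y, start = NULL) {
  Xi <- cbind(1, X)
  negpen <- function(beta) {
    eta <- drop(Xi %*% beta)
    p <- plogis(eta)
    ll <- sum(y * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
    info <- crossprod(Xi * sqrt(p * (1 - p)))
    -(ll + 0.5 * as.numeric(determinant(info, logarithm = TRUE)$modulus))
  }
  if (is.null(start)) start <- rep(0, ncol(Xi))
  optim(start, negpen, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))$par
}
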