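# Synthetic-data generators: fully simulated Gaussian data with a known
# population R^2 (via Cholesky-correlated standard-normal predictors), and
# logistic data emulating the structure of deep-vein-thrombosis diagnostic
# data sets (dichotomous clinical predictors, calibrated outcome prevalence).

#' Configuration for the Gaussian linear-regression generator
#'
#' Predictors are i.i.d. standard normal, correlated through the Cholesky
#' factor of `correlation`; the outcome is `X %*% beta + noise` with equal
#' coefficients across predictors and the noise variance solved so that the
#' generating model's R-squared equals `r2_target` exactly (signal variance
#' `r2_target`, noise variance `1 - r2_target`).
#'
#' @param n_sample Number of rows of the development sample drawn (without
#'   replacement) from the population.
#' @param n_population Number of rows of the generated population (default
#'   1000).
#' @param p Number of predictors (default 20).
#' @param r2_target Fraction of outcome variance explained by the generating
#'   model, in (0, 1).
#' @param correlation p x p positive-definite predictor correlation matrix;
#'   identity by default.
#' @param seed Integer seed.
#' @return A `linear_sim_config` list.
#' @export
linear_sim_config <- function(n_sample, n_population = 1000L, p = 20L,
                              r2_target = 0.5, correlation = NULL, seed = 1L) {
  stopifnot(r2_target > 0, r2_target < 1, p >= 1, n_sample <= n_population)
  if (is.null(correlation)) correlation <- diag(p)
  stopifnot(nrow(correlation) == p, ncol(correlation) == p)
  structure(list(n_sample = as.integer(n_sample),
                 n_population = as.integer(n_population),
                 p = as.integer(p), r2_target = r2_target,
                 correlation = correlation, seed = as.integer(seed)),
            class = "linear_sim_config")
}

#' Generate correlated Gaussian regression data with a known R-squared
#'
#' @param config A [linear_sim_config].
#' @return List with `population` and `sample` ([sc_data], linear family),
#'   `beta` (true slopes) and `sigma` (true noise SD).
#' @export
gen_linear_cholesky <- function(config) {
  stopifnot(inherits(config, "linear_sim_config"))
  U <- tryCatch(chol(config$correlation),
                error = function(e) stop("correlation matrix is not positive definite"))
  set.seed(config$seed)
  p <- config$p
  Z <- matrix(stats::rnorm(config$n_population * p), ncol = p)
  X <- Z %*% U                       # cov(X) = correlation
  # equal coefficients; var(X beta) = b^2 * sum(R) = r2_target, noise var 1 - r2
  b <- sqrt(config$r2_target / sum(config$correlation))
  beta <- rep(b, p)
  sigma <- sqrt(1 - config$r2_target)
  y <- drop(X %*% beta) + stats::rnorm(config$n_population, sd = sigma)
  population <- sc_data(y, X, "linear")
  idx <- sample.int(config$n_population, config$n_sample)
  list(population = population,
       sample = sc_data_rows(population, idx, allow_degenerate = FALSE),
       beta = beta, sigma = sigma)
}

#' Configuration for the DVT-like logistic generator
#'
#' Emulates the structure of diagnostic deep-vein-thrombosis data: dichotomous
#' clinical predictors (Bernoulli with configurable prevalences), optional
#' continuous predictors (standard normal), and a Bernoulli outcome from a
#' logistic model whose intercept is calibrated so the expected outcome
#' prevalence hits `target_outcome_prevalence`. Defaults emulate a development
#' set with 8 dichotomous predictors and prevalence 289/1295; only dimensions,
#' predictor types, effect sizes and prevalence are emulated - not any real
#' joint distribution.
#'
#' @param n Number of rows.
#' @param p_binary Number of dichotomous predictors (default 8).
#' @param p_continuous Number of standard-normal predictors (default 0).
#' @param predictor_prevalences Bernoulli probabilities for the dichotomous
#'   predictors (recycled to `p_binary`; default 0.5).
#' @param betas Log-odds-ratio vector for all predictors (binary first), of
#'   length `p_binary + p_continuous`; default `log(2)` for each, a typical
#'   moderate diagnostic effect.
#' @param target_outcome_prevalence Expected outcome prevalence (default
#'   289/1295).
#' @param seed Integer seed.
#' @return A `logistic_sim_config` list.
#' @export
logistic_sim_config <- function(n, p_binary = 8L, p_continuous = 0L,
                                predictor_prevalences = 0.5,
                                betas = NULL,
                                target_outcome_prevalence = 289 / 1295,
                                seed = 1L) {
  p <- p_binary + p_continuous
  stopifnot(p >= 0, n >= p + 2,
            target_outcome_prevalence > 0, target_outcome_prevalence < 1)
  predictor_prevalences <- rep_len(predictor_prevalences, p_binary)
  if (is.null(betas)) betas <- rep(log(2), p)
  stopifnot(length(betas) == p)
  structure(list(n = as.integer(n), p_binary = as.integer(p_binary),
                 p_continuous = as.integer(p_continuous),
                 predictor_prevalences = predictor_prevalences,
                 betas = betas,
                 target_outcome_prevalence = target_outcome_prevalence,
                 seed = as.integer(seed)),
            class = "logistic_sim_config")
}

#' Oudega-like and Deepvein-like convenience configurations
#'
#' `oudega_like_config` emulates a DVT development set: 1295 rows, 8
#' dichotomous predictors, expected 289 events. `deepvein_like_config`
#' emulates a cohort with a mix of continuous and dichotomous predictors: 929
#' rows, 4 dichotomous plus 4 continuous predictors.
#'
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [logistic_sim_config].
#' @return A `logistic_sim_config`.
#' @export
oudega_like_config <- function(n = 1295L, seed = 1L, ...) {
  logistic_sim_config(n = n, p_binary = 8L, p_continuous = 0L,
                      target_outcome_prevalence = 289 / 1295, seed = seed, ...)
}

#' @rdname oudega_like_config
#' @export
deepvein_like_config <- function(n = 929L, seed = 1L, ...) {
  logistic_sim_config(n = n, p_binary = 4L, p_continuous = 4L,
                      target_outcome_prevalence = 0.25, seed = seed, ...)
}

# calibrate the intercept by bisection on the expected prevalence, estimated
# on a fixed probe sample of predictor draws
calibrate_intercept <- function(config, probe_n = 1e5, tol = 0.002) {
  set.seed(child_seed(config$seed, 0L, 99L))
  Xp <- draw_predictors(config, probe_n)
  off <- if (length(config$betas)) drop(Xp %*% config$betas) else rep(0, probe_n)
  prev_at <- function(b0) mean(stats::plogis(b0 + off))
  lo <- -30; hi <- 30
  if (prev_at(lo) > config$target_outcome_prevalence ||
      prev_at(hi) < config$target_outcome_prevalence)
    stop("target prevalence unreachable with the given betas")
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    pv <- prev_at(mid)
    if (abs(pv - config$target_outcome_prevalence) < tol / 2) break
    if (pv < config$target_outcome_prevalence) lo <- mid else hi <- mid
  }
  mid
}

draw_predictors <- function(config, n) {
  p <- config$p_binary + config$p_continuous
  X <- matrix(0, nrow = n, ncol = p)
  for (j in seq_len(config$p_binary))
    X[, j] <- stats::rbinom(n, 1L, config$predictor_prevalences[j])
  for (j in seq_len(config$p_continuous))
    X[, config$p_binary + j] <- stats::rnorm(n)
  colnames(X) <- c(if (config$p_binary) paste0("b", seq_len(config$p_binary)),
                   if (config$p_continuous) paste0("z", seq_len(config$p_continuous)))
  X
}

#' Generate a DVT-like logistic data set
#'
#' @param config A [logistic_sim_config].
#' @return An [sc_data] with `family = "logistic"`. The calibrated intercept
#'   and the true coefficient vector are attached as attributes
#'   `"true_intercept"` and `"true_betas"`.
#' @examples
#' d <- gen_logistic_dvt_like(oudega_like_config(seed = 42))
#' d
#' @export
gen_logistic_dvt_like <- function(config) {
  stopifnot(inherits(config, "logistic_sim_config"))
  b0 <- calibrate_intercept(config)
  set.seed(config$seed)
  X <- draw_predictors(config, config$n)
  lp <- b0 + (if (length(config$betas)) drop(X %*% config$betas) else 0)
  y <- stats::rbinom(config$n, 1L, stats::plogis(lp))
  out <- sc_data(y, X, "logistic", allow_degenerate = TRUE)
  attr(out, "true_intercept") <- b0
  attr(out, "true_betas") <- config$betas
  out
}

#' Subsample a logistic data set to a target events-per-variable
#'
#' Removes cases and non-cases at random until the event count equals
#' `round(target_epv * p_model)`, keeping the outcome prevalence within 0.01
#' of the original (similar case-mix). The result is a strict row-subset of
#' the input.
#'
#' @param data A logistic [sc_data].
#' @param target_epv Target events per model variable; must not exceed the
#'   current EPV.
#' @param p_model Number of model variables (default `data$p`).
#' @param seed Integer seed.
#' @return An [sc_data] with exactly `round(target_epv * p_model)` events.
#' @export
subsample_epv <- function(data, target_epv, p_model = data$p, seed = 1L) {
  stopifnot(inherits(data, "sc_data"), data$family == "logistic")
  ev_target <- round(target_epv * p_model)
  ev_have <- n_events(data)
  if (ev_target > ev_have)
    stop("target EPV requires ", ev_target, " events but only ", ev_have,
         " are available")
  if (ev_target < 1) stop("target EPV leaves no events")
  prev <- ev_have / data$n
  n_new <- round(ev_target / prev)
  nonev_target <- n_new - ev_target
  nonev_have <- data$n - ev_have
  if (nonev_target > nonev_have) nonev_target <- nonev_have
  set.seed(seed)
  keep <- c(sample(which(data$y == 1), ev_target),
            sample(which(data$y == 0), nonev_target))
  out <- sc_data_rows(data, sort(keep), allow_degenerate = FALSE)
  if (abs(n_events(out) / out$n - prev) > 0.01)
    warning("subsampled prevalence deviates from the original by more than 0.01")
  out
}

#' Draw predictor subsets spanning a range of Nagelkerke R-squared values
#'
#' Repeatedly draws `draw_size` predictors from a pool of `pool_size`
#' predictors of `data`, fits a maximum-likelihood logistic model, computes
#' its Nagelkerke R-squared, and keeps one data set per requested R-squared
#' bin, until all bins are filled or the draw budget is exhausted.
#'
#' @param data A logistic [sc_data] with at least `pool_size` predictors.
#' @param pool_size Number of predictors forming the sampling pool (the first
#'   `pool_size` columns).
#' @param draw_size Number of predictors per drawn data set.
#' @param r2_bins List of length-2 numeric vectors `(lo, hi]`; one kept data
#'   set per bin.
#' @param max_draws Draw budget (default 500); unfilled bins are reported with
#'   a warning and returned as `NULL`.
#' @param seed Integer seed.
#' @return A list, one element per bin: `NULL` for an unfilled bin, otherwise
#'   an [sc_data] with `draw_size` predictors and attribute `"nagelkerke_r2"`.
#' @export
subset_predictors_by_r2 <- function(data, pool_size, draw_size, r2_bins,
                                    max_draws = 500L, seed = 1L) {
  stopifnot(inherits(data, "sc_data"), data$family == "logistic",
            pool_size <= data$p, draw_size <= pool_size)
  set.seed(seed)
  pool <- seq_len(pool_size)
  kept <- vector("list", length(r2_bins))
  for (draw in seq_len(max_draws)) {
    if (!any(vapply(kept, is.null, logical(1)))) break
    cols <- sample(pool, draw_size)
    d_sub <- sc_data(data$y, data$X[, cols, drop = FALSE], "logistic",
                     names = data$names[cols])
    fit <- tryCatch(fit_logistic_ml(d_sub), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    r2 <- nagelkerke_r2(fit, d_sub)
    for (b in seq_along(r2_bins)) {
      if (is.null(kept[[b]]) && r2 > r2_bins[[b]][1] && r2 <= r2_bins[[b]][2]) {
        attr(d_sub, "nagelkerke_r2") <- r2
        kept[[b]] <- d_sub
        break
      }
    }
  }
  unfilled <- which(vapply(kept, is.null, logical(1)))
  if (length(unfilled))
    warning("bins not filled within ", max_draws, " draws: ",
            paste(unfilled, collapse = ", "))
  kept
}
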