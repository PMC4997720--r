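# The six model-building strategies under comparison. Strategies 2-5 estimate
# a uniform shrinkage factor (the calibration slope of the model's linear
# predictor in data not used for fitting, or the closed-form heuristic), apply
# it to the full-data fit and re-estimate the intercept; Firth penalization
# shrinks during estimation instead.

#' Specify a model-building strategy
#'
#' Creates the parameter bundle consumed by [fit_strategy] and
#' [compare_strategies]. Defaults follow common practice for internal
#' validation: an 80/20 split repeated 100 times, 10-fold cross-validation
#' averaged over 10 replicates, and 100 bootstrap rounds.
#'
#' @param name One of `"null"` (plain OLS / ML fit, no shrinkage),
#'   `"heuristic"` (closed-form shrinkage from the model likelihood-ratio
#'   statistic), `"split"` (split-sample shrinkage), `"cv"` (k-fold
#'   cross-validation shrinkage), `"boot"` (bootstrap shrinkage) or `"firth"`
#'   (Firth-penalized logistic regression).
#' @param split_fraction Fraction of the data used for fitting in each
#'   split-sample round (default 0.8; the remaining 20\% estimates the slope).
#' @param split_rounds Number of random splits averaged over (default 100).
#' @param k_folds Number of cross-validation folds (default 10).
#' @param cv_replicates Number of repeated cross-validations averaged over
#'   (default 10).
#' @param boot_rounds Number of bootstrap rounds (default 100).
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(name = c("null", "heuristic", "split", "cv", "boot", "firth"),
                          split_fraction = 0.8, split_rounds = 100L,
                          k_folds = 10L, cv_replicates = 10L,
                          boot_rounds = 100L) {
  name <- match.arg(name)
  stopifnot(split_fraction > 0, split_fraction < 1,
            split_rounds >= 1, k_folds >= 2, cv_replicates >= 1, boot_rounds >= 1)
  structure(list(name = name, split_fraction = split_fraction,
                 split_rounds = as.integer(split_rounds),
                 k_folds = as.integer(k_folds),
                 cv_replicates = as.integer(cv_replicates),
                 boot_rounds = as.integer(boot_rounds)),
            class = "strategy_spec")
}

#' @export
print.strategy_spec <- function(x, ...) {
  extra <- switch(x$name,
    split = sprintf(" (fraction %.2f, %d rounds)", x$split_fraction, x$split_rounds),
    cv = sprintf(" (%d folds x %d replicates)", x$k_folds, x$cv_replicates),
    boot = sprintf(" (%d rounds)", x$boot_rounds),
    "")
  cat("<strategy_spec> ", x$name, extra, "\n", sep = "")
  invisible(x)
}

new_shrinkage_report <- function(per_round_gammas, n_failed = 0L) {
  ok <- per_round_gammas[is.finite(per_round_gammas)]
  structure(list(gamma = if (length(ok)) mean(ok) else NA_real_,
                 per_round_gammas = per_round_gammas,
                 n_failed_rounds = as.integer(n_failed)),
            class = "shrinkage_report")
}

#' @export
print.shrinkage_report <- function(x, ...) {
  cat("<shrinkage_report> gamma = ", signif(x$gamma, 4), " (",
      sum(is.finite(x$per_round_gammas)), " rounds, ",
      x$n_failed_rounds, " failed)\n", sep = "")
  invisible(x)
}

# ---- uniform shrinkage -----------------------------------------------------

#' Apply a uniform shrinkage factor and re-estimate the intercept
#'
#' Multiplies every slope coefficient by `gamma` and re-estimates the
#' intercept: for logistic models by maximum likelihood of an intercept-only
#' model with offset `gamma * X %*% beta` (so the mean predicted risk matches
#' the observed prevalence); for linear models by
#' `mean(y) - gamma * colMeans(X) %*% beta`.
#'
#' @param model An `sc_fit` fitted to `data`'s family.
#' @param gamma Shrinkage factor. Not restricted to \[0, 1\]: negative or
#'   above-one estimates are applied as-is (and are informative about the data).
#' @param data The [sc_data] object used to re-estimate the intercept.
#' @return A new `sc_fit` with `shrinkage_applied = gamma`.
#' @export
apply_uniform_shrinkage <- function(model, gamma, data) {
  stopifnot(inherits(model, "sc_fit"), inherits(data, "sc_data"))
  if (model$family != data$family) stop("model and data families differ")
  if (!is.finite(gamma)) stop("gamma must be finite")
  new_coef <- gamma * model$coefficients
  offset <- if (data$p > 0) drop(data$X %*% new_coef) else rep(0, data$n)
  if (data$family == "linear") {
    intercept <- mean(data$y) - mean(offset)
    fit_stat <- sum((data$y - intercept - offset)^2)
  } else {
    intercept <- offset_intercept_ml(data$y, offset)
    fit_stat <- m2ll_from_prob(data$y, stats::plogis(intercept + offset))
  }
  new_sc_fit(intercept, new_coef, data$family, shrinkage_applied = gamma,
             converged = model$converged, fit_stat = fit_stat,
             method = paste0(model$method, "+shrink"))
}

# 1-D Newton for the ML intercept of a logistic model with a fixed offset
offset_intercept_ml <- function(y, offset, tol = 1e-10, max_iter = 100L) {
  prev <- mean(y)
  prev <- min(max(prev, 1e-6), 1 - 1e-6)
  b0 <- stats::qlogis(prev) - mean(offset)
  for (i in seq_len(max_iter)) {
    prob <- stats::plogis(b0 + offset)
    g <- sum(y - prob)
    if (abs(g) < tol) break
    w <- sum(prob * (1 - prob))
    if (w <= 0) break
    step <- g / w
    b0 <- b0 + sign(step) * min(abs(step), 5)   # damped for stability
  }
  b0
}

# ---- individual strategies -------------------------------------------------

#' The null strategy: plain OLS or maximum-likelihood fit
#'
#' The common comparator: predictors prespecified, no shrinkage applied.
#'
#' @param data An [sc_data] object.
#' @return An `sc_fit` with `shrinkage_applied = 1`.
#' @export
strategy_null <- function(data) {
  if (data$family == "linear") fit_ols(data) else fit_logistic_ml(data)
}

#' Heuristic shrinkage (closed-form)
#'
#' Fits the null-strategy model and shrinks it by the closed-form factor
#' \deqn{\gamma = (\chi^2_{model} - p) / \chi^2_{model},}
#' where \eqn{\chi^2_{model}} is the model likelihood-ratio statistic (the drop
#' in -2 log-likelihood from the intercept-only to the full model; for linear
#' models computed from Gaussian likelihoods as `n * log(SSE0/SSE1)`) and p the
#' number of predictors. The factor is applied as-is, without clipping: in
#' noise-dominated data it can be zero or negative.
#'
#' @param data An [sc_data] object.
#' @return A list with elements `model` (shrunken `sc_fit`) and `report`
#'   (a `shrinkage_report` whose `per_round_gammas` has length 1).
#' @export
strategy_heuristic <- function(data) {
  model <- strategy_null(data)
  chi2 <- model_chi2(model, data)
  if (!is.finite(chi2) || chi2 == 0)
    stop("model likelihood-ratio statistic is zero: heuristic shrinkage undefined")
  gamma <- (chi2 - data$p) / chi2
  list(model = apply_uniform_shrinkage(model, gamma, data),
       report = new_shrinkage_report(gamma))
}

# model LR statistic: intercept-only vs full model
model_chi2 <- function(model, data) {
  if (data$family == "linear") {
    sse1 <- sse(model, data)
    sse0 <- sum((data$y - mean(data$y))^2)
    if (sse1 <= 0) return(Inf)
    data$n * log(sse0 / sse1)
  } else {
    m2ll_null(data$y) - minus2_log_likelihood(model, data)
  }
}

#' Split-sample shrinkage
#'
#' In each round the data are randomly split; a model is fitted to the fitting
#' portion (`split_fraction` of the rows) and the calibration slope of its
#' linear predictor in the held-out portion is recorded as that round's
#' shrinkage estimate. The final factor is the mean over successful rounds and
#' is applied to the full-data null fit. Rounds whose fit fails (a single
#' outcome class in a portion, separation, a degenerate slope) are counted in
#' `n_failed_rounds` and excluded.
#'
#' @param data An [sc_data] object.
#' @param spec A [strategy_spec]; `split_fraction` and `split_rounds` are used.
#' @param seed Optional integer seed for the strategy's internal resampling.
#' @return A list with `model` (shrunken full-data fit) and `report`.
#' @export
strategy_split <- function(data, spec = strategy_spec("split"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- data$n
  m <- round(spec$split_fraction * n)
  if (m < data$p + 2L || n - m < 2L)
    stop("split_fraction leaves too few observations for fitting or validation")
  Xi <- design_matrix(data)
  gammas <- rep(NA_real_, spec$split_rounds)
  for (r in seq_len(spec$split_rounds)) {
    idx <- sample.int(n, m)
    gammas[r] <- heldout_slope(Xi, data$y, data$family, fit_idx = idx,
                               eval_idx = setdiff(seq_len(n), idx))
  }
  finalize_shrinkage_strategy(data, gammas)
}

#' k-fold cross-validation shrinkage
#'
#' Per cross-validation replicate the rows are randomly partitioned into
#' `k_folds` folds; for each fold a model is fitted on the remaining folds and
#' its linear predictor computed on the held-out fold. The held-out linear
#' predictors are pooled across folds and a single calibration slope per
#' replicate is estimated from the pooled values (pooling is more stable than
#' averaging per-fold slopes from small folds). The final factor is the mean
#' over replicates, applied to the full-data null fit. A replicate with any
#' failed fold fit is counted as failed and excluded.
#'
#' @inheritParams strategy_split
#' @export
strategy_cv <- function(data, spec = strategy_spec("cv"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- data$n
  k <- spec$k_folds
  if (n < k) stop("need at least k_folds observations")
  Xi <- design_matrix(data)
  gammas <- rep(NA_real_, spec$cv_replicates)
  for (r in seq_len(spec$cv_replicates)) {
    fold <- sample(rep_len(seq_len(k), n))
    lp_pool <- rep(NA_real_, n)
    ok <- TRUE
    for (f in seq_len(k)) {
      hold <- which(fold == f)
      cf <- fit_coef_internal(Xi[-hold, , drop = FALSE], data$y[-hold], data$family)
      if (is.null(cf)) { ok <- FALSE; break }
      lp_pool[hold] <- drop(Xi[hold, , drop = FALSE] %*% cf)
    }
    if (ok)
      gammas[r] <- calibration_slope_or_na(lp_pool, data$y, data$family)
  }
  finalize_shrinkage_strategy(data, gammas)
}

#' Bootstrap shrinkage
#'
#' In each round a bootstrap sample (with replacement, size n) is drawn, a
#' model fitted to it, and the calibration slope of its linear predictor
#' evaluated in the original data is recorded. The final factor is the mean
#' over successful rounds, applied to the full-data null fit. Rounds with a
#' single-class bootstrap sample or a non-converged fit are counted and
#' excluded.
#'
#' @inheritParams strategy_split
#' @export
strategy_boot <- function(data, spec = strategy_spec("boot"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- data$n
  Xi <- design_matrix(data)
  gammas <- rep(NA_real_, spec$boot_rounds)
  for (r in seq_len(spec$boot_rounds)) {
    idx <- sample.int(n, n, replace = TRUE)
    gammas[r] <- heldout_slope(Xi, data$y, data$family, fit_idx = idx,
                               eval_idx = seq_len(n))
  }
  finalize_shrinkage_strategy(data, gammas)
}

#' Firth penalization as a strategy
#'
#' Returns the Firth-penalized logistic fit; shrinkage occurs during the
#' coefficient estimation itself, so no shrinkage factor or report exists for
#' this strategy.
#'
#' @param data An [sc_data] object with `family = "logistic"`.
#' @return An `sc_fit`.
#' @export
strategy_firth <- function(data) {
  if (data$family != "logistic")
    stop("unsupported strategy: Firth penalization is defined for logistic models only")
  fit_logistic_firth(data)
}

# ---- shared strategy internals ---------------------------------------------

# coefficients (with intercept) on a subset, or NULL on failure; logistic fits
# must pass the separation guard to count
fit_coef_internal <- function(Xi, y, family) {
  if (family == "linear") return(ols_coef(Xi, y))
  fit <- ml_coef(Xi, y)
  if (is.null(fit) || !fit$converged) return(NULL)
  fit$coef
}

# one validation round: fit on fit_idx rows, slope of the lp in eval_idx rows
heldout_slope <- function(Xi, y, family, fit_idx, eval_idx) {
  cf <- fit_coef_internal(Xi[fit_idx, , drop = FALSE], y[fit_idx], family)
  if (is.null(cf)) return(NA_real_)
  lp <- drop(Xi[eval_idx, , drop = FALSE] %*% cf)
  calibration_slope_or_na(lp, y[eval_idx], family)
}

finalize_shrinkage_strategy <- function(data, gammas) {
  report <- new_shrinkage_report(gammas, n_failed = sum(!is.finite(gammas)))
  if (!is.finite(report$gamma))
    stop("all shrinkage rounds failed for this data set")
  model <- strategy_null(data)
  list(model = apply_uniform_shrinkage(model, report$gamma, data),
       report = report)
}

#' Fit any strategy by its specification
#'
#' Uniform dispatcher used by the comparison loop: fits the strategy named in
#' `spec` to `data` and returns the fitted model together with its shrinkage
#' report (where one exists).
#'
#' @param data An [sc_data] object.
#' @param spec A [strategy_spec].
#' @param seed Optional integer seed for strategies with internal resampling
#'   (split, cv, boot); ignored by the deterministic strategies.
#' @return A list of class `sc_strategy_fit` with elements `model` (`sc_fit`),
#'   `report` (`shrinkage_report` or `NULL`), `gamma` (the applied factor, or
#'   `NA` for null/firth) and `spec`.
#' @export
fit_strategy <- function(data, spec, seed = NULL) {
  stopifnot(inherits(spec, "strategy_spec"))
  res <- switch(spec$name,
    null = list(model = strategy_null(data), report = NULL),
    heuristic = strategy_heuristic(data),
    split = strategy_split(data, spec, seed),
    cv = strategy_cv(data, spec, seed),
    boot = strategy_boot(data, spec, seed),
    firth = list(model = strategy_firth(data), report = NULL))
  structure(list(model = res$model, report = res$report,
                 gamma = if (is.null(res$report)) NA_real_ else res$report$gamma,
                 spec = spec),
            class = "sc_strategy_fit")
}
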