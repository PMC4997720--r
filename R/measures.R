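# Performance and fit measures shared by the comparison framework:
# SSE for linear models, -2 log-likelihood / Nagelkerke R2 / Brier score /
# calibration for logistic models.

#' Sum of squared prediction errors
#'
#' @param model A linear `sc_fit`.
#' @param data An [sc_data] object with `family = "linear"`.
#' @return `sum((y - yhat)^2)`.
#' @export
sse <- function(model, data) {
  if (model$family != "linear" || data$family != "linear")
    stop("sse requires a linear model and linear-family data")
  sum((data$y - linear_predictor(model, data))^2)
}

#' -2 log-likelihood of a logistic model in a data set
#'
#' Predicted probabilities are clipped to `[1e-12, 1 - 1e-12]` before the
#' log-likelihood is evaluated, so that models refit or shrunken in resamples
#' that predict 0/1 in the evaluation data still yield a finite value.
#'
#' @param model A logistic `sc_fit`.
#' @param data An [sc_data] object with `family = "logistic"`.
#' @return `-2 * sum(y log p + (1 - y) log(1 - p))`.
#' @export
minus2_log_likelihood <- function(model, data) {
  if (model$family != "logistic" || data$family != "logistic")
    stop("minus2_log_likelihood requires a logistic model and logistic-family data")
  m2ll_from_prob(data$y, predict_risk(model, data))
}

# -2LL of the intercept-only ML model: closed form at p = prevalence
m2ll_null <- function(y) {
  prev <- mean(y)
  m2ll_from_prob(y, rep(prev, length(y)))
}

#' Nagelkerke's R-squared
#'
#' Rescaled likelihood-based coefficient of determination,
#' \deqn{R^2_N = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}},}
#' where \eqn{L_0} is the likelihood of the intercept-only model fitted to the
#' same data and \eqn{L_1} the likelihood of `model`. Lies in \[0, 1\] for
#' maximum-likelihood fits.
#'
#' @inheritParams minus2_log_likelihood
#' @return A number in \[0, 1\] (ML fits); penalized or shrunken models can in
#'   principle fall slightly below the intercept-only likelihood.
#' @export
nagelkerke_r2 <- function(model, data) {
  if (model$family != "logistic" || data$family != "logistic")
    stop("nagelkerke_r2 requires a logistic model and logistic-family data")
  if (length(unique(data$y)) < 2L)
    stop("degenerate outcome: Nagelkerke R2 undefined with a single class")
  n <- data$n
  m0 <- m2ll_null(data$y)
  m1 <- minus2_log_likelihood(model, data)
  (1 - exp((m1 - m0) / n)) / (1 - exp(-m0 / n))
}

#' Brier score
#'
#' Mean squared difference between predicted probabilities and the observed
#' 0/1 outcomes; lower is better, 0 is perfect.
#'
#' @inheritParams minus2_log_likelihood
#' @return A number in \[0, 1\].
#' @export
brier_score <- function(model, data) {
  if (model$family != "logistic" || data$family != "logistic")
    stop("brier_score requires a logistic model and logistic-family data")
  mean((predict_risk(model, data) - data$y)^2)
}

#' Calibration slope of a linear predictor in validation data
#'
#' The slope from regressing the outcome on a model's linear predictor in data
#' not used for fitting: logistic regression for the logistic family, least
#' squares for the linear family. A slope below 1 indicates overfitting of the
#' model that produced the linear predictor; this slope is the shrinkage-factor
#' estimate of one validation round in the split-sample, cross-validation and
#' bootstrap strategies.
#'
#' @param lp Numeric vector of linear-predictor values (must not be constant).
#' @param y Outcome vector of the same length.
#' @param family `"linear"` or `"logistic"`.
#' @return The slope, with attribute `"converged"` (logistic only) indicating
#'   whether the slope fit itself met the score tolerance without diverging
#'   (separation in the validation data is flagged this way).
#' @export
calibration_slope <- function(lp, y, family = c("linear", "logistic")) {
  family <- match.arg(family)
  if (length(lp) != length(y)) stop("lp and y lengths differ")
  if (stats::sd(lp) == 0) stop("degenerate predictor: linear predictor is constant")
  if (family == "linear") {
    slope <- stats::cov(lp, y) / stats::var(lp)
    attr(slope, "converged") <- TRUE
    return(slope)
  }
  if (length(unique(y)) < 2L)
    stop("degenerate outcome: both classes required for a logistic calibration slope")
  fit <- ml_coef(cbind(1, lp), y)
  if (is.null(fit)) stop("calibration slope fit failed")
  slope <- unname(fit$coef[2L])
  attr(slope, "converged") <- fit$converged
  slope
}

# internal: slope or NA (never errors); used by the shrinkage strategies, where
# a failed round is counted and excluded rather than aborting the strategy
calibration_slope_or_na <- function(lp, y, family) {
  if (stats::sd(lp) == 0) return(NA_real_)
  if (family == "linear") return(stats::cov(lp, y) / stats::var(lp))
  if (length(unique(y)) < 2L) return(NA_real_)
  fit <- ml_coef(cbind(1, lp), y)
  if (is.null(fit) || !fit$converged) return(NA_real_)
  unname(fit$coef[2L])
}

#' Calibration table by deciles of predicted risk
#'
#' Groups observations into (up to) 10 groups by quantiles of predicted risk
#' and tabulates mean predicted risk against the observed event rate per group
#' - the table behind the usual calibration plot.
#'
#' @inheritParams minus2_log_likelihood
#' @param groups Number of risk groups (default 10).
#' @return A data frame with columns `decile`, `mean_predicted`, `observed_rate`,
#'   `count`; `sum(count) == n`. With heavy ties fewer than `groups` groups are
#'   formed and a warning is issued.
#' @export
calibration_deciles <- function(model, data, groups = 10L) {
  if (model$family != "logistic" || data$family != "logistic")
    stop("calibration_deciles requires a logistic model and logistic-family data")
  if (data$n < groups) stop("need at least ", groups, " observations")
  prob <- predict_risk(model, data)
  breaks <- unique(stats::quantile(prob, probs = seq(0, 1, length.out = groups + 1),
                                   type = 7, names = FALSE))
  if (length(breaks) < 2L) {            # constant predictions: one group
    g <- factor(rep(1L, data$n))
  } else {
    g <- cut(prob, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    g <- factor(g)
  }
  if (nlevels(g) < groups)
    warning("ties in predicted risk: only ", nlevels(g), " distinct groups formed")
  out <- data.frame(
    decile = seq_len(nlevels(g)),
    mean_predicted = as.numeric(tapply(prob, g, mean)),
    observed_rate = as.numeric(tapply(data$y, g, mean)),
    count = as.integer(tapply(prob, g, length))
  )
  rownames(out) <- NULL
  out
}
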