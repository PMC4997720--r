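#' @keywords internal
"_PACKAGE"

# ---- fitted-model container ------------------------------------------------

new_sc_fit <- function(intercept, coefficients, family, shrinkage_applied = 1,
                       converged = TRUE, fit_stat = NA_real_, method = "ml") {
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 family = family,
                 shrinkage_applied = shrinkage_applied,
                 converged = converged,
                 fit_stat = fit_stat,   # SSE (linear) or -2LL (logistic) in fitting data
                 method = method),
            class = "sc_fit")
}

#' @export
print.sc_fit <- function(x, ...) {
  cat("<sc_fit> ", x$family, " model (", x$method, ")",
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  print(round(c("(Intercept)" = x$intercept, x$coefficients), 4))
  if (x$shrinkage_applied != 1)
    cat("uniform shrinkage factor applied:", signif(x$shrinkage_applied, 4), "\n")
  cat(if (x$family == "linear") "fitting-data SSE: " else "fitting-data -2LL: ",
      signif(x$fit_stat, 6), "\n", sep = "")
  invisible(x)
}

#' Linear predictor of a fitted model
#'
#' @param model An `sc_fit` object.
#' @param data An [sc_data] object (or a bare predictor matrix).
#' @return Numeric vector `intercept + X %*% coefficients`, one value per row.
#' @export
linear_predictor <- function(model, data) {
  X <- if (inherits(data, "sc_data")) data$X else data
  if (ncol(X) != length(model$coefficients))
    stop("predictor count mismatch: model has ", length(model$coefficients),
         " coefficients, data has ", ncol(X), " columns")
  drop(model$intercept + X %*% model$coefficients)
}

#' Predicted event probabilities of a logistic model
#'
#' @inheritParams linear_predictor
#' @return Vector of probabilities `plogis(linear_predictor)`.
#' @export
predict_risk <- function(model, data) {
  if (model$family != "logistic") stop("predict_risk requires a logistic model")
  stats::plogis(linear_predictor(model, data))
}

# intercept-augmented design matrix
design_matrix <- function(data) cbind("(Intercept)" = 1, data$X)

# ---- ordinary least squares ------------------------------------------------

#' Fit a linear model by ordinary least squares
#'
#' @param data An [sc_data] object with `family = "linear"`.
#' @return An `sc_fit` with the least-squares intercept and slopes, the
#'   fitting-data SSE in `fit_stat`, and `shrinkage_applied = 1`.
#' @export
fit_ols <- function(data) {
  stopifnot(inherits(data, "sc_data"))
  if (data$family != "linear") stop("fit_ols requires a linear-family data set")
  Xi <- design_matrix(data)
  qr_x <- qr(Xi)
  if (qr_x$rank < ncol(Xi)) {
    bad <- colnames(Xi)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(Xi))]]
    stop("singular design matrix; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qr_x, data$y)
  res <- data$y - drop(Xi %*% beta)
  new_sc_fit(beta[1L], beta[-1L], "linear",
             fit_stat = sum(res^2), method = "ols")
}

# fast internal OLS on a prebuilt design matrix; returns coefficients or NULL
ols_coef <- function(Xi, y) {
  fit <- .lm.fit(Xi, y)
  cf <- fit$coefficients
  if (anyNA(cf) || fit$rank < ncol(Xi)) return(NULL)
  cf
}

# ---- maximum-likelihood logistic -------------------------------------------

# -2 log likelihood from probabilities, clipped so resampled/shrunken models
# with p = 0/1 in the evaluation data still yield a finite value
PROB_CLIP <- 1e-12

m2ll_from_prob <- function(y, prob) {
  prob <- pmin(pmax(prob, PROB_CLIP), 1 - PROB_CLIP)
  -2 * sum(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Fit a logistic model by maximum likelihood
#'
#' IRLS fit with an explicit separation guard: the returned model carries a
#' `converged` flag that is `TRUE` only when the score equations hold at
#' tolerance AND no coefficient exceeds the divergence bound. Separated data
#' (where the MLE is infinite) therefore yield `converged = FALSE` rather than
#' silently enormous coefficients.
#'
#' @param data An [sc_data] object with `family = "logistic"` and both classes
#'   present.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Score tolerance: converged when `max(abs(score)) < tol`.
#' @param divergence_bound Declare non-convergence when any `abs(coefficient)`
#'   exceeds this bound (default 20; sensible for standardized or 0/1
#'   predictors, where true log odds ratios of this size do not occur).
#' @return An `sc_fit`; `fit_stat` holds the fitting-data -2 log-likelihood.
#' @export
fit_logistic_ml <- function(data, max_iter = 100L, tol = 1e-6,
                            divergence_bound = 20) {
  stopifnot(inherits(data, "sc_data"))
  if (data$family != "logistic") stop("fit_logistic_ml requires a logistic-family data set")
  if (length(unique(data$y)) < 2L)
    stop("degenerate outcome: only one class present")
  Xi <- design_matrix(data)
  fit <- suppressWarnings(
    stats::glm.fit(Xi, data$y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = max_iter))
  )
  beta <- fit$coefficients
  if (anyNA(beta))
    stop("singular design matrix; offending column(s): ",
         paste(colnames(Xi)[is.na(beta)], collapse = ", "))
  prob <- stats::plogis(drop(Xi %*% beta))
  score <- drop(crossprod(Xi, data$y - prob))
  converged <- max(abs(score)) < tol && max(abs(beta)) <= divergence_bound
  new_sc_fit(beta[1L], beta[-1L], "logistic", converged = converged,
             fit_stat = m2ll_from_prob(data$y, prob), method = "ml")
}

# fast internal ML logistic on a prebuilt design; returns list(coef, converged)
# or NULL when the fit is unusable (single class / singular design)
ml_coef <- function(Xi, y, max_iter = 100L, tol = 1e-6, divergence_bound = 20) {
  if (all(y == y[1L])) return(NULL)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(Xi, y, family = stats::binomial(),
                                    control = stats::glm.control(epsilon = 1e-10,
                                                                 maxit = max_iter))),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(NULL)
  beta <- fit$coefficients
  prob <- stats::plogis(drop(Xi %*% beta))
  score <- drop(crossprod(Xi, y - prob))
  list(coef = beta,
       converged = max(abs(score)) < tol && max(abs(beta)) <= divergence_bound)
}

# ---- Firth-penalized logistic ----------------------------------------------

# penalized log-likelihood l(beta) + 0.5 log det I(beta); all parameters
# (including the intercept) enter the information matrix
firth_penalized_loglik <- function(Xi, y, beta) {
  eta <- drop(Xi %*% beta)
  prob <- stats::plogis(eta)
  w <- prob * (1 - prob)
  XtWX <- crossprod(Xi * sqrt(w))
  # log(1 + e^eta) computed overflow-safely
  ll <- sum(y * eta) - sum(pmax(eta, 0) + log1p(exp(-abs(eta))))
  ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
}

#' Fit a logistic model by Firth-penalized maximum likelihood
#'
#' Maximizes the penalized log-likelihood l(beta) + 1/2 log det I(beta)
#' (Jeffreys-prior penalty) by modified-score IRLS with hat-value corrections
#' and step-halving. The penalty shrinks coefficients during estimation and
#' yields finite estimates even under complete separation, where ordinary
#' maximum likelihood diverges. All parameters, including the intercept, are
#' penalized.
#'
#' @inheritParams fit_logistic_ml
#' @param max_iter Maximum modified-score iterations (default 100).
#' @param tol Convergence tolerance on the maximum absolute modified score.
#' @return An `sc_fit` with finite coefficients; `fit_stat` holds the
#'   (unpenalized) -2 log-likelihood in the fitting data.
#' @export
fit_logistic_firth <- function(data, max_iter = 100L, tol = 1e-6) {
  stopifnot(inherits(data, "sc_data"))
  if (data$family != "logistic") stop("fit_logistic_firth requires a logistic-family data set")
  Xi <- design_matrix(data)
  y <- data$y
  k <- ncol(Xi)
  prev <- mean(y)
  beta <- c(stats::qlogis(min(max(prev, 1 / (2 * length(y))),
                              1 - 1 / (2 * length(y)))),
            rep(0, k - 1L))
  pl_old <- firth_penalized_loglik(Xi, y, beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xi %*% beta)
    prob <- stats::plogis(eta)
    w <- prob * (1 - prob)
    Xw <- Xi * sqrt(w)
    XtWX <- crossprod(Xw)
    XtWX_inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(XtWX_inv)) stop("singular information matrix in Firth fit")
    h <- rowSums((Xw %*% XtWX_inv) * Xw)             # hat values
    score_mod <- drop(crossprod(Xi, y - prob + h * (0.5 - prob)))
    if (max(abs(score_mod)) < tol) { converged <- TRUE; break }
    delta <- drop(XtWX_inv %*% score_mod)
    step <- 1
    repeat {                                          # step-halving on the penalized likelihood
      beta_new <- beta + step * delta
      pl_new <- firth_penalized_loglik(Xi, y, beta_new)
      if (is.finite(pl_new) && pl_new >= pl_old - 1e-10) break
      step <- step / 2
      if (step < 1e-8) { beta_new <- beta; pl_new <- pl_old; break }
    }
    beta <- beta_new
    pl_old <- pl_new
  }
  if (!converged) {
    eta <- drop(Xi %*% beta)
    prob <- stats::plogis(eta)
    w <- prob * (1 - prob)
    Xw <- Xi * sqrt(w)
    XtWX_inv <- solve(crossprod(Xw))
    h <- rowSums((Xw %*% XtWX_inv) * Xw)
    converged <- max(abs(drop(crossprod(Xi, y - prob + h * (0.5 - prob))))) < tol
  }
  prob <- stats::plogis(drop(Xi %*% beta))
  new_sc_fit(beta[1L], beta[-1L], "logistic", converged = converged,
             fit_stat = m2ll_from_prob(y, prob), method = "firth")
}
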