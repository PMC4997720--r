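# The wrapper framework: bootstrap the development data, build a model in each
# resample according to each of two strategies, evaluate both models in the
# original data (which stands in for the source population), and summarize the
# distribution of performance ratios/differences.

#' Compare two model-building strategies by repeated bootstrap resampling
#'
#' Per replicate one bootstrap sample of size n is drawn from `data`; both
#' strategies are applied to that same sample (a paired design, which
#' minimizes Monte-Carlo variance of the comparison); the two fitted models
#' are then evaluated in the original data. For the linear family the recorded
#' value is the ratio `SSE(B)/SSE(A)`; for the logistic family it is the
#' difference in -2 log-likelihoods, `-2LL(B) - (-2LL(A))`. Values below the
#' cutoff (1 for ratios, 0 for differences) mean strategy B outperformed
#' strategy A in that replicate; the proportion of such replicates is the
#' victory rate of B over A.
#'
#' Replicates in which either strategy wholly fails (single-class bootstrap
#' sample, separation of the full fit, all shrinkage rounds failed) are
#' dropped and counted in `n_dropped`; separation-prone data announce
#' themselves through this count and through skewed comparison distributions.
#' More than 50\% dropped replicates is an error.
#'
#' @param data The development [sc_data] set.
#' @param spec_a,spec_b [strategy_spec]s for the comparator (A) and candidate
#'   (B) strategies.
#' @param replicates Number of comparison replicates. Defaults to 5000 for
#'   logistic data and 10000 for linear data; scale down for quick looks.
#' @param seed Integer master seed; every resample and every strategy-internal
#'   round derives deterministically from it.
#' @param eval_data The data set standing in for the source population, in
#'   which both fitted models are evaluated. Defaults to `data` itself (the
#'   only option with empirical data); when the data were simulated from a
#'   known population, passing the population here evaluates the strategies
#'   against the truth rather than against the finite development sample.
#' @return An object of class `sc_comparison`: list with `metric`
#'   (`"sse_ratio"` or `"minus2ll_diff"`), `values` (one per surviving
#'   replicate), `gammas_a`/`gammas_b` (per-replicate shrinkage factors, `NA`
#'   where the strategy has none), `failed_a`/`failed_b`, `victory_rate`,
#'   `median`, `iqr`, `mean_shrinkage_a`/`_b`, `n_dropped`, `replicates`,
#'   `seed`, `spec_a`, `spec_b`.
#' @examples
#' d <- gen_logistic_dvt_like(logistic_sim_config(n = 300, seed = 7))
#' cmp <- compare_strategies(d, strategy_spec("null"), strategy_spec("heuristic"),
#'                           replicates = 50, seed = 1)
#' cmp
#' @export
compare_strategies <- function(data, spec_a, spec_b,
                               replicates = if (data$family == "logistic") 5000L else 10000L,
                               seed = 1L, eval_data = data) {
  stopifnot(inherits(data, "sc_data"),
            inherits(spec_a, "strategy_spec"), inherits(spec_b, "strategy_spec"),
            replicates >= 1)
  if (eval_data$family != data$family || eval_data$p != data$p)
    stop("eval_data must match the development data's family and predictors")
  metric <- if (data$family == "linear") "sse_ratio" else "minus2ll_diff"
  n <- data$n
  R <- as.integer(replicates)

  # the comparison's own bootstrap stream, drawn up-front so strategy-internal
  # resampling cannot perturb it
  boot_idx <- local({
    set.seed(child_seed(seed, 0L, 1L))
    lapply(seq_len(R), function(i) sample.int(n, n, replace = TRUE))
  })

  values <- rep(NA_real_, R)
  gammas_a <- rep(NA_real_, R)
  gammas_b <- rep(NA_real_, R)
  failed_a <- logical(R)
  failed_b <- logical(R)

  for (r in seq_len(R)) {
    d_boot <- sc_data_rows(data, boot_idx[[r]])
    fa <- fit_one_strategy(d_boot, spec_a, child_seed(seed, r, name_hash(spec_a$name)))
    fb <- fit_one_strategy(d_boot, spec_b, child_seed(seed, r, name_hash(spec_b$name)))
    failed_a[r] <- fa$failed
    failed_b[r] <- fb$failed
    if (fa$failed || fb$failed) next
    gammas_a[r] <- fa$gamma
    gammas_b[r] <- fb$gamma
    values[r] <- if (metric == "sse_ratio") {
      sse(fb$model, eval_data) / sse(fa$model, eval_data)
    } else {
      minus2_log_likelihood(fb$model, eval_data) -
        minus2_log_likelihood(fa$model, eval_data)
    }
  }

  keep <- !is.na(values)
  n_dropped <- sum(!keep)
  if (n_dropped > R / 2)
    stop("more than half of the comparison replicates failed (", n_dropped,
         " of ", R, "); the data are too sparse or separated for these strategies")
  vals <- values[keep]
  summ <- summarize_distribution(vals)
  structure(list(
    metric = metric,
    values = vals,
    gammas_a = gammas_a, gammas_b = gammas_b,
    failed_a = failed_a, failed_b = failed_b,
    victory_rate = victory_rate(vals, metric),
    median = summ[["median"]], iqr = summ[["iqr"]],
    mean_shrinkage_a = mean_or_na(gammas_a[keep]),
    mean_shrinkage_b = mean_or_na(gammas_b[keep]),
    n_dropped = n_dropped, replicates = R, seed = seed,
    spec_a = spec_a, spec_b = spec_b
  ), class = "sc_comparison")
}

mean_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x)) mean(x) else NA_real_
}

# fit one strategy inside the comparison loop; failures become flags, and a
# final model that did not converge counts as a failure
fit_one_strategy <- function(d_boot, spec, seed) {
  res <- tryCatch(fit_strategy(d_boot, spec, seed), error = function(e) NULL)
  if (is.null(res) || !isTRUE(res$model$converged))
    return(list(failed = TRUE, model = NULL, gamma = NA_real_))
  list(failed = FALSE, model = res$model, gamma = res$gamma)
}

#' @export
print.sc_comparison <- function(x, ...) {
  cutoff <- if (x$metric == "sse_ratio") 1 else 0
  cat("<sc_comparison> ", x$spec_b$name, " vs ", x$spec_a$name,
      " (", x$metric, ", ", x$replicates, " replicates, seed ", x$seed, ")\n",
      sep = "")
  cat(sprintf("  victory rate of %s over %s: %.1f%%  (values < %g)\n",
              x$spec_b$name, x$spec_a$name, 100 * x$victory_rate, cutoff))
  cat(sprintf("  median %.3g, IQR %.3g", x$median, x$iqr))
  if (is.finite(x$mean_shrinkage_b))
    cat(sprintf(", mean shrinkage (%s) %.3f", x$spec_b$name, x$mean_shrinkage_b))
  cat("\n")
  if (x$n_dropped > 0)
    cat("  dropped replicates (failed fits):", x$n_dropped, "\n")
  invisible(x)
}

#' Victory rate of a comparison distribution
#'
#' The proportion of values strictly below the metric's cutoff: 1 for SSE
#' ratios, 0 for -2 log-likelihood differences. Exact ties at the cutoff count
#' as non-victories, so a strategy compared with itself has victory rate 0.
#'
#' @param values Non-empty numeric vector of per-replicate comparison values.
#' @param metric `"sse_ratio"` or `"minus2ll_diff"`.
#' @return A proportion in \[0, 1\].
#' @export
victory_rate <- function(values, metric = c("sse_ratio", "minus2ll_diff")) {
  metric <- match.arg(metric)
  if (length(values) == 0) stop("empty comparison distribution")
  cutoff <- if (metric == "sse_ratio") 1 else 0
  mean(values < cutoff)
}

#' Median and interquartile range of a comparison distribution
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param values Non-empty numeric vector.
#' @return Named vector `c(median = ..., iqr = ...)`.
#' @export
summarize_distribution <- function(values) {
  if (length(values) == 0) stop("empty comparison distribution")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2L], iqr = q[3L] - q[1L])
}

#' Histogram of a comparison distribution
#'
#' Plots the per-replicate comparison values with a vertical indicator at the
#' cutoff (1 for SSE ratios, 0 for -2LL differences); the area to the left of
#' the line is the victory rate, annotated on the plot.
#'
#' @param result An `sc_comparison`.
#' @param path Output image path (extension selects the device, e.g. `.png`).
#' @param bins Number of histogram bins.
#' @return `path`, invisibly; the underlying ggplot is attached as attribute
#'   `"plot"`.
#' @export
plot_comparison_histogram <- function(result, path, bins = 60L) {
  stopifnot(inherits(result, "sc_comparison"))
  cutoff <- if (result$metric == "sse_ratio") 1 else 0
  xlab <- if (result$metric == "sse_ratio") "SSE(B) / SSE(A)"
          else "-2LL(B) - (-2LL(A))"
  df <- data.frame(value = result$values)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = cutoff, colour = "blue") +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("VR = %.1f%%", 100 * result$victory_rate)) +
    ggplot2::labs(x = xlab, y = "replicates",
                  title = sprintf("%s vs %s", result$spec_b$name, result$spec_a$name)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, gg, width = 6, height = 4, dpi = 150)
  out <- path
  attr(out, "plot") <- gg
  invisible(out)
}

#' External validation of a fitted logistic model
#'
#' Convenience wrapper computing the Brier score and the calibration-by-deciles
#' table of a model in validation data not used for fitting.
#'
#' @param model A logistic `sc_fit`.
#' @param data A logistic [sc_data] validation set.
#' @return List with elements `brier` and `deciles`.
#' @export
external_validation <- function(model, data) {
  if (model$family != data$family) stop("model and data families differ")
  list(brier = brier_score(model, data),
       deciles = calibration_deciles(model, data))
}
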