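# Simulation scenarios: sweep one data characteristic (sample size, explained
# variance, events per variable, Nagelkerke R^2), run strategy-vs-null
# comparisons at every grid point, and collect victory-rate curves.

#' Configure a simulation sweep
#'
#' Four scenarios are supported, each varying one data characteristic while
#' all others are held fixed:
#' \describe{
#'   \item{`opv_linear`}{Gaussian data, fixed p and R-squared; `grid` gives the
#'     number of sample rows (so OPV = rows / p varies).}
#'   \item{`r2_linear`}{Gaussian data, fixed rows and p; `grid` gives the
#'     generating-model R-squared.}
#'   \item{`epv_logistic`}{A logistic base data set subsampled to each target
#'     EPV in `grid` while preserving prevalence.}
#'   \item{`nagelkerke_logistic`}{Predictor subsets of a logistic base data set
#'     chosen so the fitted Nagelkerke R-squared falls at each grid value
#'     (within `r2_bin_width`).}
#' }
#'
#' @param scenario One of `"opv_linear"`, `"r2_linear"`, `"epv_logistic"`,
#'   `"nagelkerke_logistic"`.
#' @param grid Numeric vector of parameter values (rows, R-squared, EPV, or
#'   Nagelkerke R-squared targets by scenario).
#' @param strategies List of [strategy_spec]s, each compared against the null
#'   strategy.
#' @param base For linear scenarios a [linear_sim_config] (its `n_sample` /
#'   `r2_target` field is overridden per grid point); for logistic scenarios a
#'   logistic [sc_data] base set.
#' @param replicates Comparison replicates per grid point; defaults to 10000
#'   for linear and 5000 for logistic scenarios (scale down for quick runs).
#' @param p_model Model size used for EPV arithmetic (default: predictors of
#'   the base data).
#' @param r2_bin_width Half-width of the Nagelkerke R-squared acceptance bin
#'   (default 0.025).
#' @param max_draws Draw budget per Nagelkerke bin (default 500).
#' @param seed Integer master seed; per-point seeds derive deterministically
#'   from it, so any row can be recomputed in isolation.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("opv_linear", "r2_linear",
                                         "epv_logistic", "nagelkerke_logistic"),
                            grid, strategies, base,
                            replicates = NULL, p_model = NULL,
                            r2_bin_width = 0.025, max_draws = 500L, seed = 1L) {
  scenario <- match.arg(scenario)
  linear <- scenario %in% c("opv_linear", "r2_linear")
  if (is.null(replicates)) replicates <- if (linear) 10000L else 5000L
  if (linear) {
    stopifnot(inherits(base, "linear_sim_config"))
  } else {
    stopifnot(inherits(base, "sc_data"), base$family == "logistic")
    if (is.null(p_model)) p_model <- base$p
  }
  stopifnot(length(grid) >= 1, all(vapply(strategies, inherits, logical(1),
                                          "strategy_spec")))
  structure(list(scenario = scenario, grid = grid, strategies = strategies,
                 base = base, replicates = as.integer(replicates),
                 p_model = p_model, r2_bin_width = r2_bin_width,
                 max_draws = as.integer(max_draws), seed = as.integer(seed)),
            class = "scenario_config")
}

# data set for one grid point (deterministic given config and point index)
scenario_point_data <- function(config, i) {
  g <- config$grid[i]
  pt_seed <- child_seed(config$seed, i, 17L)
  switch(config$scenario,
    opv_linear = {
      cfg <- config$base
      cfg$n_sample <- as.integer(g)
      cfg$seed <- pt_seed
      gen_linear_cholesky(cfg)
    },
    r2_linear = {
      cfg <- config$base
      cfg$r2_target <- g
      cfg$seed <- pt_seed
      gen_linear_cholesky(cfg)
    },
    epv_logistic = subsample_epv(config$base, g, config$p_model, seed = pt_seed),
    nagelkerke_logistic = {
      bin <- list(c(g - config$r2_bin_width, g + config$r2_bin_width))
      res <- subset_predictors_by_r2(config$base, pool_size = config$base$p,
                                     draw_size = config$p_model, r2_bins = bin,
                                     max_draws = config$max_draws, seed = pt_seed)
      if (is.null(res[[1]]))
        stop("no predictor subset found with Nagelkerke R2 near ", g)
      res[[1]]
    })
}

#' Run a simulation sweep
#'
#' For each grid point the scenario's data set is constructed, each strategy
#' is compared against the null strategy with [compare_strategies], and the
#' summary statistics are collected. Grid points where the comparison is
#' infeasible (for example an EPV too low for any resampling strategy to fit)
#' produce a row with `status = "failed"` rather than aborting the sweep -
#' at very low EPV victory-rate estimation is not always possible.
#'
#' @param config A [scenario_config].
#' @return A data frame of class `sc_sweep`: one row per (grid point,
#'   strategy) with columns `param`, `strategy`, `victory_rate`, `median`,
#'   `iqr`, `mean_shrinkage`, `dropped_replicates`, `n`, `status`. The
#'   configuration is attached as attribute `"config"`.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  null_spec <- strategy_spec("null")
  rows <- list()
  linear <- config$scenario %in% c("opv_linear", "r2_linear")
  for (i in seq_along(config$grid)) {
    g <- config$grid[i]
    pt <- tryCatch(scenario_point_data(config, i), error = function(e) NULL)
    # fully simulated scenarios evaluate against the known population; the
    # empirical-data scenarios evaluate in the initial data set itself
    d <- if (is.null(pt)) NULL else if (linear) pt$sample else pt
    ev <- if (is.null(pt)) NULL else if (linear) pt$population else pt
    for (s in seq_along(config$strategies)) {
      spec <- config$strategies[[s]]
      cmp <- NULL
      if (!is.null(d))
        cmp <- tryCatch(
          compare_strategies(d, null_spec, spec, replicates = config$replicates,
                             seed = child_seed(config$seed, i, 1000L + s),
                             eval_data = ev),
          error = function(e) NULL)
      rows[[length(rows) + 1L]] <- if (is.null(cmp)) {
        data.frame(param = g, strategy = spec$name, victory_rate = NA_real_,
                   median = NA_real_, iqr = NA_real_,
                   mean_shrinkage = NA_real_, dropped_replicates = NA_integer_,
                   n = if (is.null(d)) NA_integer_ else d$n, status = "failed")
      } else {
        data.frame(param = g, strategy = spec$name,
                   victory_rate = cmp$victory_rate, median = cmp$median,
                   iqr = cmp$iqr, mean_shrinkage = cmp$mean_shrinkage_b,
                   dropped_replicates = cmp$n_dropped, n = d$n, status = "ok")
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sc_sweep", class(out))
  attr(out, "config") <- config
  out
}

#' Plot victory-rate curves from a sweep
#'
#' One victory-rate-versus-parameter curve per strategy. Loess smoothing, when
#' requested, affects the displayed curve only - stored sweep values are never
#' smoothed.
#'
#' @param result An `sc_sweep` data frame from [run_sweep].
#' @param path Output image path.
#' @param smooth Overlay a loess smoother (span `smooth_span`) instead of
#'   connecting the raw points (default `FALSE`).
#' @param smooth_span Loess span (default 0.75).
#' @return `path`, invisibly, with the ggplot attached as attribute `"plot"`.
#' @export
plot_sweep <- function(result, path, smooth = FALSE, smooth_span = 0.75) {
  stopifnot(inherits(result, "sc_sweep") || is.data.frame(result))
  df <- result[result$status == "ok", , drop = FALSE]
  if (nrow(df) == 0) stop("no successful sweep rows to plot")
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$param, y = .data$victory_rate,
                                         colour = .data$strategy)) +
    ggplot2::geom_point()
  gg <- if (smooth && length(unique(df$param)) > 3) {
    gg + ggplot2::geom_smooth(method = "loess", span = smooth_span,
                              se = FALSE, formula = y ~ x)
  } else {
    gg + ggplot2::geom_line()
  }
  gg <- gg +
    ggplot2::labs(x = "scenario parameter", y = "victory rate over null") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  ggplot2::ggsave(path, gg, width = 6, height = 4, dpi = 150)
  out <- path
  attr(out, "plot") <- gg
  invisible(out)
}
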