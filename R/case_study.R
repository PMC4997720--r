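# The end-to-end workflow: compare strategies a priori in development data,
# select winners, develop final models, and validate them externally.

#' A priori strategy selection with external validation
#'
#' Runs [compare_strategies] of every candidate strategy against the null
#' strategy in the development data, ranks candidates by victory rate (ties
#' broken by the more negative/smaller median), develops final models on the
#' full development data for the selected strategies plus the null reference,
#' and assesses each final model in the validation data by Brier score and
#' calibration deciles.
#'
#' @param dev_data Development [sc_data] set.
#' @param val_data Validation [sc_data] set with the same predictors and
#'   family.
#' @param strategies List of [strategy_spec]s to consider (a `"null"` entry is
#'   allowed and simply validated as the reference).
#' @param replicates Comparison replicates (default 500; increase for final
#'   analyses).
#' @param seed Integer master seed.
#' @param n_select How many top-ranked candidate strategies to develop final
#'   models for (default: all).
#' @param out_dir Optional directory; when given, the comparison table,
#'   validation table, calibration tables and a run manifest are written there.
#' @return A list of class `sc_case_study`: `comparisons` (data frame of VR /
#'   median / IQR / mean shrinkage per candidate), `selected` (strategy names,
#'   ranked), `models` (named list of final `sc_fit`s, always including
#'   `null`), `validation` (data frame with Brier score per final model) and
#'   `deciles` (named list of calibration tables).
#' @export
run_case_study <- function(dev_data, val_data, strategies,
                           replicates = 500L, seed = 1L, n_select = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(dev_data, "sc_data"), inherits(val_data, "sc_data"))
  if (dev_data$family != val_data$family)
    stop("development and validation data families differ")
  if (!identical(dev_data$names, val_data$names))
    stop("predictor columns differ between development and validation data: ",
         paste(union(setdiff(dev_data$names, val_data$names),
                     setdiff(val_data$names, dev_data$names)), collapse = ", "))
  null_spec <- strategy_spec("null")
  cand <- Filter(function(s) s$name != "null", strategies)

  comparisons <- do.call(rbind, lapply(seq_along(cand), function(i) {
    cmp <- compare_strategies(dev_data, null_spec, cand[[i]],
                              replicates = replicates,
                              seed = child_seed(seed, i, 5000L))
    data.frame(strategy = cand[[i]]$name, victory_rate = cmp$victory_rate,
               median = cmp$median, iqr = cmp$iqr,
               mean_shrinkage = cmp$mean_shrinkage_b,
               dropped_replicates = cmp$n_dropped)
  }))

  if (is.null(comparisons)) {
    selected <- character(0)
  } else {
    ord <- order(-comparisons$victory_rate, comparisons$median)
    selected <- comparisons$strategy[ord]
    if (!is.null(n_select)) selected <- utils::head(selected, n_select)
  }

  final_names <- unique(c("null", selected))
  spec_by_name <- c(list(null = null_spec),
                    stats::setNames(cand, vapply(cand, `[[`, "", "name")))
  models <- lapply(final_names, function(nm)
    fit_strategy(dev_data, spec_by_name[[nm]],
                 seed = child_seed(seed, name_hash(nm), 6000L))$model)
  names(models) <- final_names

  validation <- NULL
  deciles <- NULL
  if (dev_data$family == "logistic") {
    ev <- lapply(models, external_validation, data = val_data)
    validation <- data.frame(strategy = final_names,
                             brier = vapply(ev, `[[`, 0, "brier"))
    deciles <- lapply(ev, `[[`, "deciles")
  } else {
    validation <- data.frame(strategy = final_names,
                             sse = vapply(models, sse, 0, data = val_data))
  }
  rownames(validation) <- NULL

  out <- structure(list(comparisons = comparisons, selected = selected,
                        models = models, validation = validation,
                        deciles = deciles, seed = seed,
                        replicates = as.integer(replicates)),
                   class = "sc_case_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                       row.names = FALSE)
    utils::write.csv(validation, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    for (nm in names(deciles))
      utils::write.csv(deciles[[nm]],
                       file.path(out_dir, paste0("calibration_", nm, ".csv")),
                       row.names = FALSE)
    write_manifest(list(command = "validate", replicates = replicates,
                        seed = seed, n_select = n_select,
                        strategies = vapply(strategies, `[[`, "", "name")),
                   file.path(out_dir, "manifest.json"))
  }
  out
}

#' @export
print.sc_case_study <- function(x, ...) {
  cat("<sc_case_study> (", x$replicates, " replicates, seed ", x$seed, ")\n",
      sep = "")
  if (!is.null(x$comparisons)) {
    cat("a priori comparisons against the null strategy:\n")
    print(transform(x$comparisons,
                    victory_rate = round(victory_rate, 3),
                    median = signif(median, 3), iqr = signif(iqr, 3),
                    mean_shrinkage = round(mean_shrinkage, 3)),
          row.names = FALSE)
  }
  cat("selected strategies:", paste(x$selected, collapse = ", "), "\n")
  cat("external validation of final models:\n")
  print(x$validation, row.names = FALSE)
  invisible(x)
}

#' Write / read a run manifest
#'
#' A manifest records the full resolved configuration of a run, including the
#' master seed, so that the run can be reproduced bit-identically.
#'
#' @param config Named list of configuration values (scalars and short
#'   vectors).
#' @param path JSON file path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_manifest <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
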