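#' Construct a development data set for strategy comparison
#'
#' Bundles an outcome vector, a numeric predictor matrix and a model family
#' into the unit that every model-building strategy consumes. Predictors and
#' their functional forms are taken as fixed a priori; the package performs no
#' variable selection.
#'
#' @param y Outcome vector. Real-valued for `family = "linear"`; strictly 0/1
#'   for `family = "logistic"`.
#' @param X Numeric predictor matrix (or data frame coercible to one) with one
#'   row per observation. May have zero columns for intercept-only problems.
#' @param family `"linear"` or `"logistic"`.
#' @param names Optional predictor labels; defaults to the column names of `X`.
#' @param allow_degenerate If `TRUE`, a logistic outcome with a single class is
#'   tolerated (used internally when inspecting bootstrap resamples); such data
#'   cannot be fitted.
#'
#' @return An object of class `"sc_data"`: a list with elements `y`, `X`,
#'   `family`, `names`, `n`, `p`.
#' @examples
#' d <- sc_data(rbinom(60, 1, 0.3), matrix(rbinom(120, 1, 0.5), 60, 2), "logistic")
#' d
#' @export
sc_data <- function(y, X, family = c("linear", "logistic"), names = NULL,
                    allow_degenerate = FALSE) {
  family <- match.arg(family)
  if (is.null(X)) X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n)
    stop("nrow(X) (", nrow(X), ") does not match length(y) (", n, ")")
  if (anyNA(y) || anyNA(X))
    stop("missing values are not allowed in outcome or predictors")
  if (n < p + 2L)
    stop("need at least p + 2 = ", p + 2L, " observations, got ", n)
  if (family == "logistic") {
    if (!all(y %in% c(0, 1)))
      stop("logistic outcome must contain only 0 and 1")
    if (!allow_degenerate && length(unique(y)) < 2L)
      stop("logistic outcome is degenerate: only one class present")
  }
  if (is.null(names)) names <- colnames(X)
  if (is.null(names)) names <- if (p > 0L) paste0("x", seq_len(p)) else character(0)
  if (length(names) != p)
    stop("length(names) must equal ncol(X)")
  colnames(X) <- names
  structure(list(y = y, X = X, family = family, names = names, n = n, p = p),
            class = "sc_data")
}

#' @export
print.sc_data <- function(x, ...) {
  cat("<sc_data> ", x$family, " family: n = ", x$n, ", p = ", x$p, sep = "")
  if (x$family == "logistic") {
    ev <- n_events(x)
    cat(", events = ", ev, " (prevalence ", signif(ev / x$n, 3),
        ", EPV ", if (x$p > 0) signif(ev / x$p, 3) else "-", ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Event count, events per variable and observations per variable
#'
#' `n_events` counts outcome events of a logistic data set; `epv` and `opv`
#' are the sparsity measures events-per-variable and observations-per-variable
#' that drive strategy performance.
#'
#' @param data An [sc_data] object.
#' @param p_model Number of model parameters to divide by; defaults to the
#'   number of predictors in `data`.
#' @return A single number.
#' @export
n_events <- function(data) {
  stopifnot(inherits(data, "sc_data"), data$family == "logistic")
  sum(data$y == 1)
}

#' @rdname n_events
#' @export
epv <- function(data, p_model = data$p) n_events(data) / p_model

#' @rdname n_events
#' @export
opv <- function(data, p_model = data$p) {
  stopifnot(inherits(data, "sc_data"))
  data$n / p_model
}

# row subset keeping metadata; allow_degenerate because resamples may lose a class
sc_data_rows <- function(data, idx, allow_degenerate = TRUE) {
  sc_data(data$y[idx], data$X[idx, , drop = FALSE], data$family,
          names = data$names, allow_degenerate = allow_degenerate)
}

#' Read a development data set from a delimited text file
#'
#' Reads a CSV/TSV file with a header, validates it and returns an [sc_data]
#' object. All columns other than the outcome are treated as predictors unless
#' `predictors` names an explicit subset. Logistic outcomes are required to be
#' coded strictly 0/1.
#'
#' @param path Path to a delimited text file with a header row.
#' @param outcome Name of the outcome column.
#' @param family `"linear"` or `"logistic"`.
#' @param predictors Optional character vector of predictor column names.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @return An [sc_data] object.
#' @export
read_dataset <- function(path, outcome, family = c("linear", "logistic"),
                         predictors = NULL, sep = ",") {
  family <- match.arg(family)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!outcome %in% names(df))
    stop("outcome column '", outcome, "' not found in ", path)
  if (is.null(predictors)) predictors <- setdiff(names(df), outcome)
  missing_cols <- setdiff(predictors, names(df))
  if (length(missing_cols))
    stop("predictor columns not found: ", paste(missing_cols, collapse = ", "))
  na_cols <- names(df)[vapply(df[c(outcome, predictors)], anyNA, logical(1))]
  if (length(na_cols))
    stop("missing values in columns: ", paste(na_cols, collapse = ", "))
  y <- df[[outcome]]
  if (family == "logistic" && !all(y %in% c(0, 1)))
    stop("logistic outcome column '", outcome, "' contains values other than 0/1")
  d <- sc_data(y, as.matrix(df[predictors]), family, names = predictors)
  if (family == "logistic")
    message(sprintf("read %s: n = %d, p = %d, events = %d, EPV = %.1f",
                    basename(path), d$n, d$p, n_events(d),
                    if (d$p > 0) epv(d) else NA_real_))
  else
    message(sprintf("read %s: n = %d, p = %d", basename(path), d$n, d$p))
  d
}

#' Write a data set to CSV
#'
#' @param data An [sc_data] object.
#' @param path Output file path.
#' @param outcome Name used for the outcome column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, outcome = "y") {
  stopifnot(inherits(data, "sc_data"))
  df <- data.frame(data$y, data$X, check.names = FALSE)
  names(df) <- c(outcome, data$names)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
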