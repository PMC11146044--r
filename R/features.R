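#' Construct a feature matrix
#'
#' Container for time-lagged OKN features: one row per analysis timepoint,
#' one column per (variable, lag) pair, plus a per-row completeness flag.
#'
#' @param time timepoint in seconds (one per row).
#' @param X numeric feature matrix.
#' @param complete logical; `FALSE` where the lag window extends before the
#'   start of the block or into missing data.
#' @param rate analysis sampling rate in Hz.
#' @param lags lag grid in seconds.
#' @return an object of class `feature_matrix`.
#' @export
feature_matrix <- function(time, X, complete = rowSums(!is.finite(X)) == 0,
                           rate = NULL, lags = NULL) {
  X <- as.matrix(X)
  stopifnot(length(time) == nrow(X), length(complete) == nrow(X))
  structure(list(time = as.numeric(time), X = X,
                 complete = as.logical(complete), rate = rate, lags = lags),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d timepoints x %d features (%d complete)\n",
              nrow(x$X), ncol(x$X), sum(x$complete)))
  invisible(x)
}

#' Assemble the time-lagged OKN feature matrix
#'
#' Samples the three smoothed OKN variables at a set of lags relative to
#' each analysis timepoint. With the defaults (lags -2.0 to 0 s in 100-ms
#' steps, i.e. 21 lags, at 100 Hz) this yields the 63-dimensional feature
#' vector per timepoint. Rows whose lag window extends before the start of
#' the trace or into missing data are flagged incomplete.
#'
#' @param okn an [okn_variables()] object (native grid, e.g. 1000 Hz).
#' @param rate analysis rate in Hz (must divide the source rate).
#' @param lag_min most negative lag in seconds (<= 0).
#' @param lag_step lag step in seconds.
#' @return a [feature_matrix()].
#' @export
assemble_features <- function(okn, rate = 100, lag_min = -2.0,
                              lag_step = 0.1) {
  stopifnot(inherits(okn, "okn_variables"))
  if (lag_min > 0 || lag_step <= 0)
    stop_bad_arg("`lag_min` must be <= 0 and `lag_step` > 0")
  src <- okn$rate
  step <- src / rate
  if (abs(step - round(step)) > 1e-9)
    stop_bad_arg("analysis rate must divide the source sampling rate")
  step <- as.integer(round(step))
  offs <- seq(lag_min, 0, by = lag_step) * src
  if (any(abs(offs - round(offs)) > 1e-6))
    stop_bad_arg("lag grid is not commensurate with the source sampling rate")
  offs <- as.integer(round(offs))
  lags <- offs / src
  n <- length(okn$t)
  idx <- seq.int(1L, n, by = step)
  vars <- list(v = okn$v_smooth, fp_len = okn$fp_len, fp_dist = okn$fp_dist)
  X <- matrix(NA_real_, nrow = length(idx),
              ncol = length(vars) * length(offs))
  nm <- character(ncol(X))
  k <- 0L
  for (vn in names(vars)) {
    v <- vars[[vn]]
    for (j in seq_along(offs)) {
      k <- k + 1L
      src_idx <- idx + offs[j]
      ok <- src_idx >= 1L
      col <- rep(NA_real_, length(idx))
      col[ok] <- v[src_idx[ok]]
      X[, k] <- col
      nm[k] <- sprintf("%s_lag%+.1f", vn, lags[j])
    }
  }
  colnames(X) <- nm
  feature_matrix(time = (idx - 1L) / src, X = X, rate = rate, lags = lags)
}

#' Attach report-derived labels to a feature matrix
#'
#' The label at each timepoint is the report state at that timepoint;
#' timepoints where no (or both) buttons were pressed, and incomplete rows,
#' are excluded (`NA`).
#'
#' @param features a [feature_matrix()].
#' @param report a `report_trace` covering the feature time range.
#' @return a factor of length `nrow(features$X)` with levels
#'   `integrated`/`segregated`; `NA` marks excluded timepoints.
#' @export
align_labels <- function(features, report) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(report, "report_trace"))
  idx <- as.integer(round(features$time * report$rate)) + 1L
  if (any(idx < 1L) || any(idx > length(report$states)))
    stop_bad_arg("report does not cover the feature time range")
  st <- report$states[idx]
  st[st == 0L] <- NA_integer_
  lab <- factor(PERCEPT_LEVELS[st], levels = PERCEPT_LEVELS)
  lab[!features$complete] <- NA
  lab
}

#' Per-column standardization statistics of a feature matrix
#'
#' @param features a [feature_matrix()].
#' @param rows optional logical row selector (defaults to complete rows);
#'   compute these from a training block only.
#' @return a list with `center` and `scale` vectors.
#' @export
feature_stats <- function(features, rows = NULL) {
  stopifnot(inherits(features, "feature_matrix"))
  rows <- rows %||% features$complete
  X <- features$X[rows, , drop = FALSE]
  m <- colMeans(X)
  s <- apply(X, 2, sd)
  # zero-variance columns are passed through unchanged
  zero <- !is.finite(s) | s <= 0
  list(center = ifelse(zero, 0, m), scale = ifelse(zero, 1, s))
}

#' Standardize a feature matrix by training-block statistics
#'
#' Centers and scales each column by the training block's mean and SD
#' (zero-variance columns pass through unchanged). The three OKN variables
#' have incommensurate units and linear SVMs are scale-sensitive, so
#' standardization is on by default throughout the pipeline.
#'
#' @param features a [feature_matrix()].
#' @param stats statistics from [feature_stats()] on the training block.
#' @return a standardized [feature_matrix()].
#' @export
standardize_features <- function(features, stats) {
  stopifnot(inherits(features, "feature_matrix"))
  X <- sweep(features$X, 2, stats$center, "-")
  X <- sweep(X, 2, stats$scale, "/")
  feature_matrix(features$time, X, features$complete, features$rate,
                 features$lags)
}
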