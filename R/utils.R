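`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad_arg <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_bad_arg("`", name, "` must be a single number in [0, 1], got ",
                 deparse(substitute(x)))
  x
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_bad_arg("`", name, "` must be a single positive number")
  x
}

#' Trailing (causal) sliding mean over defined samples
#'
#' Mean of the last `width` samples (including the current one), ignoring
#' non-finite values. Positions whose window contains no defined sample are
#' `NA`. Used for all smoothed OKN variables so that no value at time t
#' depends on samples after t.
#'
#' @param y numeric vector.
#' @param width window length in samples (>= 1).
#' @return numeric vector of the same length as `y`.
#' @export
trailing_mean <- function(y, width) {
  stopifnot(width >= 1)
  n <- length(y)
  d <- is.finite(y)
  y0 <- ifelse(d, y, 0)
  cs <- cumsum(y0)
  cn <- cumsum(as.numeric(d))
  i0 <- seq_len(n) - width
  prev_s <- ifelse(i0 >= 1L, cs[pmax(i0, 1L)], 0)
  prev_n <- ifelse(i0 >= 1L, cn[pmax(i0, 1L)], 0)
  k <- cn - prev_n
  out <- rep(NA_real_, n)
  ok <- k > 0
  out[ok] <- (cs - prev_s)[ok] / k[ok]
  out
}

# Centered sliding mean over defined samples; `half` samples on each side.
centered_mean <- function(y, half) {
  n <- length(y)
  d <- is.finite(y)
  y0 <- ifelse(d, y, 0)
  cs <- c(0, cumsum(y0))
  cn <- c(0, cumsum(as.numeric(d)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  k <- cn[hi + 1L] - cn[lo]
  out <- rep(NA_real_, n)
  ok <- k > 0
  out[ok] <- ((cs[hi + 1L] - cs[lo])[ok]) / k[ok]
  out
}

# Runs of TRUE in a logical vector as a data.frame(start, end) of sample indices.
logical_runs <- function(x) {
  x[is.na(x)] <- FALSE
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Deterministic sub-seed scheme
#'
#' Expands a master seed into per-participant / per-block seeds by a fixed
#' counter scheme, so any block can be regenerated in isolation. All seeds
#' stay within 32-bit integer range.
#'
#' @param master master seed (integer).
#' @param ... one or more non-negative integer counters
#'   (e.g. participant index, block index).
#' @return a single integer seed.
#' @export
sub_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i) * 16807 + 1) %% 2147483647
  as.integer(s)
}

# Run `expr` under a fixed seed when `seed` is non-NULL, restoring RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
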