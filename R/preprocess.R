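#' Blink detection around missing data
#'
#' Extends every run of invalid samples by `pad_ms` on each side, because
#' eye-position estimates immediately before and after a tracking loss are
#' contaminated by the closing/opening lid.
#'
#' @param trace a [gaze_trace()].
#' @param pad_ms padding in ms applied to each side of every invalid run.
#' @return a logical validity mask (`FALSE` inside padded blink runs).
#' @export
detect_blinks <- function(trace, pad_ms = 50) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (pad_ms < 0) stop_bad_arg("`pad_ms` must be >= 0")
  bad <- !trace$valid | !is.finite(trace$x)
  if (!any(bad)) return(rep(TRUE, length(bad)))
  pad <- as.integer(round(pad_ms / 1000 * trace$rate))
  runs <- logical_runs(bad)
  n <- length(bad)
  mask <- rep(TRUE, n)
  for (j in seq_len(nrow(runs))) {
    mask[max(1L, runs$start[j] - pad):min(n, runs$end[j] + pad)] <- FALSE
  }
  mask
}

#' Fast-phase (saccade) detection on a gaze trace
#'
#' Velocity-threshold saccade detector: samples whose locally smoothed
#' absolute velocity exceeds `vel_thresh` for at least `min_dur_ms` form
#' fast-phase events; event edges are extended while the smoothed velocity
#' stays above `low_thresh` (hysteresis), and events separated by less than
#' `merge_gap_ms` are merged. Samples inside padded blink runs are labelled
#' `missing`; everything else is `slow`. The thresholds separate the
#' 1-2 deg/s slow-phase drift of the stimulus from saccadic speeds by more
#' than an order of magnitude.
#'
#' @param trace a [gaze_trace()].
#' @param vel_thresh detection threshold in deg/s.
#' @param min_dur_ms minimum event duration in ms.
#' @param merge_gap_ms events closer than this are merged (ms).
#' @param smooth_ms width of the centered velocity-smoothing window (ms).
#' @param low_thresh hysteresis threshold in deg/s for event-edge extension.
#' @param pad_ms blink padding passed to [detect_blinks()].
#' @return a factor with levels `slow`, `fast`, `missing` (one per sample),
#'   with the detected events as attribute `events`.
#' @export
detect_fast_phases <- function(trace, vel_thresh = 22, min_dur_ms = 4,
                               merge_gap_ms = 20, smooth_ms = 10,
                               low_thresh = 10, pad_ms = 50) {
  stopifnot(inherits(trace, "gaze_trace"))
  check_positive(vel_thresh, "vel_thresh")
  check_positive(min_dur_ms, "min_dur_ms")
  rate <- trace$rate
  n <- length(trace$x)
  half <- max(1L, as.integer(round(smooth_ms / 1000 * rate / 2)))
  if (n <= 2L * half + 1L)
    stop_bad_arg("trace shorter than the velocity-smoothing kernel")
  mask <- detect_blinks(trace, pad_ms)
  x <- ifelse(mask, trace$x, NA_real_)
  v <- c(NA_real_, diff(x)) * rate
  vs <- centered_mean(v, half)
  core <- !is.na(vs) & abs(vs) >= vel_thresh
  min_len <- max(1L, as.integer(round(min_dur_ms / 1000 * rate)))
  runs <- logical_runs(core)
  runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
  fast <- rep(FALSE, n)
  if (nrow(runs) > 0) {
    # hysteresis: extend each event across the containing run of
    # above-low-threshold samples
    above <- !is.na(vs) & abs(vs) >= low_thresh
    rid <- cumsum(c(TRUE, diff(above) != 0))
    run_start <- which(!duplicated(rid))
    run_end <- c(run_start[-1] - 1L, n)
    for (j in seq_len(nrow(runs))) {
      s <- runs$start[j]; e <- runs$end[j]
      if (above[s]) s <- run_start[rid[s]]
      if (above[e]) e <- run_end[rid[e]]
      fast[s:e] <- TRUE
    }
    # merge events separated by short gaps
    gap <- as.integer(round(merge_gap_ms / 1000 * rate))
    if (gap > 0) {
      ev <- logical_runs(fast)
      if (nrow(ev) > 1) {
        for (j in seq_len(nrow(ev) - 1L)) {
          if (ev$start[j + 1L] - ev$end[j] - 1L < gap)
            fast[ev$end[j]:ev$start[j + 1L]] <- TRUE
        }
      }
    }
  }
  lab <- rep("slow", n)
  lab[fast] <- "fast"
  lab[!mask] <- "missing"
  out <- factor(lab, levels = c("slow", "fast", "missing"))
  attr(out, "events") <- logical_runs(out == "fast")
  out
}

#' Smoothed slow-phase velocity
#'
#' Sample-to-sample velocity computed only where both samples of the
#' difference are slow-phase and valid (fast phases and blinks are excised,
#' never bridged), then smoothed by a trailing (causal) mean over the last
#' `window_s` seconds of defined samples.
#'
#' @param trace a [gaze_trace()].
#' @param labels phase labels from [detect_fast_phases()].
#' @param window_s smoothing window in seconds.
#' @return a list with `raw` and `smooth` velocity series in deg/s
#'   (`NA` where undefined).
#' @export
compute_slow_velocity <- function(trace, labels, window_s = 1.0) {
  stopifnot(inherits(trace, "gaze_trace"), length(labels) == length(trace$x))
  rate <- trace$rate
  slow <- labels == "slow"
  ok <- slow & c(FALSE, slow[-length(slow)]) & is.finite(trace$x) &
    c(FALSE, is.finite(trace$x[-length(trace$x)]))
  v <- rep(NA_real_, length(trace$x))
  v[ok] <- (trace$x[ok] - trace$x[which(ok) - 1L]) * rate
  list(raw = v, smooth = trailing_mean(v, as.integer(round(window_s * rate))))
}

#' Fast-phase-direction run length and extent
#'
#' For each sample, the length (in samples) and absolute extent (in deg) of
#' the maximal run of consecutive samples whose displacement sign equals the
#' OKN fast-phase direction and that contains the sample (0 where the sign
#' differs); both series are then smoothed by a trailing mean over
#' `window_s` seconds. These run statistics are computed from displacement
#' signs, not from the slow/fast labels, so genuine fast phases produce
#' long, large-extent runs while isolated noise flips contribute only short,
#' tiny runs that the sliding average suppresses. By default the
#' displacement sign is taken on a `smooth_ms` boxcar-smoothed copy of the
#' position trace, which removes sub-millisecond noise flips entirely; set
#' `smooth_ms = 0` for raw per-sample signs. Missing samples break runs and
#' are excluded from the sliding means.
#'
#' @param trace a [gaze_trace()].
#' @param labels phase labels from [detect_fast_phases()] (used only to
#'   propagate missingness).
#' @param fast_dir fast-phase direction (-1 or +1).
#' @param window_s trailing smoothing window in seconds.
#' @param smooth_ms boxcar width for pre-smoothing the position trace
#'   before taking displacement signs (0 = raw).
#' @return a list with `len_raw`, `dist_raw`, `len_smooth`, `dist_smooth`.
#' @export
compute_fastphase_runs <- function(trace, labels, fast_dir, window_s = 1.0,
                                   smooth_ms = 20) {
  stopifnot(inherits(trace, "gaze_trace"), fast_dir %in% c(-1, 1))
  rate <- trace$rate
  n <- length(trace$x)
  missing <- labels == "missing" | !is.finite(trace$x)
  x <- ifelse(missing, NA_real_, trace$x)
  if (smooth_ms > 0) {
    x <- centered_mean(x, max(1L, as.integer(round(smooth_ms / 1000 * rate / 2))))
    x[missing] <- NA_real_
  }
  disp <- c(NA_real_, diff(x))
  indir <- disp * fast_dir > 0
  def <- !is.na(indir)
  indir[!def] <- FALSE
  # runs of consecutive equal (indir, defined) values, vectorized via rle
  change <- c(TRUE, diff(indir) != 0 | diff(def) != 0)
  starts <- which(change)
  lens <- diff(c(starts, n + 1L))
  abs0 <- cumsum(abs(ifelse(def, disp, 0)))
  ends <- c(starts[-1] - 1L, n)
  ext <- abs0[ends] - c(0, abs0[ends[-length(ends)]])
  run_len <- rep.int(lens, lens)
  run_ext <- rep.int(ext, lens)
  len_raw <- ifelse(def, ifelse(indir, run_len, 0), NA_real_)
  dist_raw <- ifelse(def, ifelse(indir, run_ext, 0), NA_real_)
  w <- as.integer(round(window_s * rate))
  list(len_raw = len_raw, dist_raw = dist_raw,
       len_smooth = trailing_mean(len_raw, w),
       dist_smooth = trailing_mean(dist_raw, w))
}

#' Extract the three smoothed OKN variables from a raw gaze trace
#'
#' Full preprocessing chain: blink padding, fast/slow-phase segmentation,
#' smoothed slow-phase velocity, and smoothed fast-phase-direction run
#' length and extent, all on the native sampling grid of the trace. All
#' smoothing is trailing (causal), so values at time t never use samples
#' after t.
#'
#' @param trace a [gaze_trace()].
#' @param fast_dir fast-phase direction; `NULL` infers it from the median
#'   displacement during detected fast phases.
#' @param window_s trailing smoothing window in seconds.
#' @param run_smooth_ms position pre-smoothing for the run scanner (ms).
#' @param ... further arguments passed to [detect_fast_phases()].
#' @return an object of class `okn_variables`: list with `t`, `v_smooth`,
#'   `fp_len`, `fp_dist`, `labels`, `rate`, `fast_dir`.
#' @export
okn_variables <- function(trace, fast_dir = NULL, window_s = 1.0,
                          run_smooth_ms = 20, ...) {
  labels <- detect_fast_phases(trace, ...)
  if (is.null(fast_dir)) {
    d <- diff(trace$x)[labels[-1] == "fast"]
    d <- d[is.finite(d)]
    fast_dir <- if (length(d) && median(d) < 0) -1 else 1
  }
  vel <- compute_slow_velocity(trace, labels, window_s)
  runs <- compute_fastphase_runs(trace, labels, fast_dir, window_s,
                                 smooth_ms = run_smooth_ms)
  structure(
    list(t = trace$t, v_smooth = vel$smooth, fp_len = runs$len_smooth,
         fp_dist = runs$dist_smooth, labels = labels, rate = trace$rate,
         fast_dir = fast_dir),
    class = "okn_variables"
  )
}

#' @export
print.okn_variables <- function(x, ...) {
  cat(sprintf(
    "OKN variables: %.1f s at %g Hz (%.1f%% fast, %.1f%% missing), fast_dir = %+d\n",
    length(x$t) / x$rate, x$rate, 100 * mean(x$labels == "fast"),
    100 * mean(x$labels == "missing"), x$fast_dir))
  invisible(x)
}
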