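#' Parameters of the synthetic optokinetic nystagmus (OKN)
#'
#' Describes the sawtooth eye-movement pattern evoked by the drifting
#' pattern-component rivalry stimulus. Slow phases track the perceived
#' motion: the horizontal slow-phase velocity is higher during the
#' integrated (plaid) percept than during the segregated (component)
#' percept, and fast phases are longer in duration and extent during
#' integration. Velocity is signed with positive = stimulus direction, so
#' the fast-phase (resetting) direction is negative by default.
#'
#' @param v_int,v_seg slow-phase horizontal velocities in deg/s for the
#'   integrated and segregated states (`v_int > v_seg >= 0`; if not, a
#'   warning is raised because decoding becomes uninformative by
#'   construction).
#' @param fast_dir sign of the fast-phase direction (-1 or +1).
#' @param reset_ecc eccentricity in deg that triggers a fast phase.
#' @param fastphase_dur_int,fastphase_dur_seg mean fast-phase durations in
#'   ms per state.
#' @param fastphase_speed fast-phase speed in deg/s (extent = speed x
#'   duration, hence state-dependent).
#' @param dur_cv coefficient of variation of fast-phase durations.
#' @param noise_sd per-sample position noise in deg.
#' @param blink_rate blinks per minute.
#' @param blink_dur mean blink duration in ms.
#' @return an object of class `okn_params`.
#' @export
okn_params <- function(v_int = 1.9, v_seg = 0.5, fast_dir = -1,
                       reset_ecc = 2, fastphase_dur_int = 40,
                       fastphase_dur_seg = 25, fastphase_speed = 60,
                       dur_cv = 0.2, noise_sd = 0.01, blink_rate = 12,
                       blink_dur = 150) {
  if (!fast_dir %in% c(-1, 1))
    stop_bad_arg("`fast_dir` must be -1 or +1")
  if (v_seg < 0) stop_bad_arg("`v_seg` must be >= 0")
  if (v_int <= v_seg)
    warning("v_int <= v_seg: percept decoding is uninformative by construction",
            call. = FALSE)
  check_positive(reset_ecc, "reset_ecc")
  check_positive(fastphase_dur_int, "fastphase_dur_int")
  check_positive(fastphase_dur_seg, "fastphase_dur_seg")
  check_positive(fastphase_speed, "fastphase_speed")
  if (noise_sd < 0 || blink_rate < 0)
    stop_bad_arg("`noise_sd` and `blink_rate` must be >= 0")
  check_positive(blink_dur, "blink_dur")
  structure(
    list(v_int = v_int, v_seg = v_seg, fast_dir = fast_dir,
         reset_ecc = reset_ecc, fastphase_dur_int = fastphase_dur_int,
         fastphase_dur_seg = fastphase_dur_seg,
         fastphase_speed = fastphase_speed, dur_cv = dur_cv,
         noise_sd = noise_sd, blink_rate = blink_rate,
         blink_dur = blink_dur),
    class = "okn_params"
  )
}

#' Construct a gaze trace
#'
#' A timestamped horizontal eye-position trace on a uniform grid with a
#' per-sample validity mask (invalid = tracker lost the eye, e.g. blinks).
#'
#' @param t time in seconds (uniform grid).
#' @param x horizontal position in deg (`NA` allowed where invalid).
#' @param valid logical validity mask.
#' @param rate sampling rate in Hz.
#' @return an object of class `gaze_trace`.
#' @export
gaze_trace <- function(t, x, valid = is.finite(x), rate = NULL) {
  n <- length(t)
  stopifnot(length(x) == n, length(valid) == n)
  if (is.null(rate)) rate <- if (n > 1) 1 / (t[2] - t[1]) else 1000
  structure(list(t = as.numeric(t), x = as.numeric(x),
                 valid = as.logical(valid), rate = rate),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  cat(sprintf("gaze trace: %.1f s at %g Hz, %.2f%% samples missing\n",
              length(x$t) / x$rate, x$rate, 100 * mean(!x$valid)))
  invisible(x)
}

#' Simulate an OKN gaze trace from a latent percept trace
#'
#' Produces a sawtooth horizontal eye-position trace whose slow-phase
#' velocity and fast-phase duration/extent depend on the current percept,
#' with additive position noise and blink runs during which samples are
#' missing. Ground-truth per-sample percept states and slow/fast phase
#' labels are retained as attributes `state` and `phase` for segmentation
#' tests.
#'
#' @param latent a `percept_trace` (resampled to `rate` if needed).
#' @param okn an [okn_params()] object.
#' @param rate gaze sampling rate in Hz.
#' @param seed optional integer seed.
#' @return a [gaze_trace()].
#' @export
simulate_okn <- function(latent, okn = okn_params(), rate = 1000,
                         seed = NULL) {
  stopifnot(inherits(latent, "percept_trace"), inherits(okn, "okn_params"))
  with_seed_if(seed, {
    n_src <- length(latent$states)
    duration <- n_src / latent$rate
    n <- as.integer(round(duration * rate))
    idx <- pmin(n_src, floor((seq_len(n) - 1) / rate * latent$rate) + 1L)
    states <- latent$states[idx]
    sim <- okn_integrate(states, rate, okn$v_int, okn$v_seg, okn$fast_dir,
                         okn$reset_ecc, okn$fastphase_dur_int,
                         okn$fastphase_dur_seg, okn$dur_cv,
                         okn$fastphase_speed, okn$noise_sd,
                         start_pos = okn$fast_dir * okn$reset_ecc / 2)
    x <- sim$x
    valid <- rep(TRUE, n)
    if (okn$blink_rate > 0) {
      n_blink <- rpois(1, okn$blink_rate * duration / 60)
      if (n_blink > 0) {
        onset <- sort(as.integer(ceiling(runif(n_blink) * n)))
        durs <- pmax(1L, as.integer(round(
          rgamma(n_blink, shape = 4, scale = okn$blink_dur / 4) / 1000 * rate)))
        for (j in seq_len(n_blink)) {
          hi <- min(n, onset[j] + durs[j] - 1L)
          valid[onset[j]:hi] <- FALSE
        }
        x[!valid] <- NA_real_
      }
    }
    out <- gaze_trace(t = (seq_len(n) - 1) / rate, x = x, valid = valid,
                      rate = rate)
    attr(out, "state") <- states
    attr(out, "phase") <- ifelse(valid,
                                 c("slow", "fast")[sim$phase + 1L],
                                 "missing")
    out
  })
}
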