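#' Parameters of a bistable percept process for one modality
#'
#' Describes the alternating-renewal dynamics of one modality's bistable
#' perception and the fidelity of its button report.
#'
#' @param mean_dom mean dominance-phase duration in seconds. With the default
#'   gamma `shape` of 3, a 9-s mean gives a median phase of about 8 s.
#' @param shape shape parameter of the gamma dominance-duration distribution.
#' @param pi_seg stationary proportion of the segregated percept in `[0, 1]`.
#' @param kappa cross-modal coupling in `[0, 1]`: 1 = both modalities share
#'   one percept trace, 0 = independent.
#' @param eps_report probability that a perceptual phase is reported as the
#'   wrong percept.
#' @param lag_report report latency in seconds (button follows percept;
#'   0.35 s is a typical manual reaction time to an endogenous perceptual
#'   switch, and with the default `eps_report` it reproduces catch-trial
#'   hit rates in the mid-80s percent range).
#' @param gamma_gap fraction of time with no exclusive report (button gaps,
#'   placed around perceptual switches).
#' @return an object of class `percept_params`.
#' @export
percept_params <- function(mean_dom = 9, shape = 3, pi_seg = 0.5, kappa = 0.3,
                           eps_report = 0.07, lag_report = 0.35,
                           gamma_gap = 0.03) {
  check_positive(mean_dom, "mean_dom")
  check_positive(shape, "shape")
  check_prob(pi_seg, "pi_seg")
  check_prob(kappa, "kappa")
  check_prob(eps_report, "eps_report")
  check_prob(gamma_gap, "gamma_gap")
  if (!is.numeric(lag_report) || length(lag_report) != 1L ||
      !is.finite(lag_report) || lag_report < 0)
    stop_bad_arg("`lag_report` must be a single non-negative number of seconds")
  structure(
    list(mean_dom = mean_dom, shape = shape, pi_seg = pi_seg, kappa = kappa,
         eps_report = eps_report, lag_report = lag_report,
         gamma_gap = gamma_gap),
    class = "percept_params"
  )
}

new_percept_trace <- function(states, rate) {
  structure(list(states = as.integer(states), rate = rate),
            class = "percept_trace")
}

#' @export
print.percept_trace <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("percept trace: %.1f s at %g Hz, %.1f%% segregated\n",
              n / x$rate, x$rate, 100 * mean(x$states == 2L)))
  invisible(x)
}

# Alternating two-state renewal trace with gamma phase durations.
# `means` is c(mean duration state 1, mean duration state 2) in seconds;
# returns an integer vector of length round(duration * rate) with values 1/2.
renewal_states <- function(duration, rate, means, shape, p_start_2) {
  n <- as.integer(round(duration * rate))
  out <- integer(0)
  state <- if (runif(1) < p_start_2) 2L else 1L
  total <- 0L
  while (total < n) {
    dur <- max(1L, as.integer(round(
      rgamma(1, shape = shape, scale = means[state] / shape) * rate)))
    dur <- min(dur, n - total)
    out <- c(out, rep.int(state, dur))
    total <- total + dur
    state <- 3L - state
  }
  out
}

# State-dependent disagreement-flip probabilities for one modality.
# Solves  pi_c*(1-d_seg) + (1-pi_c)*d_int = pi_m   (occupancy)
#         pi_c*d_seg     + (1-pi_c)*d_int = delta  (mean flip probability)
# and clips to [0, 1] (exact only when the target is reachable, e.g. always
# in the symmetric pi case).
flip_probs <- function(pi_c, pi_m, delta) {
  d_seg <- (pi_c + delta - pi_m) / (2 * pi_c)
  d_int <- (delta - pi_c + pi_m) / (2 * (1 - pi_c))
  c(seg = min(max(d_seg, 0), 1), int = min(max(d_int, 0), 1))
}

# Apply the disagreement stage to a common trace for one modality.
apply_disagreement <- function(common, rate, kappa, pi_m, pi_c, mean_dom, shape) {
  delta <- (1 - kappa) / 2
  if (delta <= 0) return(common)                     # kappa = 1: identical
  d <- flip_probs(pi_c, pi_m, delta)
  d_max <- max(d)
  if (d_max <= 0) return(common)
  n <- length(common)
  # renewal windows of candidate disagreement with occupancy d_max
  win <- renewal_states(n / rate, rate,
                        means = c(mean_dom * (1 - d_max), mean_dom * d_max),
                        shape = shape, p_start_2 = d_max) == 2L
  # thin per overlap segment (window x common phase) to the state-dependent rate
  seg_id <- cumsum(c(TRUE, diff(common) != 0 | diff(win) != 0))
  first <- !duplicated(seg_id)
  keep_prob <- ifelse(common[first] == 2L, d["seg"], d["int"]) / d_max
  keep <- (runif(sum(first)) < keep_prob)[seg_id] & win
  out <- common
  out[keep] <- 3L - out[keep]
  out
}

#' Simulate coupled bistable percept traces for two modalities
#'
#' Generates a pair of latent percept traces (auditory, visual) from a shared
#' alternating-renewal process with gamma-distributed dominance durations,
#' combined with per-modality disagreement renewal processes. Each modality's
#' trace equals the common trace, flipped inside its disagreement windows;
#' the mean flip probability is `delta = (1 - kappa)/2`, so for symmetric
#' percept proportions the stationary cross-modal match probability is
#' `(1 + kappa_a * kappa_v)/2`. Flip probabilities are state-dependent so
#' that each modality attains its own stationary segregated proportion
#' `pi_seg` (exactly reachable whenever the asymmetry is compatible with the
#' coupling; at `kappa = 1` both traces are identical by construction).
#'
#' @param params_a,params_v [percept_params()] for the auditory and visual
#'   modality.
#' @param duration trace duration in seconds.
#' @param rate sampling rate in Hz.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return a list with `percept_trace` elements `auditory` and `visual`.
#' @examples
#' p <- percept_params(kappa = 1)
#' tr <- simulate_coupled_percepts(p, p, duration = 60, rate = 100, seed = 1)
#' identical(tr$auditory$states, tr$visual$states)
#' @export
simulate_coupled_percepts <- function(params_a, params_v, duration,
                                      rate = 100, seed = NULL) {
  stopifnot(inherits(params_a, "percept_params"),
            inherits(params_v, "percept_params"))
  check_positive(duration, "duration")
  check_positive(rate, "rate")
  with_seed_if(seed, {
    pi_c <- (params_a$pi_seg + params_v$pi_seg) / 2
    pi_c <- min(max(pi_c, 1e-3), 1 - 1e-3)
    mean_dom <- (params_a$mean_dom + params_v$mean_dom) / 2
    shape <- (params_a$shape + params_v$shape) / 2
    common <- renewal_states(duration, rate,
                             means = c(2 * mean_dom * (1 - pi_c),
                                       2 * mean_dom * pi_c),
                             shape = shape, p_start_2 = pi_c)
    a <- apply_disagreement(common, rate, params_a$kappa, params_a$pi_seg,
                            pi_c, mean_dom, shape)
    v <- apply_disagreement(common, rate, params_v$kappa, params_v$pi_seg,
                            pi_c, mean_dom, shape)
    list(auditory = new_percept_trace(a, rate),
         visual = new_percept_trace(v, rate))
  })
}

#' Simulate a single-modality percept trace
#'
#' Alternating-renewal trace with gamma dominance durations whose
#' state-dependent means are tuned so the segregated occupancy is `pi_seg`
#' and the overall mean dominance duration is `mean_dom`.
#'
#' @inheritParams simulate_coupled_percepts
#' @param params a [percept_params()] object.
#' @return a `percept_trace`.
#' @export
simulate_percepts <- function(params, duration, rate = 100, seed = NULL) {
  stopifnot(inherits(params, "percept_params"))
  check_positive(duration, "duration")
  with_seed_if(seed, {
    pi <- min(max(params$pi_seg, 1e-3), 1 - 1e-3)
    states <- renewal_states(duration, rate,
                             means = c(2 * params$mean_dom * (1 - pi),
                                       2 * params$mean_dom * pi),
                             shape = params$shape, p_start_2 = pi)
    new_percept_trace(states, rate)
  })
}

#' Realized reporting accuracy against the simulated ground truth
#'
#' Time-weighted accuracy of a report trace against the latent percept trace
#' it was generated from, compensating the report latency (so that pure
#' lag does not count as error, only mislabeling does). Only exclusive
#' report samples enter. This ground-truth quantity is available for
#' synthetic sessions only; experimental sessions estimate reporting
#' accuracy from catch trials instead.
#'
#' @param report a `report_trace`.
#' @param latent the `percept_trace` the report was simulated from.
#' @param lag_report the report latency used in [simulate_report()].
#' @return accuracy in `[0, 1]`.
#' @export
report_accuracy <- function(report, latent, lag_report = 0) {
  stopifnot(inherits(report, "report_trace"), inherits(latent, "percept_trace"),
            report$rate == latent$rate)
  n <- length(latent$states)
  k <- min(n, as.integer(round(lag_report * latent$rate)))
  shifted <- c(rep.int(latent$states[1], k), latent$states[seq_len(n - k)])
  ex <- report$states != 0L
  if (!any(ex)) stop_bad_arg("no exclusive report samples")
  mean(report$states[ex] == shifted[ex])
}

new_report_trace <- function(states, rate) {
  structure(list(states = as.integer(states), rate = rate),
            class = "report_trace")
}

#' @export
print.report_trace <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf(
    "report trace: %.1f s at %g Hz (%.1f%% integrated, %.1f%% segregated, %.1f%% none)\n",
    n / x$rate, x$rate, 100 * mean(x$states == 1L),
    100 * mean(x$states == 2L), 100 * mean(x$states == 0L)))
  invisible(x)
}

#' Simulate a button-report trace from a latent percept trace
#'
#' The latent trace is delayed by the report latency; each perceptual phase
#' is independently mislabeled with probability `eps_report`; gaps with no
#' exclusive report (state `none`) are inserted around perceptual switches
#' (where button releases occur in practice) until the expected none-fraction
#' is `gamma_gap`.
#'
#' @param latent a `percept_trace`.
#' @param eps_report per-phase mislabeling probability.
#' @param lag_report report latency in seconds.
#' @param gamma_gap target fraction of time with no exclusive report.
#' @param seed optional integer seed.
#' @return a `report_trace` with per-sample states in
#'   \{0 = none, 1 = integrated, 2 = segregated\}.
#' @export
simulate_report <- function(latent, eps_report = 0, lag_report = 0,
                            gamma_gap = 0, seed = NULL) {
  stopifnot(inherits(latent, "percept_trace"))
  check_prob(eps_report, "eps_report")
  check_prob(gamma_gap, "gamma_gap")
  with_seed_if(seed, {
    rate <- latent$rate
    n <- length(latent$states)
    lag_k <- as.integer(round(lag_report * rate))
    lag_k <- min(lag_k, n)
    states <- c(rep.int(latent$states[1], lag_k),
                latent$states[seq_len(n - lag_k)])
    # phase-wise mislabeling
    r <- rle(states)
    flip <- rbinom(length(r$lengths), 1, eps_report) == 1L
    r$values[flip] <- 3L - r$values[flip]
    states <- inverse.rle(r)
    # none-gaps centered on the (post-error) switches
    if (gamma_gap > 0) {
      bounds <- cumsum(rle(states)$lengths)
      bounds <- bounds[-length(bounds)]           # interior switch positions
      if (length(bounds) == 0L) bounds <- as.integer(round(n / 2))
      g <- gamma_gap * n / length(bounds)         # mean gap length in samples
      durs <- pmax(1, round(rgamma(length(bounds), shape = 2, scale = g / 2)))
      lo <- pmax(1L, as.integer(bounds - floor(durs / 2) + 1L))
      hi <- pmin(n, as.integer(lo + durs - 1L))
      for (j in seq_along(lo)) states[lo[j]:hi[j]] <- 0L
    }
    new_report_trace(states, rate)
  })
}
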