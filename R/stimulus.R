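#' Auditory streaming (ABA_) stimulus frequencies
#'
#' Computes the tone frequencies of an ABA_ auditory streaming stimulus from
#' its center frequency and the A-B separation in semitones, together with
#' the endpoint frequencies of the disambiguated (catch-trial) versions.
#' The center frequency `f_m` is the geometric mean of `f_A` and `f_B`
#' (equal ratios on a linear scale, equal distances in log frequency), and
#' the disambiguation endpoints extend the chain so that all four successive
#' ratios are identical:
#' `f_A/f_A_minus = f_m/f_A = f_B/f_m = f_B_plus/f_B`.
#'
#' @param f_m center frequency in Hz (geometric mean of the two tones).
#' @param s A-B frequency separation in semitones (>= 0).
#' @param tone_dur tone duration in ms.
#' @param gap inter-tone silence in ms.
#' @return an object of class `streaming_stimulus`: a list with elements
#'   `f_m`, `s`, `tone_dur`, `gap`, `soa` (stimulus onset asynchrony,
#'   `tone_dur + gap`), `f_A`, `f_B`, `f_A_minus`, `f_B_plus` (all Hz).
#' @examples
#' spec <- stream_frequencies(534, 7)
#' spec$f_B / spec$f_A            # 7 semitones = 2^(7/12)
#' stream_frequencies(534, 12)$soa
#' @export
stream_frequencies <- function(f_m = 534, s = 7, tone_dur = 130, gap = 20) {
  check_positive(f_m, "f_m")
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s < 0)
    stop_bad_arg("`s` must be a single non-negative number of semitones")
  check_positive(tone_dur, "tone_dur")
  if (!is.numeric(gap) || length(gap) != 1L || !is.finite(gap) || gap < 0)
    stop_bad_arg("`gap` must be a single non-negative number of ms")
  # each tone sits s/2 semitones (= s/24 octaves) from the geometric mean
  f_A <- f_m * 2^(-s / 24)
  f_B <- f_m * 2^(s / 24)
  structure(
    list(
      f_m = f_m, s = s, tone_dur = tone_dur, gap = gap,
      soa = tone_dur + gap,
      f_A = f_A, f_B = f_B,
      f_A_minus = f_A^2 / f_m,
      f_B_plus = f_B^2 / f_m
    ),
    class = "streaming_stimulus"
  )
}

#' @export
print.streaming_stimulus <- function(x, ...) {
  cat(sprintf(
    "ABA_ streaming stimulus: f_A = %.1f Hz, f_B = %.1f Hz (f_m = %.1f Hz, %.3g st)\n",
    x$f_A, x$f_B, x$f_m, x$s
  ))
  cat(sprintf("  disambiguation endpoints: f_A-d = %.1f Hz, f_B+d = %.1f Hz\n",
              x$f_A_minus, x$f_B_plus))
  cat(sprintf("  timing: %g-ms tones, %g-ms gaps (SOA %g ms)\n",
              x$tone_dur, x$gap, x$soa))
  invisible(x)
}
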