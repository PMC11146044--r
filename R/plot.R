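#' Plot per-participant consistency with its bounds
#'
#' Bar plot of the audio-visual consistency per participant (sorted by
#' theoretical maximum), overlaid with the theoretical and expected
#' maximum/minimum consistency bounds and the 50% chance line.
#'
#' @param summaries participant summary data.frame (columns `consistency`,
#'   `theo_max`, `theo_min`, `exp_max`, `exp_min`, all in percent).
#' @param ... further arguments to [graphics::barplot()].
#' @return the bar midpoints, invisibly.
#' @export
plot_consistency_bounds <- function(summaries, ...) {
  ord <- order(summaries$theo_max, decreasing = TRUE)
  s <- summaries[ord, ]
  mid <- graphics::barplot(s$consistency, names.arg = s$participant,
                           ylim = c(0, 100), col = "grey40",
                           xlab = "participant",
                           ylab = "consistency (%)", ...)
  graphics::abline(h = 50, lty = 2)
  graphics::lines(mid, s$theo_max, col = "black", lwd = 2)
  graphics::lines(mid, s$exp_max, col = "blue", lwd = 2)
  graphics::lines(mid, s$theo_min, col = "red", lwd = 2)
  graphics::lines(mid, s$exp_min, col = "cyan3", lwd = 2)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("black", "blue", "red", "cyan3"),
                   legend = c("theoretical max", "expected max",
                              "theoretical min", "expected min"))
  invisible(mid)
}
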