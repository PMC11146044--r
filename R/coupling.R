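#' Theoretical consistency bounds from percept asymmetry
#'
#' Extreme values of the class-adjusted consistency between the two
#' modalities' percepts, achievable given only the marginal segregated
#' proportions `a` (auditory) and `v` (visual). The joint occupancy of
#' (auditory segregated, visual segregated) has a single free parameter
#' bounded by the marginals; the balanced consistency is linear in it, so
#' the extremes are attained at the interval endpoints:
#' `theo_max = (min(a,v)/a + min(1-a,1-v)/(1-a)) / 2` and
#' `theo_min = (max(0,a+v-1)/a + max(0,1-a-v)/(1-a)) / 2`.
#' If one percept is more frequent in one modality than the other, the
#' consistency can reach neither 100% nor 0%.
#'
#' @param a auditory segregated proportion, in (0, 1).
#' @param v visual segregated proportion, in (0, 1).
#' @return list with `theo_max` and `theo_min`.
#' @export
theoretical_bounds <- function(a, v) {
  if (!is.finite(a) || a <= 0 || a >= 1 || !is.finite(v) || v <= 0 || v >= 1)
    stop_bad_arg("`a` and `v` must lie strictly inside (0, 1): the per-class ",
                 "accuracy ratio is undefined at 0 or 1")
  list(
    theo_max = (min(a, v) / a + min(1 - a, 1 - v) / (1 - a)) / 2,
    theo_min = (max(0, a + v - 1) / a + max(0, 1 - a - v) / (1 - a)) / 2
  )
}

#' Expected consistency bounds under imperfect decoding and reporting
#'
#' Attenuates the theoretical bounds by the visual decoding accuracy `d`
#' and the auditory reporting accuracy `r`. When the true percepts match,
#' the decoded visual label is consistent with the auditory report if
#' either both channels are correct or both are incorrect (two classes),
#' and channel errors are assumed independent, giving the match-transmission
#' probability `q = d*r + (1-d)*(1-r)`. The per-class true-match proportions
#' at each theoretical extreme are mapped through `m -> m*q + (1-m)*(1-q)`
#' and averaged.
#'
#' @inheritParams theoretical_bounds
#' @param d visual decoding accuracy in `[0, 1]` (estimated from the
#'   unimodal visual evaluation accuracy).
#' @param r auditory reporting accuracy in `[0, 1]` (estimated from the
#'   auditory catch-trial hit rate in bimodal blocks).
#' @return list with `exp_max`, `exp_min` and `q`.
#' @export
expected_bounds <- function(a, v, d, r) {
  check_prob(d, "d")
  check_prob(r, "r")
  if (!is.finite(a) || a <= 0 || a >= 1 || !is.finite(v) || v <= 0 || v >= 1)
    stop_bad_arg("`a` and `v` must lie strictly inside (0, 1)")
  q <- d * r + (1 - d) * (1 - r)
  g <- function(m) m * q + (1 - m) * (1 - q)
  x_max <- min(a, v)
  x_min <- max(0, a + v - 1)
  per_class <- function(x) c(seg = x / a, int = (1 - a - v + x) / (1 - a))
  list(
    exp_max = mean(g(per_class(x_max))),
    exp_min = mean(g(per_class(x_min))),
    q = q
  )
}

#' All four consistency bounds for one participant
#'
#' @inheritParams expected_bounds
#' @return an object of class `bounds_result`: list with `a`, `v`, `d`,
#'   `r`, `q`, `theo_max`, `theo_min`, `exp_max`, `exp_min`.
#' @export
consistency_bounds <- function(a, v, d, r) {
  tb <- theoretical_bounds(a, v)
  eb <- expected_bounds(a, v, d, r)
  structure(c(list(a = a, v = v, d = d, r = r, q = eb$q), tb,
              eb[c("exp_max", "exp_min")]),
            class = "bounds_result")
}

#' @export
print.bounds_result <- function(x, ...) {
  cat(sprintf(
    "consistency bounds (a=%.3f, v=%.3f, d=%.3f, r=%.3f, q=%.3f):\n",
    x$a, x$v, x$d, x$r, x$q))
  cat(sprintf("  theoretical [%.3f, %.3f], expected [%.3f, %.3f]\n",
              x$theo_min, x$theo_max, x$exp_min, x$exp_max))
  invisible(x)
}

#' Moment-by-moment audio-visual consistency
#'
#' For every (decoder model, bimodal block) pair, decodes the visual percept
#' from the block's eye-movement features and scores it with the
#' class-adjusted accuracy against the simultaneous auditory report, treating
#' the auditory labels as if they referred to the corresponding visual
#' percept (auditory integrated/segregated mapped to visual
#' integrated/segregated). The resulting model-by-block matrix (6 x 8 for
#' the default design) is averaged into a participant-level consistency.
#' Blocks whose auditory report lacks a class leave the cell undefined; such
#' cells are excluded from the mean with a warning.
#'
#' @param models list of `decoder_model`s from [run_role_permutations()].
#' @param blocks list of bimodal blocks, each a list with `features`
#'   (a [feature_matrix()]) and `labels` (auditory report labels, `NA` =
#'   excluded).
#' @return an object of class `consistency_result`: list with `matrix`
#'   (models x blocks), `acc_seg`, `acc_int` matrices, `mean`, `n_defined`.
#' @export
compute_consistency <- function(models, blocks) {
  stopifnot(length(models) >= 1L, length(blocks) >= 1L)
  M <- matrix(NA_real_, nrow = length(models), ncol = length(blocks))
  As <- Ai <- M
  for (b in seq_along(blocks)) {
    lab <- blocks[[b]]$labels
    classes_ok <- all(PERCEPT_LEVELS %in% as.character(lab[!is.na(lab)]))
    if (!classes_ok) {
      warning("bimodal block ", b,
              ": auditory report lacks a class; cell(s) undefined",
              call. = FALSE)
      next
    }
    # models that share a training block share standardization statistics
    keys <- vapply(seq_along(models), function(m) {
      mod <- models[[m]]
      if (!is.null(mod$roles) && !is.null(mod$stats))
        paste0("t", mod$roles[["train"]]) else paste0("m", m)
    }, character(1))
    cache <- list()
    for (m in seq_along(models)) {
      mod <- models[[m]]
      if (is.null(cache[[keys[m]]])) {
        cache[[keys[m]]] <- if (!is.null(mod$stats))
          standardize_features(blocks[[b]]$features, mod$stats)
        else blocks[[b]]$features
      }
      res <- balanced_accuracy(decode_timecourse(mod, cache[[keys[m]]]), lab)
      M[m, b] <- res$balanced
      As[m, b] <- res$acc_seg
      Ai[m, b] <- res$acc_int
    }
  }
  structure(
    list(matrix = M, acc_seg = As, acc_int = Ai,
         mean = mean(M, na.rm = TRUE), n_defined = sum(!is.na(M))),
    class = "consistency_result"
  )
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf(
    "consistency: %d models x %d blocks (%d defined cells), mean %.3f\n",
    nrow(x$matrix), ncol(x$matrix), x$n_defined, x$mean))
  invisible(x)
}

#' Percept proportions of a report trace
#'
#' Proportions of the two percepts relative to the summed time of exclusive
#' reporting (they add to 1), plus the exclusive fraction of total time.
#'
#' @param report a `report_trace`.
#' @param window optional `c(start, end)` in seconds restricting the
#'   analysis (e.g. the multistable part of a block).
#' @return list with `prop_seg`, `prop_int`, `exclusive_fraction`.
#' @export
percept_proportions <- function(report, window = NULL) {
  stopifnot(inherits(report, "report_trace"))
  st <- report_window(report, window)
  ex <- st != 0L
  if (!any(ex))
    stop_bad_arg("percept proportions undefined: no exclusive report")
  list(prop_seg = sum(st == 2L) / sum(ex),
       prop_int = sum(st == 1L) / sum(ex),
       exclusive_fraction = mean(ex))
}

report_window <- function(report, window) {
  st <- report$states
  if (!is.null(window)) {
    lo <- max(1L, as.integer(floor(window[1] * report$rate)) + 1L)
    hi <- min(length(st), as.integer(ceiling(window[2] * report$rate)))
    st <- st[lo:hi]
  }
  st
}

#' Median dominance-phase duration of a report trace
#'
#' Median over the durations of maximal constant-percept phases; periods
#' without an exclusive report end a phase and are not counted.
#'
#' @inheritParams percept_proportions
#' @return median phase duration in seconds.
#' @export
median_phase_duration <- function(report, window = NULL) {
  stopifnot(inherits(report, "report_trace"))
  st <- report_window(report, window)
  r <- rle(st)
  dur <- r$lengths[r$values != 0L] / report$rate
  if (length(dur) == 0L)
    stop_bad_arg("median phase duration undefined: no exclusive phases")
  median(dur)
}

#' Group-level statistics
#'
#' One-sample two-tailed t-test against a reference (e.g. the 50% chance
#' level), paired t-test for condition contrasts, or Pearson correlation
#' for cross-participant proportion comparisons. All tests are two-tailed;
#' no multiple-testing correction is applied.
#'
#' @param values numeric vector (one value per participant).
#' @param reference reference value for the one-sample test.
#' @param paired_with second vector for `method = "paired"` or
#'   `method = "pearson"`.
#' @param method `"one_sample"`, `"paired"` or `"pearson"`.
#' @return a one-row data.frame of class `group_stats` with columns `test`,
#'   `statistic`, `df`, `p`, `estimate`, `n`.
#' @export
group_tests <- function(values, reference = 50, paired_with = NULL,
                        method = c("one_sample", "paired", "pearson")) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 2L) stop_bad_arg("at least 2 values are required")
  if (method == "one_sample") {
    if (sd(values) == 0) {
      if (all(values == reference)) {
        warning("zero variance: values identical to the reference",
                call. = FALSE)
        return(group_stats_row("one_sample_t", 0, n - 1L, 1,
                               mean(values) - reference, n))
      }
      stop_bad_arg("one-sample t-test undefined: zero variance with mean != reference")
    }
    tt <- t.test(values, mu = reference)
    return(group_stats_row("one_sample_t", unname(tt$statistic),
                           unname(tt$parameter), tt$p.value,
                           mean(values) - reference, n))
  }
  if (is.null(paired_with) || length(paired_with) != n)
    stop_bad_arg("`paired_with` must have the same length as `values`")
  if (method == "paired") {
    diffs <- values - paired_with
    if (sd(diffs) == 0) {
      if (all(diffs == 0)) {
        warning("zero variance: paired differences are all zero",
                call. = FALSE)
        return(group_stats_row("paired_t", 0, n - 1L, 1, 0, n))
      }
      stop_bad_arg("paired t-test undefined: constant nonzero differences")
    }
    tt <- t.test(values, paired_with, paired = TRUE)
    return(group_stats_row("paired_t", unname(tt$statistic),
                           unname(tt$parameter), tt$p.value, mean(diffs), n))
  }
  if (sd(values) == 0 || sd(paired_with) == 0)
    stop_bad_arg("correlation undefined: zero variance")
  ct <- cor.test(values, paired_with)
  group_stats_row("pearson", unname(ct$statistic), unname(ct$parameter),
                  ct$p.value, unname(ct$estimate), n)
}

group_stats_row <- function(test, statistic, df, p, estimate, n) {
  structure(
    data.frame(test = test, statistic = statistic, df = df, p = p,
               estimate = estimate, n = n, stringsAsFactors = FALSE),
    class = c("group_stats", "data.frame")
  )
}
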