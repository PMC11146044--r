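#' Day-2 session design
#'
#' Ordered block list of a main session. The default reproduces the paper
#' paradigm's layout: three unimodal visual blocks (before, halfway through,
#' and after the bimodal condition), two unimodal auditory blocks, and eight
#' bimodal blocks, each with a 180-s multistable part seamlessly followed by
#' a 30-s disambiguated part. The disambiguated stimulus alternates between
#' suggesting an integrated and a segregated percept, so that each percept
#' is suggested twice (for about 7.5 s); in bimodal blocks the disambiguated
#' modality alternates between visual and auditory (four blocks each).
#'
#' @param n_visual,n_auditory,n_bimodal block counts per condition.
#' @param multistable_dur multistable-part duration in seconds.
#' @param disambig_dur disambiguated-part duration in seconds.
#' @return an object of class `session_design`: a data.frame with one row
#'   per block (`block`, `condition`, `disambig_modality`,
#'   `schedule_start`), with durations as attributes.
#' @export
session_design <- function(n_visual = 3, n_auditory = 2, n_bimodal = 8,
                           multistable_dur = 180, disambig_dur = 30) {
  check_positive(multistable_dur, "multistable_dur")
  check_positive(disambig_dur, "disambig_dur")
  cond <- if (n_visual == 3 && n_auditory == 2 && n_bimodal == 8) {
    c("unimodal_visual", "unimodal_auditory", rep("bimodal", 4),
      "unimodal_visual", rep("bimodal", 4), "unimodal_auditory",
      "unimodal_visual")
  } else {
    c(rep("unimodal_visual", n_visual), rep("unimodal_auditory", n_auditory),
      rep("bimodal", n_bimodal))
  }
  dis <- character(length(cond))
  dis[cond == "unimodal_visual"] <- "visual"
  dis[cond == "unimodal_auditory"] <- "auditory"
  bi <- which(cond == "bimodal")
  dis[bi] <- rep(c("visual", "auditory"), length.out = length(bi))
  out <- data.frame(
    block = seq_along(cond), condition = cond, disambig_modality = dis,
    schedule_start = rep(PERCEPT_LEVELS, length.out = length(cond)),
    stringsAsFactors = FALSE
  )
  attr(out, "multistable_dur") <- multistable_dur
  attr(out, "disambig_dur") <- disambig_dur
  class(out) <- c("session_design", "data.frame")
  out
}

# 4-segment alternating disambiguation schedule (each percept twice).
disambig_schedule <- function(multistable_dur, disambig_dur, start_state) {
  seg <- disambig_dur / 4
  onsets <- multistable_dur + seg * 0:3
  first <- match(start_state, PERCEPT_LEVELS)
  states <- PERCEPT_LEVELS[rep(c(first, 3L - first), 2)]
  data.frame(onset = onsets, offset = onsets + seg, state = states,
             stringsAsFactors = FALSE)
}

# Overwrite the disambiguated tail of a latent trace with the schedule,
# entering each suggested state only after a short transition lag.
force_schedule <- function(latent, schedule, lag = 0.3) {
  states <- latent$states
  rate <- latent$rate
  n <- length(states)
  prev <- states[max(1L, as.integer(floor(schedule$onset[1] * rate)))]
  for (j in seq_len(nrow(schedule))) {
    lo <- as.integer(floor((schedule$onset[j] + lag) * rate)) + 1L
    hi <- min(n, as.integer(ceiling(schedule$offset[j] * rate)))
    hold_lo <- as.integer(floor(schedule$onset[j] * rate)) + 1L
    if (hold_lo <= min(lo - 1L, n))
      states[hold_lo:min(lo - 1L, n)] <- prev
    if (lo <= hi) {
      states[lo:hi] <- match(schedule$state[j], PERCEPT_LEVELS)
      prev <- states[hi]
    }
  }
  new_percept_trace(states, rate)
}

#' Build a complete synthetic day-2 session
#'
#' Generates, for every block of the design, the latent percept trace(s),
#' the button report (visual report in unimodal visual blocks, auditory
#' report in unimodal auditory and bimodal blocks), the OKN gaze trace
#' (whenever the visual stimulus is shown), and the disambiguation schedule.
#' In the disambiguated tail the forced modality's latent state follows the
#' schedule with a 300-ms transition lag, so catch-trial scoring has a
#' well-defined ground truth. Per-block seeds are derived from `seed` with
#' the documented counter scheme ([sub_seed()]), so any block is
#' regenerable in isolation. Identical seeds yield bit-identical sessions.
#'
#' @param design a [session_design()].
#' @param params_a,params_v [percept_params()] per modality.
#' @param okn an [okn_params()] object.
#' @param seed integer master seed for the session.
#' @param gaze_rate gaze sampling rate in Hz.
#' @param latent_rate latent/report sampling rate in Hz.
#' @return an object of class `synthetic_session`: list with `design`,
#'   `blocks` (each holding `condition`, `disambig_modality`, `latent`,
#'   `report`, `report_modality`, `gaze`, `schedule`, `seed`), and `seed`.
#' @export
build_session <- function(design, params_a = percept_params(),
                          params_v = percept_params(), okn = okn_params(),
                          seed = 1, gaze_rate = 1000, latent_rate = 1000) {
  stopifnot(inherits(design, "session_design"))
  mdur <- attr(design, "multistable_dur")
  ddur <- attr(design, "disambig_dur")
  total <- mdur + ddur
  blocks <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    bseed <- sub_seed(seed, i)
    cond <- design$condition[i]
    dis_mod <- design$disambig_modality[i]
    schedule <- disambig_schedule(mdur, ddur, design$schedule_start[i])
    block <- withr::with_seed(bseed, {
      latent <- list()
      if (cond == "bimodal") {
        lat <- simulate_coupled_percepts(params_a, params_v, total,
                                         rate = latent_rate)
        latent$auditory <- lat$auditory
        latent$visual <- lat$visual
      } else if (cond == "unimodal_visual") {
        latent$visual <- simulate_percepts(params_v, total, rate = latent_rate)
      } else {
        latent$auditory <- simulate_percepts(params_a, total,
                                             rate = latent_rate)
      }
      forced <- if (dis_mod == "visual") "visual" else "auditory"
      if (!is.null(latent[[forced]]))
        latent[[forced]] <- force_schedule(latent[[forced]], schedule)
      report_modality <- if (cond == "unimodal_visual") "visual" else
        "auditory"
      rp <- if (report_modality == "visual") params_v else params_a
      report <- simulate_report(latent[[report_modality]], rp$eps_report,
                                rp$lag_report, rp$gamma_gap)
      gaze <- if (!is.null(latent$visual))
        simulate_okn(latent$visual, okn, rate = gaze_rate)
      list(condition = cond, disambig_modality = dis_mod, latent = latent,
           report = report, report_modality = report_modality, gaze = gaze,
           schedule = schedule, seed = bseed)
    })
    blocks[[i]] <- block
  }
  structure(list(design = design, blocks = blocks, seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  tab <- table(x$design$condition)
  cat(sprintf("synthetic session: %d blocks (%s), seed %d\n",
              nrow(x$design),
              paste(names(tab), tab, sep = " = ", collapse = ", "), x$seed))
  invisible(x)
}

#' Write a gaze trace as a delimited text file
#'
#' Columns `time_s`, `x_deg`, `valid` (0/1); the ingestion contract for
#' real exports converted upstream.
#'
#' @param trace a [gaze_trace()].
#' @param path output file.
#' @export
write_gaze_trace <- function(trace, path) {
  data.table::fwrite(
    data.table::data.table(time_s = trace$t,
                           x_deg = round(trace$x, 6),
                           valid = as.integer(trace$valid)),
    path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a gaze trace written by [write_gaze_trace()]
#'
#' @param path input file.
#' @return a [gaze_trace()].
#' @export
read_gaze_trace <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  gaze_trace(d$time_s, d$x_deg, d$valid == 1L)
}

#' Write a report trace as an event table
#'
#' Columns `onset_s`, `offset_s`, `state`; periods without an exclusive
#' report are simply absent from the table.
#'
#' @param report a `report_trace`.
#' @param path output file.
#' @export
write_report_events <- function(report, path) {
  r <- rle(report$states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  data.table::fwrite(
    data.table::data.table(
      onset_s = (starts[keep] - 1L) / report$rate,
      offset_s = ends[keep] / report$rate,
      state = PERCEPT_LEVELS[r$values[keep]]),
    path, sep = "\t")
  invisible(path)
}

#' Read a report event table back into a report trace
#'
#' @param path input file.
#' @param rate sampling rate of the reconstructed trace in Hz.
#' @param duration trace duration in seconds (defaults to the last offset).
#' @return a `report_trace`.
#' @export
read_report_events <- function(path, rate = 1000, duration = NULL) {
  d <- data.table::fread(path, sep = "\t")
  duration <- duration %||% max(d$offset_s)
  n <- as.integer(round(duration * rate))
  st <- integer(n)
  for (j in seq_len(nrow(d))) {
    lo <- as.integer(round(d$onset_s[j] * rate)) + 1L
    hi <- min(n, as.integer(round(d$offset_s[j] * rate)))
    if (lo <= hi) st[lo:hi] <- match(d$state[j], PERCEPT_LEVELS)
  }
  new_report_trace(st, rate)
}

#' Write a session to disk
#'
#' Writes per-block gaze traces (delimited text), report event tables and a
#' JSON manifest (block order, conditions, schedules, seeds).
#'
#' @param session a `synthetic_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = session$seed, n_blocks = nrow(session$design),
                   blocks = list())
  for (i in seq_along(session$blocks)) {
    b <- session$blocks[[i]]
    stem <- file.path(dir, sprintf("block%02d", i))
    if (!is.null(b$gaze)) write_gaze_trace(b$gaze, paste0(stem, "_gaze.tsv"))
    write_report_events(b$report, paste0(stem, "_report.tsv"))
    manifest$blocks[[i]] <- list(
      block = i, condition = b$condition,
      disambig_modality = b$disambig_modality,
      report_modality = b$report_modality, seed = b$seed,
      schedule = b$schedule,
      duration_s = length(b$report$states) / b$report$rate,
      has_gaze = !is.null(b$gaze))
  }
  jsonlite::write_json(manifest, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
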