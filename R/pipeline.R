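default_config <- function() {
  list(
    participants = 1L,
    seed = 1L,
    design = list(n_visual = 3, n_auditory = 2, n_bimodal = 8,
                  multistable_dur = 180, disambig_dur = 30),
    percept = list(auditory = unclass(percept_params()),
                   visual = unclass(percept_params())),
    okn = unclass(okn_params()),
    preprocess = list(vel_thresh = 22, min_dur_ms = 4, merge_gap_ms = 20,
                      smooth_ms = 10, low_thresh = 10, pad_ms = 50,
                      run_smooth_ms = 20, window_s = 1),
    features = list(rate = 100, lag_min = -2, lag_step = 0.1,
                    standardize = TRUE),
    svm = list(cost_grid = okn_cost_grid(), stride = 1),
    inclusion = list(hit_rate = 70, decoding = 70)
  )
}

#' Pipeline run configuration
#'
#' Bundles every simulator, preprocessing, feature, SVM and bounds parameter
#' together with the master seed. The defaults reproduce the reference
#' settings: 1000-Hz gaze, 100-Hz features with lags -2.0 to 0 s in 100-ms
#' steps (63 dimensions), the 11-value cost grid, and the 3 unimodal visual /
#' 2 unimodal auditory / 8 bimodal block design with 180-s multistable and
#' 30-s disambiguated parts. Any nested field can be overridden, e.g.
#' `run_config(participants = 4, svm = list(stride = 10))`.
#'
#' @param ... named overrides merged recursively into the defaults.
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- modifyList(default_config(), list(...))
  cfg$participants <- as.integer(cfg$participants)
  cfg$seed <- as.integer(cfg$seed)
  # validate through the constructors
  do.call(percept_params, cfg$percept$auditory)
  do.call(percept_params, cfg$percept$visual)
  do.call(okn_params, cfg$okn)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration (YAML or JSON by file extension)
#'
#' @param config a [run_config()].
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `path` / the re-read `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unclass(config), path, precision = 15)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

config_percept <- function(config, modality)
  do.call(percept_params, config$percept[[modality]])

config_okn <- function(config) do.call(okn_params, config$okn)

config_design <- function(config)
  do.call(session_design, config$design)

# ---- shared in-memory analysis helpers -------------------------------------

#' OKN variables and labelled features for one block
#'
#' Convenience wrapper chaining [okn_variables()], [assemble_features()] and
#' [align_labels()] with the parameters of a [run_config()].
#'
#' @param gaze a [gaze_trace()].
#' @param report a `report_trace` for the reporting modality of the block.
#' @param config a [run_config()].
#' @return a list with `features` (a [feature_matrix()]) and `labels`.
#' @export
extract_block_features <- function(gaze, report, config = run_config()) {
  pp <- config$preprocess
  okn <- okn_variables(gaze, fast_dir = config$okn$fast_dir,
                       window_s = pp$window_s,
                       run_smooth_ms = pp$run_smooth_ms,
                       vel_thresh = pp$vel_thresh,
                       min_dur_ms = pp$min_dur_ms,
                       merge_gap_ms = pp$merge_gap_ms,
                       smooth_ms = pp$smooth_ms, low_thresh = pp$low_thresh,
                       pad_ms = pp$pad_ms)
  ft <- assemble_features(okn, rate = config$features$rate,
                          lag_min = config$features$lag_min,
                          lag_step = config$features$lag_step)
  list(features = ft, labels = align_labels(ft, report))
}

# restrict labels to the multistable part (exclude the disambiguated tail)
multistable_labels <- function(block_ft, multistable_dur) {
  lab <- block_ft$labels
  lab[block_ft$features$time >= multistable_dur] <- NA
  lab
}

#' Train the six percept decoders of a session
#'
#' Extracts labelled features from the session's unimodal visual blocks
#' (multistable parts only) and runs the block-role permutation scheme.
#'
#' @param session a `synthetic_session` containing 3 unimodal visual blocks.
#' @param config a [run_config()].
#' @return list of 6 `decoder_model`s.
#' @export
train_decoders <- function(session, config = run_config()) {
  idx <- which(session$design$condition == "unimodal_visual")
  mdur <- attr(session$design, "multistable_dur")
  blocks <- lapply(idx, function(i) {
    b <- session$blocks[[i]]
    ft <- extract_block_features(b$gaze, b$report, config)
    list(features = ft$features,
         labels = multistable_labels(ft, mdur))
  })
  run_role_permutations(blocks, cost_grid = config$svm$cost_grid,
                        stride = config$svm$stride,
                        standardize = config$features$standardize)
}

#' Full coupling analysis of one synthetic participant
#'
#' Computes everything the participant summary needs: catch-trial hit rates
#' (visual and auditory, unimodal and bimodal), percept proportions, median
#' phase durations, the 6 x n_bimodal consistency matrix against the
#' auditory report, and the four consistency bounds from the realized
#' asymmetries (a, v), decoding accuracy d (mean unimodal evaluation
#' accuracy) and reporting accuracy r (bimodal auditory catch-trial hit
#' rate).
#'
#' @param session a `synthetic_session`.
#' @param models decoders from [train_decoders()].
#' @param config a [run_config()].
#' @param participant participant index recorded in the summary.
#' @return a list with `summary` (one-row data.frame), `consistency`
#'   (a `consistency_result`) and `bounds` (a `bounds_result`).
#' @export
analyze_session <- function(session, models, config = run_config(),
                            participant = 1L) {
  design <- session$design
  mdur <- attr(design, "multistable_dur")
  win <- c(0, mdur)
  cond <- design$condition
  vis <- which(cond == "unimodal_visual")
  aud <- which(cond == "unimodal_auditory")
  bim <- which(cond == "bimodal")

  hit <- function(i) score_hit_rate(session$blocks[[i]]$report,
                                    session$blocks[[i]]$schedule)
  visual_hit <- mean(vapply(vis, hit, numeric(1)))
  auditory_hit_unimodal <- if (length(aud)) mean(vapply(aud, hit, numeric(1)))
    else NA_real_
  bim_aud <- bim[design$disambig_modality[bim] == "auditory"]
  auditory_hit_bimodal <- if (length(bim_aud))
    mean(vapply(bim_aud, hit, numeric(1))) else NA_real_

  prop_v <- percept_mean(session, vis, win)
  prop_a_uni <- percept_mean(session, aud, win)
  prop_a_bim <- percept_mean(session, bim, win)

  d <- mean(vapply(models, function(m) m$eval_accuracy, numeric(1)))

  bft <- lapply(bim, function(i) {
    b <- session$blocks[[i]]
    ft <- extract_block_features(b$gaze, b$report, config)
    list(features = ft$features, labels = multistable_labels(ft, mdur))
  })
  consistency <- compute_consistency(models, bft)

  a <- prop_a_bim["prop_seg"]
  v <- prop_v["prop_seg"]
  # reporting accuracy: bimodal auditory catch trials, falling back to the
  # unimodal auditory hit rate when the design has no such blocks
  r_pct <- if (is.finite(auditory_hit_bimodal)) auditory_hit_bimodal else
    auditory_hit_unimodal
  r <- if (is.finite(r_pct)) min(max(r_pct / 100, 0), 1) else NA_real_
  bounds <- if (is.finite(r))
    consistency_bounds(clamp01(a), clamp01(v), d, r)
  else
    structure(list(a = clamp01(a), v = clamp01(v), d = d, r = NA_real_,
                   q = NA_real_, theo_max = NA_real_, theo_min = NA_real_,
                   exp_max = NA_real_, exp_min = NA_real_),
              class = "bounds_result")

  med_bim <- mean(vapply(bim, function(i)
    median_phase_duration(session$blocks[[i]]$report, win), numeric(1)))
  med_aud <- if (length(aud)) mean(vapply(aud, function(i)
    median_phase_duration(session$blocks[[i]]$report, win), numeric(1)))
    else NA_real_

  summary <- data.frame(
    participant = participant,
    visual_hit = visual_hit,
    auditory_hit_unimodal = auditory_hit_unimodal,
    auditory_hit_bimodal = auditory_hit_bimodal,
    decoding_accuracy = 100 * d,
    prop_seg_visual = 100 * unname(v),
    prop_seg_auditory_unimodal = 100 * unname(prop_a_uni["prop_seg"]),
    prop_seg_auditory_bimodal = 100 * unname(a),
    exclusive_visual = 100 * unname(prop_v["exclusive_fraction"]),
    exclusive_auditory_bimodal = 100 * unname(prop_a_bim["exclusive_fraction"]),
    median_phase_bimodal = med_bim,
    median_phase_auditory_unimodal = med_aud,
    consistency = 100 * consistency$mean,
    theo_max = 100 * bounds$theo_max, theo_min = 100 * bounds$theo_min,
    exp_max = 100 * bounds$exp_max, exp_min = 100 * bounds$exp_min,
    stringsAsFactors = FALSE
  )
  list(summary = summary, consistency = consistency, bounds = bounds)
}

clamp01 <- function(x, eps = 1e-6) min(max(as.numeric(x), eps), 1 - eps)

percept_mean <- function(session, idx, win) {
  if (!length(idx))
    return(c(prop_seg = NA_real_, prop_int = NA_real_,
             exclusive_fraction = NA_real_))
  m <- vapply(idx, function(i) {
    p <- percept_proportions(session$blocks[[i]]$report, win)
    c(prop_seg = p$prop_seg, prop_int = p$prop_int,
      exclusive_fraction = p$exclusive_fraction)
  }, numeric(3))
  rowMeans(m)
}

#' Participant inclusion criteria
#'
#' A participant is included iff the visual catch-trial hit rate, the
#' auditory catch-trial hit rate (unimodal blocks) and the mean visual
#' decoding accuracy all reach their thresholds (70% each by default);
#' each failed criterion is flagged separately.
#'
#' @param summaries summary data.frame from [run_pipeline()] /
#'   [analyze_session()] (columns `visual_hit`, `auditory_hit_unimodal`,
#'   `decoding_accuracy`).
#' @param hit_rate,decoding thresholds in percent.
#' @return `summaries` with added logical columns `fail_visual_hit`,
#'   `fail_auditory_hit`, `fail_decoding`, `included`.
#' @export
apply_inclusion_criteria <- function(summaries, hit_rate = 70,
                                     decoding = 70) {
  need <- c("visual_hit", "auditory_hit_unimodal", "decoding_accuracy")
  if (!all(need %in% names(summaries)))
    stop_bad_arg("summaries must contain columns: ",
                 paste(setdiff(need, names(summaries)), collapse = ", "))
  summaries$fail_visual_hit <- !(summaries$visual_hit >= hit_rate)
  summaries$fail_auditory_hit <- !(summaries$auditory_hit_unimodal >= hit_rate)
  summaries$fail_decoding <- !(summaries$decoding_accuracy >= decoding)
  summaries$included <- !(summaries$fail_visual_hit |
                            summaries$fail_auditory_hit |
                            summaries$fail_decoding)
  summaries
}
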