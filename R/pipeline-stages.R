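# File-based staged pipeline: every stage consumes only the run directory's
# config plus files written by earlier stages, so deleting intermediate
# outputs and re-running a stage regenerates them identically.

PIPELINE_STAGES <- c("simulate", "preprocess", "features", "train", "decode",
                     "couple", "report")

pdir <- function(run_dir, p) file.path(run_dir, sprintf("p%02d", p))

log_line <- function(run_dir, ...) {
  cat(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...), "\n",
      sep = "", file = file.path(run_dir, "log.txt"), append = TRUE)
}

read_config_from <- function(run_dir) {
  path <- file.path(run_dir, "config.json")
  if (!file.exists(path))
    stop_bad_arg("no config.json in ", run_dir, "; run `run_pipeline()` or ",
                 "write one with `write_run_config()`")
  read_run_config(path)
}

read_session_manifest <- function(run_dir, p) {
  jsonlite::read_json(file.path(pdir(run_dir, p), "session.json"),
                      simplifyVector = TRUE)
}

#' Write / read the three smoothed OKN variables as a delimited table
#'
#' Columns `time_s`, `v_smooth`, `fp_len`, `fp_dist`, `label`.
#'
#' @param okn an [okn_variables()] object.
#' @param path file path.
#' @export
write_okn_variables <- function(okn, path) {
  data.table::fwrite(
    data.table::data.table(time_s = okn$t,
                           v_smooth = okn$v_smooth,
                           fp_len = okn$fp_len,
                           fp_dist = okn$fp_dist,
                           label = as.character(okn$labels)),
    path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_okn_variables
#' @param fast_dir fast-phase direction recorded with the table.
#' @export
read_okn_variables <- function(path, fast_dir = -1) {
  d <- data.table::fread(path, sep = "\t")
  rate <- if (nrow(d) > 1) 1 / (d$time_s[2] - d$time_s[1]) else 1000
  structure(
    list(t = d$time_s, v_smooth = d$v_smooth, fp_len = d$fp_len,
         fp_dist = d$fp_dist,
         labels = factor(d$label, levels = c("slow", "fast", "missing")),
         rate = round(rate), fast_dir = fast_dir),
    class = "okn_variables"
  )
}

write_block_features <- function(ft, labels, path) {
  X <- as.data.frame(ft$X)
  data.table::fwrite(
    cbind(data.table::data.table(time = ft$time,
                                 complete = as.integer(ft$complete),
                                 label = as.character(labels)),
          X),
    path, sep = "\t", na = "NA")
  jsonlite::write_json(
    list(rate = ft$rate, lags = ft$lags, columns = colnames(ft$X)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_block_features <- function(path) {
  d <- data.table::fread(path, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- as.matrix(d[, side$columns, with = FALSE])
  ft <- feature_matrix(d$time, X, d$complete == 1L, rate = side$rate,
                       lags = side$lags)
  list(features = ft, labels = factor(d$label, levels = PERCEPT_LEVELS))
}

serialize_model <- function(m) {
  list(weights = unname(m$weights), bias = m$bias,
       positive_class = m$positive_class, cost = m$cost,
       roles = as.list(m$roles),
       stats = list(center = unname(m$stats$center),
                    scale = unname(m$stats$scale)),
       opt_accuracy = m$opt_accuracy, eval_accuracy = m$eval_accuracy)
}

deserialize_model <- function(x) {
  structure(
    list(weights = as.numeric(x$weights), bias = x$bias,
         positive_class = x$positive_class, levels = PERCEPT_LEVELS,
         cost = x$cost, roles = unlist(x$roles),
         stats = list(center = as.numeric(x$stats$center),
                      scale = as.numeric(x$stats$scale)),
         opt_accuracy = x$opt_accuracy, eval_accuracy = x$eval_accuracy),
    class = "decoder_model"
  )
}

block_file <- function(run_dir, p, i, sub, suffix) {
  d <- file.path(pdir(run_dir, p), sub)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  file.path(d, sprintf("block%02d%s", i, suffix))
}

stage_simulate <- function(run_dir) {
  config <- read_config_from(run_dir)
  design <- config_design(config)
  pa <- config_percept(config, "auditory")
  pv <- config_percept(config, "visual")
  okn <- config_okn(config)
  manifest <- list(participants = config$participants,
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(
                     file.path(run_dir, "config.json"))),
                   participant_seeds = integer(0))
  for (p in seq_len(config$participants)) {
    pseed <- sub_seed(config$seed, p)
    session <- build_session(design, pa, pv, okn, seed = pseed)
    write_session(session, pdir(run_dir, p))
    manifest$participant_seeds <- c(manifest$participant_seeds, pseed)
    log_line(run_dir, "simulate: participant %d (seed %d), %d blocks", p,
             pseed, nrow(design))
  }
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run_dir)
}

stage_preprocess <- function(run_dir) {
  config <- read_config_from(run_dir)
  pp <- config$preprocess
  for (p in seq_len(config$participants)) {
    sm <- read_session_manifest(run_dir, p)
    for (i in seq_len(sm$n_blocks)) {
      if (!sm$blocks$has_gaze[i]) next
      gaze <- read_gaze_trace(block_file(run_dir, p, i, ".", "_gaze.tsv"))
      okn <- okn_variables(gaze, fast_dir = config$okn$fast_dir,
                           window_s = pp$window_s,
                           run_smooth_ms = pp$run_smooth_ms,
                           vel_thresh = pp$vel_thresh,
                           min_dur_ms = pp$min_dur_ms,
                           merge_gap_ms = pp$merge_gap_ms,
                           smooth_ms = pp$smooth_ms,
                           low_thresh = pp$low_thresh, pad_ms = pp$pad_ms)
      write_okn_variables(okn, block_file(run_dir, p, i, "okn", "_okn.tsv"))
      log_line(run_dir, "preprocess: p%02d block%02d: %d samples (%d missing)",
               p, i, length(okn$t), sum(okn$labels == "missing"))
    }
  }
  invisible(run_dir)
}

stage_features <- function(run_dir) {
  config <- read_config_from(run_dir)
  for (p in seq_len(config$participants)) {
    sm <- read_session_manifest(run_dir, p)
    total <- max(sm$blocks$duration_s)
    for (i in seq_len(sm$n_blocks)) {
      if (!sm$blocks$has_gaze[i]) next
      okn <- read_okn_variables(block_file(run_dir, p, i, "okn", "_okn.tsv"),
                                fast_dir = config$okn$fast_dir)
      report <- read_report_events(
        block_file(run_dir, p, i, ".", "_report.tsv"),
        rate = okn$rate, duration = total)
      ft <- assemble_features(okn, rate = config$features$rate,
                              lag_min = config$features$lag_min,
                              lag_step = config$features$lag_step)
      labels <- align_labels(ft, report)
      write_block_features(ft, labels,
                           block_file(run_dir, p, i, "features",
                                      "_features.tsv"))
      log_line(run_dir,
               "features: p%02d block%02d: %d rows (%d complete, %d labelled)",
               p, i, nrow(ft$X), sum(ft$complete), sum(!is.na(labels)))
    }
  }
  invisible(run_dir)
}

load_condition_blocks <- function(run_dir, config, p, condition,
                                  multistable_only = TRUE) {
  sm <- read_session_manifest(run_dir, p)
  idx <- which(sm$blocks$condition == condition)
  mdur <- config$design$multistable_dur
  blocks <- lapply(idx, function(i) {
    bf <- read_block_features(block_file(run_dir, p, i, "features",
                                         "_features.tsv"))
    if (multistable_only) bf <- list(
      features = bf$features,
      labels = multistable_labels(bf, mdur))
    bf$block <- i
    bf
  })
  blocks
}

stage_train <- function(run_dir) {
  config <- read_config_from(run_dir)
  for (p in seq_len(config$participants)) {
    blocks <- load_condition_blocks(run_dir, config, p, "unimodal_visual")
    models <- run_role_permutations(blocks,
                                    cost_grid = config$svm$cost_grid,
                                    stride = config$svm$stride,
                                    standardize = config$features$standardize)
    jsonlite::write_json(lapply(models, serialize_model),
                         file.path(pdir(run_dir, p), "models.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line(run_dir, "train: p%02d: %d models, mean eval accuracy %.3f", p,
             length(models),
             mean(vapply(models, `[[`, numeric(1), "eval_accuracy")))
  }
  invisible(run_dir)
}

read_models <- function(run_dir, p) {
  lapply(jsonlite::read_json(file.path(pdir(run_dir, p), "models.json")),
         deserialize_model)
}

stage_decode <- function(run_dir) {
  config <- read_config_from(run_dir)
  for (p in seq_len(config$participants)) {
    models <- read_models(run_dir, p)
    blocks <- load_condition_blocks(run_dir, config, p, "bimodal",
                                    multistable_only = FALSE)
    for (b in blocks) {
      for (m in seq_along(models)) {
        mod <- models[[m]]
        ft <- standardize_features(b$features, mod$stats)
        pred <- decode_timecourse(mod, ft)
        # decoded timecourse in the report event-table format
        st <- ifelse(is.na(pred), 0L, as.integer(pred))
        tr <- new_report_trace(st, b$features$rate)
        write_report_events(tr, block_file(run_dir, p, b$block, "decoded",
                                           sprintf("_model%d.tsv", m)))
      }
    }
    log_line(run_dir, "decode: p%02d: %d blocks x %d models", p,
             length(blocks), length(models))
  }
  invisible(run_dir)
}

stage_couple <- function(run_dir) {
  config <- read_config_from(run_dir)
  mdur <- config$design$multistable_dur
  for (p in seq_len(config$participants)) {
    sm <- read_session_manifest(run_dir, p)
    models <- read_models(run_dir, p)
    d <- mean(vapply(models, `[[`, numeric(1), "eval_accuracy"))
    total <- max(sm$blocks$duration_s)

    report_of <- function(i) read_report_events(
      block_file(run_dir, p, i, ".", "_report.tsv"), rate = 1000,
      duration = total)
    schedule_of <- function(i) as.data.frame(sm$blocks$schedule[[i]])
    hit_of <- function(i) score_hit_rate(report_of(i), schedule_of(i))

    vis <- which(sm$blocks$condition == "unimodal_visual")
    aud <- which(sm$blocks$condition == "unimodal_auditory")
    bim <- which(sm$blocks$condition == "bimodal")
    bim_aud <- bim[sm$blocks$disambig_modality[bim] == "auditory"]

    bblocks <- load_condition_blocks(run_dir, config, p, "bimodal")
    consistency <- compute_consistency(models, bblocks)

    prop_of <- function(idx) {
      m <- vapply(idx, function(i) {
        pr <- percept_proportions(report_of(i), c(0, mdur))
        c(pr$prop_seg, pr$exclusive_fraction)
      }, numeric(2))
      rowMeans(m)
    }
    pv <- prop_of(vis)
    pa <- prop_of(bim)
    pa_uni <- if (length(aud)) prop_of(aud) else c(NA_real_, NA_real_)
    visual_hit <- mean(vapply(vis, hit_of, numeric(1)))
    auditory_hit_unimodal <- if (length(aud))
      mean(vapply(aud, hit_of, numeric(1))) else NA_real_
    auditory_hit_bimodal <- if (length(bim_aud))
      mean(vapply(bim_aud, hit_of, numeric(1))) else NA_real_
    r_pct <- if (is.finite(auditory_hit_bimodal)) auditory_hit_bimodal else
      auditory_hit_unimodal
    bounds <- consistency_bounds(clamp01(pa[1]), clamp01(pv[1]), d,
                                 min(max(r_pct / 100, 0), 1))
    med_bim <- mean(vapply(bim, function(i)
      median_phase_duration(report_of(i), c(0, mdur)), numeric(1)))

    analysis <- list(
      participant = p,
      visual_hit = visual_hit,
      auditory_hit_unimodal = auditory_hit_unimodal,
      auditory_hit_bimodal = auditory_hit_bimodal,
      decoding_accuracy = 100 * d,
      prop_seg_visual = 100 * pv[1],
      prop_seg_auditory_unimodal = 100 * pa_uni[1],
      prop_seg_auditory_bimodal = 100 * pa[1],
      exclusive_visual = 100 * pv[2],
      exclusive_auditory_bimodal = 100 * pa[2],
      median_phase_bimodal = med_bim,
      consistency = 100 * consistency$mean,
      consistency_matrix = consistency$matrix,
      theo_max = 100 * bounds$theo_max, theo_min = 100 * bounds$theo_min,
      exp_max = 100 * bounds$exp_max, exp_min = 100 * bounds$exp_min
    )
    jsonlite::write_json(analysis,
                         file.path(pdir(run_dir, p), "analysis.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    log_line(run_dir, "couple: p%02d: consistency %.3f over %d cells", p,
             consistency$mean, consistency$n_defined)
  }
  invisible(run_dir)
}

stage_report <- function(run_dir) {
  config <- read_config_from(run_dir)
  rows <- lapply(seq_len(config$participants), function(p) {
    a <- jsonlite::read_json(file.path(pdir(run_dir, p), "analysis.json"),
                             simplifyVector = TRUE)
    a$consistency_matrix <- NULL
    as.data.frame(a[!vapply(a, is.null, logical(1))])
  })
  summary <- do.call(rbind, rows)
  summary <- apply_inclusion_criteria(summary, config$inclusion$hit_rate,
                                      config$inclusion$decoding)
  data.table::fwrite(summary, file.path(run_dir, "summary.csv"))
  stats <- list()
  if (nrow(summary) >= 2) {
    stats$consistency_vs_chance <-
      as.list(group_tests(summary$consistency, reference = 50))
    stats$decoding_vs_chance <-
      as.list(group_tests(summary$decoding_accuracy, reference = 50))
    if (all(is.finite(summary$auditory_hit_unimodal)))
      stats$hit_bimodal_vs_unimodal <- as.list(
        group_tests(summary$auditory_hit_bimodal,
                    paired_with = summary$auditory_hit_unimodal,
                    method = "paired"))
    if (sd(summary$prop_seg_visual) > 0 &&
        sd(summary$prop_seg_auditory_bimodal) > 0)
      stats$prop_correlation <- as.list(
        group_tests(summary$prop_seg_visual,
                    paired_with = summary$prop_seg_auditory_bimodal,
                    method = "pearson"))
  }
  jsonlite::write_json(stats, file.path(run_dir, "group_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line(run_dir, "report: %d participants, %d included", nrow(summary),
           sum(summary$included))
  invisible(summary)
}

#' Run the end-to-end pipeline
#'
#' Executes the requested stages (simulate, preprocess, features, train,
#' decode, couple, report) for N synthetic participants in a run directory.
#' Each stage consumes only the written configuration and files produced by
#' earlier stages; re-running with the same configuration reproduces all
#' numeric outputs exactly. A manifest (participant seeds, config hash) and
#' a log with per-stage row counts make exclusions auditable.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param stages character vector of stages, or `"all"`.
#' @return the participant summary data.frame (invisibly) when the `report`
#'   stage ran, otherwise `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  if (identical(stages, "all")) stages <- PIPELINE_STAGES
  if (!all(stages %in% PIPELINE_STAGES))
    stop_bad_arg("unknown stage(s): ",
                 paste(setdiff(stages, PIPELINE_STAGES), collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.json")
  if (!file.exists(cfg_path) || "simulate" %in% stages)
    write_run_config(config, cfg_path)
  out <- out_dir
  for (s in stages) {
    fn <- switch(s, simulate = stage_simulate, preprocess = stage_preprocess,
                 features = stage_features, train = stage_train,
                 decode = stage_decode, couple = stage_couple,
                 report = stage_report)
    out <- tryCatch(fn(out_dir), error = function(e)
      stop("pipeline stage '", s, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  invisible(out)
}
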