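# brute-force oracle: pad every invalid run sample-by-sample
brute_blink_mask <- function(valid, pad) {
  mask <- rep(TRUE, length(valid))
  for (i in which(!valid)) {
    lo <- max(1, i - pad)
    hi <- min(length(valid), i + pad)
    mask[lo:hi] <- FALSE
  }
  mask
}

test_that("blink padding extends and merges invalid runs", {
  n <- 2000
  x <- seq_len(n) * 1e-3
  # all-valid trace: mask untouched
  tr <- gaze_trace((seq_len(n) - 1) / 1000, x)
  expect_true(all(detect_blinks(tr, 50)))
  # one 150-ms invalid run padded by 50 ms per side = 250 ms masked
  valid <- rep(TRUE, n); valid[501:650] <- FALSE
  tr <- gaze_trace((seq_len(n) - 1) / 1000, ifelse(valid, x, NA), valid)
  expect_equal(sum(!detect_blinks(tr, 50)), 250)
  # random runs match the brute-force interval union
  withr::with_seed(2, {
    for (rep in 1:10) {
      valid <- rep(TRUE, n)
      for (k in 1:5) {
        s <- sample(n - 80, 1)
        valid[s:(s + sample(80, 1))] <- FALSE
      }
      tr <- gaze_trace((seq_len(n) - 1) / 1000, ifelse(valid, x, NA), valid)
      expect_identical(detect_blinks(tr, 30), brute_blink_mask(valid, 30))
    }
  })
})

test_that("slow drift and constant position contain no fast phases", {
  n <- 5000
  ramp <- gaze_trace((seq_len(n) - 1) / 1000, seq_len(n) * 2 / 1000)
  expect_equal(sum(detect_fast_phases(ramp) == "fast"), 0)
  flat <- gaze_trace((seq_len(n) - 1) / 1000, rep(1, n))
  expect_true(all(detect_fast_phases(flat) == "slow"))
})

test_that("injected fast phases are recovered at >= 95% per class", {
  saw <- make_sawtooth_trace(duration = 30, noise_sd = 0.002, seed = 3)
  lab <- detect_fast_phases(saw$trace)
  fast_recall <- mean(lab[saw$fast] == "fast")
  slow_recall <- mean(lab[!saw$fast] == "slow")
  expect_gte(fast_recall, 0.95)
  expect_gte(slow_recall, 0.95)
})

test_that("phase labels always partition the trace", {
  withr::with_seed(4, {
    for (i in 1:5) {
      lat <- simulate_percepts(percept_params(), 20, rate = 1000)
      g <- simulate_okn(lat, okn_params(blink_rate = 30))
      lab <- detect_fast_phases(g)
      counts <- table(lab)
      expect_equal(sum(counts), length(g$x))
      # every invalid sample is missing
      expect_true(all(lab[!g$valid] == "missing"))
    }
  })
})

test_that("short traces are rejected by the saccade detector", {
  tr <- gaze_trace(0:5 / 1000, rnorm(6))
  expect_error(detect_fast_phases(tr), "shorter")
})

test_that("smoothed slow velocity reproduces a clean ramp", {
  n <- 5000
  v <- 1.7
  tr <- gaze_trace((seq_len(n) - 1) / 1000, seq_len(n) * v / 1000)
  lab <- factor(rep("slow", n), levels = c("slow", "fast", "missing"))
  out <- compute_slow_velocity(tr, lab)
  expect_lt(max(abs(out$smooth[1001:n] - v)), 1e-9)
})

test_that("velocity is never computed across an excised gap", {
  n <- 4000
  x <- seq_len(n) * 1.9 / 1000
  x[2001:2030] <- x[2001:2030] + 3   # 3-deg jump marked as fast
  lab <- factor(rep("slow", n), levels = c("slow", "fast", "missing"))
  lab[2001:2030] <- "fast"
  tr <- gaze_trace((seq_len(n) - 1) / 1000, x)
  out <- compute_slow_velocity(tr, lab)
  expect_true(all(abs(out$raw[!is.na(out$raw)] - 1.9) < 1e-9))
})

test_that("trailing mean of a square-wave velocity matches a brute force", {
  n <- 6000
  vel <- rep(c(2, -2), each = 500, length.out = n) / 1000
  tr <- gaze_trace((seq_len(n) - 1) / 1000, cumsum(vel))
  lab <- factor(rep("slow", n), levels = c("slow", "fast", "missing"))
  out <- compute_slow_velocity(tr, lab)
  # after the transient the 1-s (full-period) mean is ~0
  expect_lt(max(abs(out$smooth[2000:n])), 0.01)
  # brute-force sliding mean oracle on a short stretch
  brute <- vapply(1500:1600, function(i)
    mean(out$raw[max(1, i - 999):i], na.rm = TRUE), numeric(1))
  expect_equal(out$smooth[1500:1600], brute, tolerance = 1e-12)
})

test_that("run statistics are zero against the drift and exact on an event", {
  n <- 3000
  # monotone drift opposite to fast_dir -> zero everywhere
  tr <- gaze_trace((seq_len(n) - 1) / 1000, seq_len(n) * 2 / 1000)
  lab <- factor(rep("slow", n), levels = c("slow", "fast", "missing"))
  runs <- compute_fastphase_runs(tr, lab, fast_dir = -1, smooth_ms = 0)
  expect_true(all(runs$len_raw[-1] == 0))
  expect_true(all(runs$dist_raw[-1] == 0))
  # a single 30-sample fast phase moving 3 deg in fast_dir
  saw <- make_sawtooth_trace(duration = 3, fast_len = 30, fast_ext = 3,
                             period = 1500)
  runs <- compute_fastphase_runs(saw$trace, factor(
    rep("slow", 3000), levels = c("slow", "fast", "missing")),
    fast_dir = -1, smooth_ms = 0)
  ev <- saw$starts[1]:(saw$starts[1] + 29)
  expect_true(all(runs$len_raw[ev] == 30))
  expect_equal(unname(runs$dist_raw[ev]), rep(3, 30), tolerance = 1e-9)
})

test_that("run series match an independent brute-force scanner", {
  saw <- make_sawtooth_trace(duration = 5, noise_sd = 0.01, seed = 5)
  lab <- factor(rep("slow", 5000), levels = c("slow", "fast", "missing"))
  runs <- compute_fastphase_runs(saw$trace, lab, fast_dir = -1,
                                 smooth_ms = 0)
  # brute force: per-sample scan outward over equal displacement signs
  x <- saw$trace$x
  disp <- c(NA, diff(x))
  indir <- disp * -1 > 0
  brute_len <- brute_dist <- rep(NA_real_, length(x))
  for (i in 2:length(x)) {
    if (!indir[i]) { brute_len[i] <- 0; brute_dist[i] <- 0; next }
    lo <- i; while (lo > 2 && indir[lo - 1]) lo <- lo - 1
    hi <- i; while (hi < length(x) && indir[hi + 1]) hi <- hi + 1
    brute_len[i] <- hi - lo + 1
    brute_dist[i] <- sum(abs(disp[lo:hi]))
  }
  expect_equal(runs$len_raw[-1], brute_len[-1], tolerance = 1e-9)
  expect_equal(runs$dist_raw[-1], brute_dist[-1], tolerance = 1e-9)
  # smoothing equals a brute-force trailing mean
  i <- 3000:3100
  brute_sm <- vapply(i, function(j)
    mean(brute_len[max(1, j - 999):j], na.rm = TRUE), numeric(1))
  expect_equal(runs$len_smooth[i], brute_sm, tolerance = 1e-9)
})

test_that("smoothed run series are robust to 0.01-deg position jitter", {
  base <- make_sawtooth_trace(duration = 20, fast_len = 40, fast_ext = 2.4,
                              period = 1260, noise_sd = 0)
  jit <- make_sawtooth_trace(duration = 20, fast_len = 40, fast_ext = 2.4,
                             period = 1260, noise_sd = 0.01, seed = 6)
  lab <- factor(rep("slow", 20000), levels = c("slow", "fast", "missing"))
  r0 <- compute_fastphase_runs(base$trace, lab, fast_dir = -1)
  r1 <- compute_fastphase_runs(jit$trace, lab, fast_dir = -1)
  i <- 2000:20000
  rel_change <- function(a, b) mean(abs(a[i] - b[i])) / mean(abs(a[i]))
  expect_lt(rel_change(r0$len_smooth, r1$len_smooth), 0.05)
  expect_lt(rel_change(r0$dist_smooth, r1$dist_smooth), 0.05)
})

test_that("OKN variables are causal: truncation never changes the past", {
  lat <- simulate_percepts(percept_params(), 30, rate = 1000, seed = 7)
  g <- simulate_okn(lat, okn_params(), seed = 8)
  full <- okn_variables(g)
  t_cut <- 20
  idx <- seq_len(t_cut * 1000)
  gcut <- gaze_trace(g$t[idx], g$x[idx], g$valid[idx], g$rate)
  cut <- okn_variables(gcut)
  margin <- 100        # samples; covers detection kernel + merge gap
  keep <- seq_len(length(idx) - margin)
  expect_identical(full$v_smooth[keep], cut$v_smooth[keep])
  expect_identical(full$fp_len[keep], cut$fp_len[keep])
  expect_identical(full$fp_dist[keep], cut$fp_dist[keep])
})
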