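# Linear-programming oracle over the joint percept distribution: the joint
# P(auditory = seg, visual = seg) = x is the single free parameter given the
# marginals; the balanced consistency is linear in x, so its extrema over
# the feasible interval are at the endpoints.
lp_bounds_oracle <- function(a, v) {
  balanced <- function(x) ((x / a) + (1 - a - v + x) / (1 - a)) / 2
  x_lo <- max(0, a + v - 1)
  x_hi <- min(a, v)
  vals <- c(balanced(x_lo), balanced(x_hi))
  list(max = max(vals), min = min(vals))
}

test_that("theoretical bounds match their worked examples", {
  expect_equal(theoretical_bounds(0.37, 0.37)$theo_max, 1)
  b <- theoretical_bounds(0.6, 0.4)
  expect_equal(b$theo_max, 5 / 6, tolerance = 1e-12)
  expect_equal(b$theo_min, 0)
  b2 <- theoretical_bounds(0.7, 0.6)
  expect_equal(b2$theo_min, 0.5 * (0.3 / 0.7), tolerance = 1e-12)
  expect_error(theoretical_bounds(0, 0.5), "inside")
  expect_error(theoretical_bounds(0.5, 1), "inside")
})

test_that("closed-form theoretical bounds equal the LP oracle on a grid", {
  grid <- seq(0.05, 0.95, length.out = 20)
  for (a in grid) {
    for (v in grid) {
      cf <- theoretical_bounds(a, v)
      lp <- lp_bounds_oracle(a, v)
      expect_lt(abs(cf$theo_max - lp$max), 1e-9)
      expect_lt(abs(cf$theo_min - lp$min), 1e-9)
    }
  }
})

test_that("expected bounds collapse correctly at the accuracy extremes", {
  # perfect decoding and reporting: expected = theoretical
  tb <- theoretical_bounds(0.6, 0.45)
  eb <- expected_bounds(0.6, 0.45, 1, 1)
  expect_equal(eb$exp_max, tb$theo_max)
  expect_equal(eb$exp_min, tb$theo_min)
  # chance-level decoding destroys all information
  eb2 <- expected_bounds(0.6, 0.45, 0.5, 0.9)
  expect_equal(eb2$exp_max, 0.5)
  expect_equal(eb2$exp_min, 0.5)
  # match-transmission probability for the reference accuracies
  eb3 <- expected_bounds(0.5, 0.5, 0.829, 0.871)
  expect_equal(eb3$q, 0.829 * 0.871 + 0.171 * 0.129, tolerance = 1e-12)
  expect_equal(eb3$q, 0.744118, tolerance = 1e-6)
})

test_that("expected bounds agree with a Monte-Carlo channel simulation", {
  withr::with_seed(11, {
    for (case in list(c(a = 0.6, v = 0.5, d = 0.9, r = 0.85),
                      c(a = 0.5, v = 0.5, d = 0.95, r = 0.9))) {
      a <- unname(case["a"]); v <- unname(case["v"])
      d <- unname(case["d"]); r <- unname(case["r"])
      n <- 4e5
      # most consistent joint distribution with these marginals
      x <- min(a, v)
      p <- c(ss = x, si = a - x, is = v - x, ii = 1 - a - v + x)
      cell <- sample(names(p), n, TRUE, prob = p)
      A <- cell %in% c("ss", "si")
      V <- cell %in% c("ss", "is")
      A_rep <- ifelse(runif(n) < r, A, !A)
      V_dec <- ifelse(runif(n) < d, V, !V)
      acc_seg <- mean(V_dec[A_rep])
      acc_int <- mean(!V_dec[!A_rep])
      mc <- (acc_seg + acc_int) / 2
      eb <- expected_bounds(a, v, d, r)
      # the closed form approximates true-class by reported-class
      # proportions; allow Monte-Carlo plus approximation error
      expect_lt(abs(mc - eb$exp_max), 0.02)
    }
  })
})

test_that("bounds are ordered for informative accuracies", {
  withr::with_seed(12, {
    for (i in 1:1000) {
      a <- runif(1, 0.05, 0.95)
      v <- runif(1, 0.05, 0.95)
      d <- runif(1, 0.5, 1)
      r <- runif(1, 0.5, 1)
      b <- consistency_bounds(a, v, d, r)
      expect_true(b$theo_min <= b$exp_min + 1e-12)
      expect_true(b$exp_min <= 0.5 + 1e-12)
      expect_true(0.5 <= b$exp_max + 1e-12)
      expect_true(b$exp_max <= b$theo_max + 1e-12)
      expect_true(all(unlist(b[c("theo_max", "theo_min", "exp_max",
                                 "exp_min")]) >= 0))
      expect_true(all(unlist(b[c("theo_max", "theo_min", "exp_max",
                                 "exp_min")]) <= 1))
    }
  })
})

test_that("percept proportions normalize over exclusive time", {
  rate <- 10
  rep1 <- report_from_codes(rep(2L, 100), rate)
  p1 <- percept_proportions(rep1)
  expect_equal(unlist(p1), c(prop_seg = 1, prop_int = 0,
                             exclusive_fraction = 1))
  # 60 s seg, 40 s int, 10 s none
  rep2 <- report_from_codes(c(rep(2L, 600), rep(1L, 400), rep(0L, 100)),
                            rate)
  p2 <- percept_proportions(rep2)
  expect_equal(p2$prop_seg, 0.6)
  expect_equal(p2$prop_int, 0.4)
  expect_equal(p2$exclusive_fraction, 100 / 110)
  expect_equal(p2$prop_seg + p2$prop_int, 1)
  expect_error(percept_proportions(report_from_codes(rep(0L, 50), rate)),
               "exclusive")
})

test_that("median phase duration follows the phase structure", {
  rate <- 10
  codes <- c(rep(1L, 20), rep(2L, 40), rep(1L, 90))   # 2, 4, 9 s
  expect_equal(median_phase_duration(report_from_codes(codes, rate)), 4)
  expect_equal(median_phase_duration(report_from_codes(rep(2L, 35), rate)),
               3.5)
  # none-gaps end a phase
  codes2 <- c(rep(1L, 20), rep(0L, 5), rep(1L, 40))
  expect_equal(median_phase_duration(report_from_codes(codes2, rate)), 3)
  expect_error(median_phase_duration(report_from_codes(rep(0L, 10), rate)),
               "phases")
})

test_that("simulated phase durations match the gamma distribution median", {
  p <- percept_params(mean_dom = 8, shape = 3, kappa = 1, eps_report = 0,
                      lag_report = 0, gamma_gap = 0)
  lat <- simulate_percepts(p, 20000, rate = 20, seed = 21)
  rep <- simulate_report(lat, 0, 0, 0, seed = 22)
  med <- median_phase_duration(rep)
  expect_lt(abs(med - qgamma(0.5, shape = 3, scale = 8 / 3)), 0.6)
})

test_that("group tests match closed forms and handle degenerate input", {
  vals <- c(55, 60, 52, 58, 54)
  res <- group_tests(vals, reference = 50)
  expect_equal(res$statistic,
               (mean(vals) - 50) * sqrt(5) / sd(vals), tolerance = 1e-12)
  expect_equal(res$df, 4)
  # all equal to the reference: t = 0, p = 1, with a zero-variance warning
  expect_warning(res0 <- group_tests(rep(50, 6), reference = 50), "variance")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  expect_error(group_tests(rep(52, 6), reference = 50), "zero variance")
  # paired test on identical vectors
  expect_warning(resp <- group_tests(vals, paired_with = vals,
                                     method = "paired"), "zero")
  expect_equal(resp$statistic, 0)
  # pearson matches cor.test
  y <- c(50, 63, 50, 60, 51)
  ct <- cor.test(vals, y)
  resc <- group_tests(vals, paired_with = y, method = "pearson")
  expect_equal(resc$estimate, unname(ct$estimate))
  expect_equal(resc$p, ct$p.value)
})

test_that("consistency cells cover models x blocks and behave at extremes", {
  # synthetic models that copy one feature's sign
  lv <- c("integrated", "segregated")
  mk_model <- function() structure(
    list(weights = c(1, rep(0, 3)), bias = 0, positive_class = "segregated",
         levels = lv, cost = 1),
    class = "decoder_model")
  models <- replicate(6, mk_model(), simplify = FALSE)
  withr::with_seed(31, {
    blocks <- lapply(1:8, function(b) {
      X <- matrix(rnorm(400), ncol = 4)
      lab <- factor(ifelse(X[, 1] >= 0, "segregated", "integrated"),
                    levels = lv)
      list(features = feature_matrix(time = 1:100 / 100, X = X), labels = lab)
    })
    cons <- compute_consistency(models, blocks)
    expect_equal(dim(cons$matrix), c(6, 8))
    expect_equal(cons$n_defined, 48)
    expect_true(all(cons$matrix == 1))       # labels equal decoded series
    # shuffled labels drop the mean to chance
    means <- vapply(1:100, function(i) {
      shuffled <- lapply(blocks, function(b) {
        b$labels <- sample(b$labels)
        b
      })
      suppressWarnings(compute_consistency(models, shuffled)$mean)
    }, numeric(1))
    expect_lt(abs(mean(means) - 0.5), 0.02)
    # a single-class block leaves its cells undefined but keeps the rest
    blocks[[3]]$labels <- factor(rep("segregated", 100), levels = lv)
    expect_warning(c2 <- compute_consistency(models, blocks), "lacks")
    expect_true(all(is.na(c2$matrix[, 3])))
    expect_equal(c2$n_defined, 42)
    expect_equal(c2$mean, 1)
  })
})
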