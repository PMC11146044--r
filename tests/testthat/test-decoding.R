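test_that("a separable problem is fit perfectly and deterministically", {
  b <- make_separable_block(seed = 1)
  rows <- b$features$complete
  m1 <- train_svm(b$features$X[rows, ], b$labels[rows], cost = 1)
  m2 <- train_svm(b$features$X[rows, ], b$labels[rows], cost = 1)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$bias, m2$bias)
  pred <- decode_timecourse(m1, b$features)
  expect_equal(balanced_accuracy(pred, b$labels)$balanced, 1.0)
})

test_that("shuffled labels decode held-out data at chance", {
  tr <- make_separable_block(n_per_class = 300, seed = 2)
  te <- make_separable_block(n_per_class = 300, seed = 3)
  accs <- withr::with_seed(4, {
    vapply(1:20, function(i) {
      y <- sample(tr$labels)
      m <- train_svm(tr$features$X, y, cost = 1)
      balanced_accuracy(decode_timecourse(m, te$features),
                        te$labels)$balanced
    }, numeric(1))
  })
  expect_lt(abs(mean(accs) - 0.5), 0.03)
})

test_that("single-class training labels raise an informative error", {
  b <- make_separable_block(seed = 5)
  y <- factor(rep("integrated", nrow(b$features$X)),
              levels = c("integrated", "segregated"))
  expect_error(train_svm(b$features$X, y, cost = 1), "segregated")
})

test_that("balanced accuracy follows the per-class definition", {
  lv <- c("integrated", "segregated")
  # seg 80/100 correct, int 40/100 correct -> (0.8 + 0.4)/2 = 0.60
  labels <- factor(rep(lv, each = 100), levels = lv)
  pred <- factor(c(rep("integrated", 40), rep("segregated", 60),
                   rep("segregated", 80), rep("integrated", 20)),
                 levels = lv)
  res <- balanced_accuracy(pred, labels)
  expect_equal(res$acc_int, 0.4)
  expect_equal(res$acc_seg, 0.8)
  expect_equal(res$balanced, 0.6)
  # perfect prediction
  expect_equal(balanced_accuracy(labels, labels)$balanced, 1)
  # 90/10 asymmetry, constant predictor -> 0.5
  asym <- factor(c(rep("segregated", 900), rep("integrated", 100)),
                 levels = lv)
  const <- factor(rep("segregated", 1000), levels = lv)
  expect_equal(balanced_accuracy(const, asym)$balanced, 0.5)
  # absent class -> error naming the zero denominator
  expect_error(balanced_accuracy(const, const), "integrated")
})

test_that("duplicating minority rows leaves balanced accuracy unchanged", {
  withr::with_seed(6, {
    lv <- c("integrated", "segregated")
    labels <- factor(sample(lv, 500, TRUE, prob = c(0.9, 0.1)), levels = lv)
    pred <- factor(sample(lv, 500, TRUE), levels = lv)
    base <- balanced_accuracy(pred, labels)$balanced
    minority <- labels == "segregated"
    k <- 7
    lab_dup <- c(labels, rep(labels[minority], k))
    pred_dup <- c(pred, rep(pred[minority], k))
    expect_lt(abs(balanced_accuracy(pred_dup, lab_dup)$balanced - base),
              1e-12)
  })
})

test_that("model selection maximizes accuracy and breaks ties to small cost", {
  b <- make_separable_block(seed = 7)
  m_good <- train_svm(b$features$X, b$labels, cost = 1)
  m_bad <- m_good
  m_bad$weights <- -m_good$weights   # inverted rule: accuracy ~0
  m_bad$bias <- -m_good$bias
  m_bad$cost <- 5
  sel <- select_model(list(m_bad, m_good), b$features, b$labels)
  expect_equal(sel$cost, 1)
  # single candidate returns itself
  expect_equal(select_model(list(m_bad), b$features, b$labels)$cost, 5)
  # exact tie -> smallest cost
  m_tie <- m_good
  m_tie$cost <- 0.01
  sel2 <- select_model(list(m_good, m_tie), b$features, b$labels)
  expect_equal(sel2$cost, 0.01)
})

test_that("the role permutation scheme returns six models with distinct roles", {
  blocks <- lapply(1:3, function(i) make_separable_block(seed = 10 + i))
  models <- run_role_permutations(blocks, cost_grid = c(0.01, 1))
  expect_length(models, 6)
  roles <- t(vapply(models, function(m) m$roles, numeric(3)))
  expect_equal(nrow(unique(roles)), 6)
  expect_true(all(apply(roles, 1, function(r) length(unique(r)) == 3)))
  # separable blocks evaluate perfectly
  expect_true(all(vapply(models, `[[`, numeric(1), "eval_accuracy") == 1))
  expect_error(run_role_permutations(blocks[1:2]), "3")
})

test_that("three identical blocks give six identical evaluation accuracies", {
  b <- make_separable_block(n_per_class = 80, sep = 1.5, seed = 20)
  models <- run_role_permutations(list(b, b, b), cost_grid = c(0.1, 1))
  accs <- vapply(models, `[[`, numeric(1), "eval_accuracy")
  expect_true(all(abs(accs - accs[1]) < 1e-12))
})

test_that("hit rate scores exclusive report time against the schedule", {
  sched <- data.frame(onset = c(0, 7.5, 15, 22.5),
                      offset = c(7.5, 15, 22.5, 30),
                      state = c("integrated", "segregated",
                                "integrated", "segregated"))
  rate <- 100
  suggested <- rep(c(1L, 2L, 1L, 2L), each = 750)
  expect_equal(score_hit_rate(report_from_codes(suggested, rate), sched), 100)
  expect_equal(score_hit_rate(report_from_codes(3L - suggested, rate), sched),
               0)
  # correct 12 s, wrong 8 s, none 10 s -> 12/(12+8) = 60%
  mixed <- suggested
  mixed[1:1000] <- 0L                    # 10 s none
  mixed[1001:1800] <- 3L - suggested[1001:1800]  # 8 s wrong
  expect_equal(score_hit_rate(report_from_codes(mixed, rate), sched), 60)
  expect_error(score_hit_rate(report_from_codes(rep(0L, 3000), rate), sched),
               "exclusive")
})

test_that("decoding maps the decision function sign to percepts", {
  m <- structure(
    list(weights = rep(0, 4), bias = 1, positive_class = "integrated",
         levels = c("integrated", "segregated"), cost = 1),
    class = "decoder_model")
  X <- matrix(rnorm(40), ncol = 4)
  expect_true(all(decode_timecourse(m, X) == "integrated"))
  expect_error(decode_timecourse(m, matrix(0, 2, 3)), "dimensionality")
  # incomplete rows stay unpredicted
  ft <- feature_matrix(time = 1:10 / 100, X = X, complete = rep(c(TRUE, FALSE), 5))
  pred <- decode_timecourse(m, ft)
  expect_true(all(is.na(pred[!ft$complete])))
  expect_true(all(!is.na(pred[ft$complete])))
})

test_that("a model fits its own training block at least as well as held-out", {
  tr <- make_separable_block(n_per_class = 150, sep = 1.2, seed = 30)
  te <- make_separable_block(n_per_class = 150, sep = 1.2, seed = 31)
  m <- train_svm(tr$features$X, tr$labels, cost = 1)
  acc_tr <- balanced_accuracy(decode_timecourse(m, tr$features), tr$labels)
  acc_te <- balanced_accuracy(decode_timecourse(m, te$features), te$labels)
  expect_gte(acc_tr$balanced, acc_te$balanced - 0.02)
})
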