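#' Default SVM cost grid
#'
#' The 11 cost-parameter settings evaluated during model selection.
#'
#' @return a numeric vector of length 11.
#' @export
okn_cost_grid <- function() {
  c(0.0001, 0.0005, 0.001, 0.005, 0.01, 0.1, 1, 2, 5, 10, 100)
}

#' Train a linear-SVM percept decoder
#'
#' Fits a soft-margin linear SVM with the given cost on (already
#' standardized) feature rows. Class weights are inversely proportional to
#' the training-class frequencies, so training matches the class-adjusted
#' (balanced) evaluation objective. The fit is deterministic given fixed
#' inputs. The decision rule is stored as an explicit weight vector and
#' bias, so decoding is a single matrix product.
#'
#' @param x numeric feature matrix (rows = timepoints).
#' @param y factor of labels with levels `integrated`/`segregated`
#'   (`NA` rows are dropped).
#' @param cost SVM cost parameter.
#' @param class_weights logical; weight classes inversely to frequency.
#' @return an object of class `decoder_model` with elements `weights`,
#'   `bias`, `positive_class`, `levels`, `cost`.
#' @export
train_svm <- function(x, y, cost = 1, class_weights = TRUE) {
  x <- as.matrix(x)
  keep <- !is.na(y) & rowSums(!is.finite(x)) == 0
  x <- x[keep, , drop = FALSE]
  y <- droplevels(factor(y[keep], levels = PERCEPT_LEVELS))
  tab <- table(y)
  if (length(tab) < 2L || any(tab == 0L)) {
    missing_class <- setdiff(PERCEPT_LEVELS, names(tab)[tab > 0])
    stop_bad_arg("training labels contain a single class; missing: ",
                 paste(missing_class, collapse = ", "))
  }
  w <- if (class_weights) {
    cw <- sum(tab) / (2 * tab)
    stats::setNames(as.numeric(cw), names(tab))
  } else NULL
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = w)
  weights <- drop(t(fit$coefs) %*% fit$SV)
  bias <- -fit$rho
  # orient the explicit rule to libSVM's decision-value convention
  k <- seq_len(min(nrow(x), 200L))
  pr <- stats::predict(fit, x[k, , drop = FALSE], decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  positive_class <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]][1]
  dec <- drop(x[k, , drop = FALSE] %*% weights) + bias
  if (sum(dv * dec) < 0) {
    weights <- -weights
    bias <- -bias
  }
  structure(
    list(weights = weights, bias = bias, positive_class = positive_class,
         levels = PERCEPT_LEVELS, cost = cost),
    class = "decoder_model"
  )
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("linear SVM decoder: %d features, cost = %g", length(x$weights),
              x$cost))
  if (!is.null(x$roles))
    cat(sprintf(" [train %s, opt %s, eval %s]", x$roles[1], x$roles[2],
                x$roles[3]))
  if (!is.null(x$eval_accuracy))
    cat(sprintf(", eval balanced accuracy %.3f", x$eval_accuracy))
  cat("\n")
  invisible(x)
}

#' Decode a percept timecourse from features
#'
#' Applies the linear decision function per timepoint; the sign maps to the
#' two percepts (ties go to the positive class). Incomplete rows are left
#' unpredicted (`NA`).
#'
#' @param model a `decoder_model`.
#' @param features a [feature_matrix()] (already standardized with the
#'   model's training statistics) or a plain numeric matrix.
#' @return a factor of predicted labels, `NA` where unpredicted.
#' @export
decode_timecourse <- function(model, features) {
  stopifnot(inherits(model, "decoder_model"))
  X <- if (inherits(features, "feature_matrix")) features$X else
    as.matrix(features)
  if (ncol(X) != length(model$weights))
    stop_bad_arg("feature dimensionality (", ncol(X),
                 ") does not match the model (", length(model$weights), ")")
  complete <- if (inherits(features, "feature_matrix")) features$complete else
    rowSums(!is.finite(X)) == 0
  pred <- factor(rep(NA_character_, nrow(X)), levels = model$levels)
  if (any(complete)) {
    dec <- drop(X[complete, , drop = FALSE] %*% model$weights) + model$bias
    neg <- setdiff(model$levels, model$positive_class)
    pred[complete] <- ifelse(dec >= 0, model$positive_class, neg)
  }
  pred
}

#' Class-adjusted (balanced) decoding accuracy
#'
#' Computes the per-class accuracies (fraction of timepoints at which the
#' model predicts a percept among the timepoints at which that percept is
#' reported) and averages them with equal class weight. The measure is
#' insensitive to asymmetric percept distributions, so random guessing
#' scores 50% regardless of class proportions.
#'
#' @param predicted factor of predicted labels.
#' @param labels factor of reported labels (`NA` = excluded timepoints).
#' @return an object of class `decoding_result`: list with `acc_seg`,
#'   `acc_int`, `balanced`, `n_seg`, `n_int`.
#' @export
balanced_accuracy <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  keep <- !is.na(labels) & !is.na(predicted)
  p <- as.character(predicted[keep])
  l <- as.character(labels[keep])
  n_seg <- sum(l == "segregated")
  n_int <- sum(l == "integrated")
  if (n_seg == 0L || n_int == 0L)
    stop_bad_arg("balanced accuracy undefined: class '",
                 if (n_seg == 0L) "segregated" else "integrated",
                 "' absent from the labels (zero denominator)")
  acc_seg <- sum(p == "segregated" & l == "segregated") / n_seg
  acc_int <- sum(p == "integrated" & l == "integrated") / n_int
  structure(
    list(acc_seg = acc_seg, acc_int = acc_int,
         balanced = (acc_seg + acc_int) / 2, n_seg = n_seg, n_int = n_int),
    class = "decoding_result"
  )
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "balanced accuracy %.3f (segregated %.3f on %d, integrated %.3f on %d)\n",
    x$balanced, x$acc_seg, x$n_seg, x$acc_int, x$n_int))
  invisible(x)
}

#' Select the decoder with highest accuracy on the optimization block
#'
#' Returns the candidate with the highest balanced accuracy on the
#' optimization block; ties are broken toward the smallest cost (stronger
#' regularization).
#'
#' @param candidates list of `decoder_model`s (one per cost).
#' @param opt_features standardized [feature_matrix()] of the optimization
#'   block.
#' @param opt_labels labels of the optimization block.
#' @return the selected `decoder_model`, with its optimization-block
#'   accuracy in `$opt_accuracy`.
#' @export
select_model <- function(candidates, opt_features, opt_labels) {
  stopifnot(length(candidates) >= 1L)
  acc <- vapply(candidates, function(m) {
    balanced_accuracy(decode_timecourse(m, opt_features), opt_labels)$balanced
  }, numeric(1))
  cost <- vapply(candidates, function(m) m$cost, numeric(1))
  best <- order(-acc, cost)[1]
  out <- candidates[[best]]
  out$opt_accuracy <- acc[best]
  out
}

#' Train and select decoders under the block-role permutation scheme
#'
#' Given the three unimodal visual blocks, permutes the roles (training,
#' cost-parameter optimization, evaluation) over all 3! ordered assignments.
#' For each assignment, one model per cost is trained on the training block
#' (standardized by its own statistics), the cost with the highest balanced
#' accuracy on the optimization block is retained, and the retained model is
#' scored on the evaluation block. The six retained models are kept for
#' further use; train, optimization and evaluation blocks are pairwise
#' distinct in every model.
#'
#' @param blocks a list of exactly 3 elements, each a list with `features`
#'   (a [feature_matrix()]) and `labels` (factor, `NA` = excluded).
#' @param cost_grid costs to evaluate (default [okn_cost_grid()]).
#' @param stride training-row decimation stride (1 = use every row, the
#'   full analysis rate). Selection and evaluation always use every row.
#' @param standardize center/scale features by training-block statistics.
#' @return a list of 6 `decoder_model`s, each carrying `roles` (train, opt,
#'   eval block indices), `stats`, `opt_accuracy` and `eval_accuracy`.
#' @export
run_role_permutations <- function(blocks, cost_grid = okn_cost_grid(),
                                  stride = 1, standardize = TRUE) {
  if (length(blocks) != 3L)
    stop_bad_arg("exactly 3 unimodal visual blocks are required, got ",
                 length(blocks))
  stride <- max(1L, as.integer(stride))
  stats_by_block <- lapply(blocks, function(b) {
    rows <- b$features$complete & !is.na(b$labels)
    if (standardize) feature_stats(b$features, rows) else
      list(center = rep(0, ncol(b$features$X)),
           scale = rep(1, ncol(b$features$X)))
  })
  std <- function(b, s) standardize_features(b$features, s)
  models_by_train <- lapply(1:3, function(tr) {
    ft <- std(blocks[[tr]], stats_by_block[[tr]])
    rows <- which(ft$complete & !is.na(blocks[[tr]]$labels))
    rows <- rows[seq.int(1L, length(rows), by = stride)]
    lapply(cost_grid, function(cc)
      train_svm(ft$X[rows, , drop = FALSE], blocks[[tr]]$labels[rows], cc))
  })
  perms <- expand.grid(train = 1:3, opt = 1:3, eval = 1:3)
  perms <- perms[perms$train != perms$opt & perms$train != perms$eval &
                   perms$opt != perms$eval, ]
  perms <- perms[order(perms$train, perms$opt), ]
  out <- vector("list", nrow(perms))
  for (i in seq_len(nrow(perms))) {
    tr <- perms$train[i]; op <- perms$opt[i]; ev <- perms$eval[i]
    s <- stats_by_block[[tr]]
    m <- select_model(models_by_train[[tr]], std(blocks[[op]], s),
                      blocks[[op]]$labels)
    m$roles <- c(train = tr, opt = op, eval = ev)
    m$stats <- s
    m$eval_accuracy <- balanced_accuracy(
      decode_timecourse(m, std(blocks[[ev]], s)), blocks[[ev]]$labels)$balanced
    out[[i]] <- m
  }
  out
}

#' Catch-trial hit rate against a disambiguation schedule
#'
#' Fraction of the exclusively reported time during which the report matches
#' the suggested percept of the disambiguated stimulus, as a percentage.
#' Time without an exclusive report is excluded from the denominator.
#'
#' @param report a `report_trace` (block-aligned: sample 1 = block onset).
#' @param schedule a data.frame with columns `onset`, `offset` (seconds,
#'   block-relative) and `state` (`integrated`/`segregated`).
#' @return hit rate in percent.
#' @export
score_hit_rate <- function(report, schedule) {
  stopifnot(inherits(report, "report_trace"),
            all(c("onset", "offset", "state") %in% names(schedule)))
  rate <- report$rate
  n <- length(report$states)
  hits <- 0L
  excl <- 0L
  for (j in seq_len(nrow(schedule))) {
    lo <- as.integer(floor(schedule$onset[j] * rate)) + 1L
    hi <- min(n, as.integer(ceiling(schedule$offset[j] * rate)))
    if (lo > hi) next
    st <- report$states[lo:hi]
    suggested <- match(as.character(schedule$state[j]), PERCEPT_LEVELS)
    ex <- st != 0L
    excl <- excl + sum(ex)
    hits <- hits + sum(st[ex] == suggested)
  }
  if (excl == 0L)
    stop_bad_arg("hit rate undefined: no exclusive report during the schedule")
  100 * hits / excl
}
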