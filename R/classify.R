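#' Default hyper-parameter grid for the RBF SVM
#'
#' @return list with candidate `C` and `gamma` vectors. `gamma` follows the
#'   `K(x, y) = exp(-gamma * ||x - y||^2)` convention, i.e. gamma =
#'   1/(2 sigma^2).
#' @export
default_svm_grid <- function() {
  list(C = c(0.1, 0.3, 1, 3, 10, 30, 100),
       gamma = c(0.01, 0.05, 0.1, 0.2, 0.5, 1, 2))
}

# Stratified fold assignment: each class is spread evenly across folds.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    i <- sample(i)
    fold[i] <- rep_len(seq_len(n_folds), length(i))
  }
  fold
}

# Stratified train/test split; returns test indices.
stratified_test_idx <- function(y, test_frac) {
  unlist(lapply(levels(y), function(cl) {
    i <- which(y == cl)
    n_test <- max(1L, round(length(i) * test_frac))
    sample(i, n_test)
  }))
}

#' Grid search for the RBF SVM
#'
#' Selects `(C, gamma)` maximizing stratified 5-fold cross-validated
#' accuracy on the training data only; ties resolve to the smallest `C`,
#' then the smallest `gamma`.
#'
#' @param x numeric feature matrix (training samples).
#' @param y factor of class labels (2 levels).
#' @param grid list with `C` and `gamma` candidate vectors.
#' @param n_folds cross-validation folds.
#' @return list with the chosen `C`, `gamma` and its `cv_accuracy`.
#' @export
grid_search_svm <- function(x, y, grid = default_svm_grid(), n_folds = 5L) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("grid search needs at least 2 classes")
  if (length(grid$C) == 0 || length(grid$gamma) == 0)
    stop("empty hyper-parameter grid")
  n_folds <- min(n_folds, min(table(y)))
  fold <- stratified_folds(y, n_folds)
  cand <- expand.grid(C = sort(grid$C), gamma = sort(grid$gamma))
  cand <- cand[order(cand$C, cand$gamma), ]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = cand$C[i], gamma = cand$gamma[i], scale = FALSE)
      pred <- stats::predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc <- correct / length(y)
    if (is.null(best) || acc > best$cv_accuracy) # strict: ties keep first
      best <- list(C = cand$C[i], gamma = cand$gamma[i], cv_accuracy = acc)
  }
  best
}

#' Train an RBF-kernel SVM
#'
#' @param x numeric feature matrix (rows already normalized with the
#'   training min-max parameters).
#' @param y factor of class labels.
#' @param C soft-margin penalty.
#' @param gamma RBF width (`exp(-gamma ||x-y||^2)`).
#' @return a fitted `e1071::svm` model with decision values enabled.
#' @export
train_svm <- function(x, y, C = 10, gamma = 0.2) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("training set contains a single class")
  e1071::svm(x, y, kernel = "radial", cost = C, gamma = gamma, scale = FALSE)
}

#' Predict labels and decision scores
#'
#' @param model a model from [train_svm()].
#' @param x feature matrix of test samples.
#' @return list with `label` (factor) and `score` (numeric decision values,
#'   oriented so larger means more likely the positive -- second -- level).
#' @export
predict_svm <- function(model, x) {
  pred <- stats::predict(model, x, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  score <- dv[, 1]
  # e1071 orients decision values toward the first label in the colname
  # "A/B"; flip so larger score means the second factor level
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (identical(first, model$levels[1])) score <- -score
  list(label = pred, score = as.numeric(score))
}

#' Binary classification metrics
#'
#' Treats the second factor level of `truth` as the positive class.
#' Accuracy, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F1
#' `2TP/(2TP+FP+FN)`, Cohen's kappa, and AUC as the rank statistic
#' (probability that a positive scores above a negative, ties counted
#' half). Rates are returned in percent; kappa on the \[-100, 100\] scale.
#'
#' @param truth factor (2 levels) of true labels.
#' @param pred factor of predicted labels.
#' @param score numeric decision scores for AUC (larger = more positive);
#'   optional.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc`, `f1`,
#'   `kappa` (all percent) and the 2x2 `confusion` matrix
#'   (rows = truth, cols = prediction).
#' @examples
#' truth <- factor(rep(c("neg", "pos"), c(40, 60)), levels = c("neg", "pos"))
#' pred <- factor(rep(c("neg", "pos", "neg", "pos"), c(30, 10, 10, 50)),
#'                levels = c("neg", "pos"))
#' classification_metrics(truth, pred)
#' @export
classification_metrics <- function(truth, pred, score = NULL) {
  truth <- as.factor(truth)
  if (nlevels(truth) != 2) stop("metrics are defined for binary labels")
  pred <- factor(pred, levels = levels(truth))
  pos <- levels(truth)[2]
  neg <- levels(truth)[1]
  if (!all(c(pos, neg) %in% truth))
    warning("a class is absent from the truth labels; ",
            "sensitivity/specificity are undefined for it")
  tp <- sum(truth == pos & pred == pos)
  fn <- sum(truth == pos & pred == neg)
  tn <- sum(truth == neg & pred == neg)
  fp <- sum(truth == neg & pred == pos)
  n <- tp + fn + tn + fp
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  p_yes <- ((tp + fp) / n) * ((tp + fn) / n)
  p_no <- ((tn + fn) / n) * ((tn + fp) / n)
  pe <- p_yes + p_no
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  auc <- if (is.null(score)) NA_real_ else rank_auc(truth == pos, score)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                      dimnames = list(truth = c(neg, pos),
                                      pred = c(neg, pos)))
  list(accuracy = 100 * acc, sensitivity = 100 * sens,
       specificity = 100 * spec, auc = 100 * auc, f1 = 100 * f1,
       kappa = 100 * kappa, confusion = confusion)
}

#' Rank-statistic AUC
#'
#' `P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)`, computed from
#' the rank sum of the positive scores.
#'
#' @param positive logical vector: is the sample a positive?
#' @param score numeric decision scores.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(positive, score) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

fit_predict <- function(classifier, x_tr, y_tr, x_te, grid, grid_once_cfg) {
  switch(classifier,
    svm = {
      cfg <- if (is.null(grid_once_cfg))
        grid_search_svm(x_tr, y_tr, grid) else grid_once_cfg
      model <- train_svm(x_tr, y_tr, C = cfg$C, gamma = cfg$gamma)
      predict_svm(model, x_te)
    },
    naive_bayes = {
      model <- multinomial_nb(x_tr, y_tr)
      predict_multinomial_nb(model, x_te)
    },
    gbdt = {
      model <- gbdt_fit(x_tr, y_tr)
      gbdt_predict(model, x_te, levels(droplevels(y_tr)))
    },
    stop("unknown classifier: ", classifier))
}

#' Repeated stratified 70/30 evaluation
#'
#' For each repeat: a stratified random split into 70% training and 30%
#' test, hyper-parameter selection and fitting on the training part only,
#' metrics on the test part. Reports the per-repeat metrics, their means,
#' the 2.5-97.5 percentile interval of each metric across repeats, and the
#' confusion matrix pooled over repeats. With a fixed `seed` the whole
#' protocol is reproducible, and different classifiers evaluated under the
#' same seed see identical splits.
#'
#' @param x numeric feature matrix (all samples; already normalized).
#' @param y factor of binary labels.
#' @param n_repeats number of random splits.
#' @param test_frac test fraction.
#' @param seed seed for the split stream.
#' @param classifier `"svm"`, `"naive_bayes"` or `"gbdt"`.
#' @param grid SVM hyper-parameter grid (ignored by the baselines).
#' @param grid_once run the grid search once on the full data and reuse the
#'   chosen `(C, gamma)` for every repeat, instead of re-searching per
#'   repeat.
#' @param prepare optional `function(x_train, y_train, x_test)` returning
#'   `list(train, test)`: per-split preprocessing (normalization, feature
#'   selection) fitted on the training part only and applied to both, so
#'   no information from the test samples reaches the model.
#' @param permute_labels run the permutation null: labels are freshly
#'   shuffled before every repeat's split, so the mean metrics estimate
#'   chance-level performance of the full pipeline (a single fixed shuffle
#'   has large across-shuffle variance at small n; averaging over one
#'   permutation per repeat is the standard resampling null).
#' @return an `eval_result`: list with `mean` (named metric means),
#'   `interval` (2.5/97.5 percentiles per metric), `per_repeat`
#'   (data.frame), `confusion` (pooled counts), `classifier`, `n_repeats`,
#'   and `splits` (the test-index sets, drawn from the seed alone).
#' @export
repeated_eval <- function(x, y, n_repeats = 1000L, test_frac = 0.3,
                          seed = 1L, classifier = "svm",
                          grid = default_svm_grid(), grid_once = FALSE,
                          prepare = NULL, permute_labels = FALSE) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("repeated evaluation expects binary labels")
  if (any(table(y) < 2)) stop("each class needs at least 2 samples to stratify")
  stopifnot(n_repeats >= 1)

  metrics_names <- c("accuracy", "sensitivity", "specificity", "auc", "f1",
                     "kappa")
  per <- matrix(NA_real_, n_repeats, length(metrics_names),
                dimnames = list(NULL, metrics_names))
  pooled <- matrix(0, 2, 2, dimnames = list(truth = levels(y),
                                            pred = levels(y)))
  # splits (and any label permutations) are drawn up front from the seed
  # alone, so every classifier evaluated under one seed sees the identical
  # split stream
  splits <- with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    y_r <- if (permute_labels) sample(y) else y
    list(test = stratified_test_idx(y_r, test_frac), y = y_r)
  }))
  with_seed(seed + 1L, {
    grid_once_cfg <- if (grid_once && classifier == "svm")
      grid_search_svm(x, y, grid) else NULL
    for (r in seq_len(n_repeats)) {
      te <- splits[[r]]$test
      y_r <- splits[[r]]$y
      tr <- setdiff(seq_len(nrow(x)), te)
      x_tr <- x[tr, , drop = FALSE]
      x_te <- x[te, , drop = FALSE]
      if (!is.null(prepare)) {
        pp <- prepare(x_tr, y_r[tr], x_te)
        x_tr <- pp$train
        x_te <- pp$test
      }
      out <- fit_predict(classifier, x_tr, y_r[tr], x_te, grid, grid_once_cfg)
      m <- classification_metrics(y_r[te], out$label, out$score)
      per[r, ] <- unlist(m[metrics_names])
      pooled <- pooled + m$confusion
    }
  })
  means <- colMeans(per)
  interval <- apply(per, 2, stats::quantile, probs = c(0.025, 0.975),
                    na.rm = TRUE)
  structure(list(mean = means, interval = interval,
                 per_repeat = as.data.frame(per), confusion = pooled,
                 classifier = classifier, n_repeats = n_repeats,
                 splits = splits),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> %s, %d repeat(s)\n", x$classifier, x$n_repeats))
  for (m in names(x$mean))
    cat(sprintf("  %-12s %6.2f  (%.2f-%.2f)\n", m, x$mean[[m]],
                x$interval[1, m], x$interval[2, m]))
  invisible(x)
}

#' Baseline classifiers under the identical split protocol
#'
#' Multinomial naive Bayes (Laplace smoothing 1.0, fitted class priors;
#' the \[0,1\]-normalized features are used directly as non-negative event
#' weights) and gradient-boosted decision trees (100 iterations, learning
#' rate 1.0), each evaluated with [repeated_eval()] under the same seed --
#' hence the same splits -- as the SVM.
#'
#' @inheritParams repeated_eval
#' @param which baselines to run.
#' @return named list of `eval_result`, one per baseline.
#' @export
baselines <- function(x, y, n_repeats = 1000L, test_frac = 0.3, seed = 1L,
                      which = c("naive_bayes", "gbdt")) {
  out <- list()
  for (b in which)
    out[[b]] <- repeated_eval(x, y, n_repeats = n_repeats,
                              test_frac = test_frac, seed = seed,
                              classifier = b)
  out
}

# --- multinomial naive Bayes ------------------------------------------------
# Features on [0,1] act as fractional event counts; Laplace alpha = 1.

multinomial_nb <- function(x, y, alpha = 1) {
  y <- droplevels(as.factor(y))
  if (any(x < 0)) stop("multinomial naive Bayes needs non-negative features")
  classes <- levels(y)
  log_prior <- log(as.numeric(table(y)) / length(y))
  log_theta <- t(vapply(classes, function(cl) {
    s <- colSums(x[y == cl, , drop = FALSE]) + alpha
    log(s / sum(s))
  }, numeric(ncol(x))))
  list(classes = classes, log_prior = log_prior, log_theta = log_theta)
}

predict_multinomial_nb <- function(model, x) {
  scores <- x %*% t(model$log_theta)
  scores <- sweep(scores, 2, model$log_prior, "+")
  lab <- factor(model$classes[max.col(scores, ties.method = "first")],
                levels = model$classes)
  list(label = lab, score = scores[, 2] - scores[, 1])
}

#' Gaussian naive Bayes variant
#'
#' Alternative to the multinomial model for continuous features; wraps
#' [e1071::naiveBayes()].
#'
#' @param x feature matrix; `y` factor labels.
#' @param y factor of labels.
#' @return fitted model usable with `predict`.
#' @export
gaussian_nb <- function(x, y) {
  e1071::naiveBayes(x, droplevels(as.factor(y)))
}

# --- gradient-boosted trees -------------------------------------------------

gbdt_fit <- function(x, y, nrounds = 100L, eta = 1.0) {
  y <- droplevels(as.factor(y))
  xgboost::xgboost(x, y, objective = "binary:logistic", nrounds = nrounds,
                   learning_rate = eta, max_depth = 3, nthreads = 1,
                   verbosity = 0)
}

gbdt_predict <- function(model, x, classes) {
  p <- stats::predict(model, x, type = "response")
  if (is.matrix(p)) p <- p[, ncol(p)]
  lab <- factor(classes[as.integer(p > 0.5) + 1L], levels = classes)
  list(label = lab, score = as.numeric(p))
}
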