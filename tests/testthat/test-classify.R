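test_that("grid search maximizes CV accuracy with smallest-C tie-break", {
  b <- blob_data(n_per_class = 15, seed = 2)

  single <- grid_search_svm(b$x, b$y, grid = list(C = 3, gamma = 0.5))
  expect_equal(single$C, 3)
  expect_equal(single$gamma, 0.5)

  with_seed <- get("with_seed", asNamespace("copdls"))
  best <- with_seed(1, grid_search_svm(b$x, b$y))
  expect_equal(best$cv_accuracy, 1) # separable: some config is perfect
  # every grid value with smaller C than the winner must be sub-perfect,
  # otherwise the tie-break was violated
  grid <- default_svm_grid()
  smaller <- grid$C[grid$C < best$C]
  for (C in smaller) {
    acc <- with_seed(1, grid_search_svm(b$x, b$y,
                                        grid = list(C = C, gamma = grid$gamma)))
    expect_lt(acc$cv_accuracy, 1)
  }

  expect_error(grid_search_svm(b$x, b$y, grid = list(C = numeric(0),
                                                     gamma = 1)), "empty")
})

test_that("the RBF SVM separates blobs and is consistent on duplicates", {
  b <- blob_data(n_per_class = 25, seed = 3)
  tr <- c(1:20, 26:45)
  te <- setdiff(seq_len(50), tr)
  model <- train_svm(b$x[tr, ], b$y[tr], C = 10, gamma = 0.2)
  out <- predict_svm(model, b$x[te, ])
  expect_equal(as.character(out$label), as.character(b$y[te]))

  # 100% training accuracy on a separable problem
  tr_out <- predict_svm(model, b$x[tr, ])
  expect_equal(as.character(tr_out$label), as.character(b$y[tr]))

  # a duplicated training point keeps its label
  dup <- predict_svm(model, b$x[c(1, 1), , drop = FALSE])
  expect_equal(as.character(dup$label[1]), as.character(dup$label[2]))

  # decision scores orient toward the positive (second) level
  expect_gt(mean(out$score[b$y[te] == "b"]), mean(out$score[b$y[te] == "a"]))

  expect_error(train_svm(b$x[1:10, ], b$y[1:10]), "single class")
})

test_that("metric arithmetic matches the definitional formulas", {
  perfect <- classification_metrics(
    factor(rep(c("n", "p"), each = 10), levels = c("n", "p")),
    factor(rep(c("n", "p"), each = 10), levels = c("n", "p")))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$kappa, 100)

  chance <- classification_metrics(
    factor(rep(c("n", "p"), each = 10), levels = c("n", "p")),
    factor(rep(c("n", "p", "p", "n"), each = 5), levels = c("n", "p")))
  expect_equal(chance$accuracy, 50)
  expect_equal(chance$kappa, 0)

  # TP=50 FN=10 TN=30 FP=10
  truth <- factor(rep(c("p", "n"), c(60, 40)), levels = c("n", "p"))
  pred <- factor(rep(c("p", "n", "p", "n"), c(50, 10, 10, 30)),
                 levels = c("n", "p"))
  m <- classification_metrics(truth, pred)
  expect_equal(m$sensitivity, 100 * 50 / 60, tolerance = 1e-12)
  expect_equal(m$specificity, 75)
  expect_equal(m$accuracy, 80)
  expect_equal(m$f1, 100 * 2 * 50 / (2 * 50 + 10 + 10), tolerance = 1e-12)
  expect_equal(m$confusion, matrix(c(30, 10, 10, 50), 2, 2, byrow = TRUE,
                                   dimnames = list(truth = c("n", "p"),
                                                   pred = c("n", "p"))))

  # kappa vanishes whenever prediction is independent of truth
  ind_truth <- factor(rep(c("n", "p"), c(30, 70)), levels = c("n", "p"))
  ind_pred <- factor(rep(c("n", "p", "n", "p"), c(12, 18, 28, 42)),
                     levels = c("n", "p"))
  expect_equal(classification_metrics(ind_truth, ind_pred)$kappa, 0,
               tolerance = 1e-10)
})

test_that("rank AUC equals brute-force pairwise comparison and pROC", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    positive <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(positive) || all(positive)) next
    score <- round(rnorm(n), 1) # rounding forces some ties
    expect_equal(rank_auc(positive, score), oracle_auc(positive, score),
                 tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(10)
    positive <- rep(c(TRUE, FALSE), each = 15)
    score <- rnorm(30) + positive
    expect_equal(rank_auc(positive, score),
                 as.numeric(pROC::auc(pROC::roc(positive, score,
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("repeated evaluation is seeded, stratified and interval-consistent", {
  b <- blob_data(n_per_class = 12, seed = 4)

  one <- repeated_eval(b$x, b$y, n_repeats = 1, seed = 5,
                       grid = list(C = 10, gamma = 0.2))
  expect_equal(unname(one$interval["2.5%", "accuracy"]),
               unname(one$mean[["accuracy"]]))

  ev <- repeated_eval(b$x, b$y, n_repeats = 15, seed = 5,
                      grid = list(C = 10, gamma = 0.2))
  expect_equal(unname(ev$mean[["accuracy"]]), 100)
  expect_equal(unname(diff(ev$interval[, "accuracy"])), 0)
  # mean lies inside the percentile interval by construction
  for (m in colnames(ev$interval))
    expect_true(ev$mean[[m]] >= ev$interval[1, m] - 1e-9 &&
                  ev$mean[[m]] <= ev$interval[2, m] + 1e-9)

  again <- repeated_eval(b$x, b$y, n_repeats = 15, seed = 5,
                         grid = list(C = 10, gamma = 0.2))
  expect_identical(ev$per_repeat, again$per_repeat)
  expect_identical(ev$confusion, again$confusion)

  expect_error(repeated_eval(b$x[c(1, 2, 24), ], b$y[c(1, 2, 24)],
                             n_repeats = 2, seed = 1), "at least 2 samples")
})

test_that("baselines beat 90% on separable blobs and share the split stream", {
  # anti-diagonal centres so the classes differ in feature *composition*,
  # which is what the multinomial model can see
  b <- blob_data(n_per_class = 12, seed = 6,
                 center_a = c(0, 6), center_b = c(6, 0))
  svm_ev <- repeated_eval(b$x, b$y, n_repeats = 10, seed = 7,
                          grid = list(C = 10, gamma = 0.2))
  # multinomial NB needs non-negative features: shift blobs into [0,1]
  x01 <- apply(b$x, 2, function(col) (col - min(col)) / diff(range(col)))
  base <- baselines(x01, b$y, n_repeats = 10, seed = 7)
  expect_gt(base$naive_bayes$mean[["accuracy"]], 90)
  expect_gt(base$gbdt$mean[["accuracy"]], 90)
  expect_identical(base$naive_bayes$splits, svm_ev$splits)
  expect_identical(base$gbdt$splits, svm_ev$splits)
})
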