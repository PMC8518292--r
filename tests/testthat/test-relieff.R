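make_table <- function(X, y) {
  colnames(X) <- paste0("F", seq_len(ncol(X)))
  info <- data.frame(channel = rep("L1", ncol(X)),
                     imf = 1L, stat = colnames(X),
                     stringsAsFactors = FALSE)
  structure(list(features = X, info = info, label = factor(y),
                 subject_id = paste0("s", seq_len(nrow(X)))),
            class = "feature_table")
}

test_that("min-max normalization maps to [0,1], stores ranges, flags constants", {
  X <- cbind(a = c(2, 4, 6), b = c(0, 0.5, 1), c = c(3, 3, 3))
  tab <- make_table(X, c("x", "y", "x"))
  expect_warning(norm <- minmax_normalize(tab), "constant")
  expect_equal(unname(norm$features[, 1]), c(0, 0.5, 1))
  expect_equal(unname(norm$features[, 2]), c(0, 0.5, 1)) # idempotent column
  expect_equal(unname(norm$features[, 3]), c(0, 0, 0))

  rng <- attr(norm, "ranges")
  test <- make_table(cbind(a = c(3, 5), b = c(0.25, 2), c = c(3, 3)),
                     c("x", "y"))
  tr <- apply_normalization(test, rng)
  expect_equal(unname(tr$features[, 1]), c(0.25, 0.75))
  expect_equal(unname(tr$features[, 2]), c(0.25, 1)) # clipped at 1
})

test_that("reliefF rewards the separating feature and zeroes constants", {
  set.seed(5)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(F1 = ifelse(y == "a", 0, 1),
             F2 = runif(n),
             F3 = rep(0.5, n))
  w <- relieff_weights(make_table(X, y), k = 3)
  expect_gt(w$weight[["F1"]], w$weight[["F2"]])
  expect_gt(w$weight[["F1"]], 0.5)
  expect_identical(w$weight[["F3"]], 0)

  # brute-force transcription of the weight update agrees
  ref <- oracle_relieff(X, factor(y), k = 3)
  expect_equal(unname(w$weight), ref, tolerance = 1e-12)
})

test_that("with k = 1 and m = n reliefF reduces to classic binary relief", {
  set.seed(11)
  for (i in 1:3) {
    n <- 30
    y <- factor(rep(c("a", "b"), each = n / 2))
    X <- matrix(runif(n * 5), n, 5)
    X[, 1] <- X[, 1] + ifelse(y == "b", 0.8, 0)
    X <- apply(X, 2, function(col) (col - min(col)) / diff(range(col)))
    w <- relieff_weights(make_table(X, y), k = 1)
    ref <- oracle_relief_binary(X, y)
    expect_equal(unname(w$weight), ref, tolerance = 1e-12)
  }
})

test_that("weights are invariant to feature order", {
  set.seed(21)
  n <- 24
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- matrix(runif(n * 6), n, 6)
  X[, 2] <- X[, 2] + ifelse(y == "b", 1, 0)
  w1 <- relieff_weights(make_table(X, y), k = 2)
  perm <- c(4, 1, 6, 2, 5, 3)
  w2 <- relieff_weights(make_table(X[, perm], y), k = 2)
  expect_equal(unname(w2$weight), unname(w1$weight[perm]), tolerance = 1e-12)
})

test_that("label shuffling collapses the discriminative weight", {
  set.seed(31)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(F1 = ifelse(y == "a", 0, 1) + rnorm(n, sd = 0.05),
             F2 = runif(n))
  X <- apply(X, 2, function(col) (col - min(col)) / diff(range(col)))
  w_true <- relieff_weights(make_table(X, y), k = 3)$weight[["F1"]]
  null_w <- replicate(40, {
    ys <- sample(y)
    max(abs(relieff_weights(make_table(X, ys), k = 3)$weight))
  })
  expect_gt(w_true, quantile(null_w, 0.95))
})

test_that("reliefF rejects classes smaller than k + 1 and clamps m", {
  X <- matrix(runif(12), 6, 2)
  y <- rep(c("a", "b"), each = 3)
  expect_error(relieff_weights(make_table(X, y), k = 3), "more than k")
  expect_warning(relieff_weights(make_table(X, y), m = 10, k = 2),
                 "clamped")
})

test_that("negative-weight pruning keeps the W >= 0 boundary", {
  w <- structure(list(weight = c(F1 = 0.2, F2 = -0.1, F3 = 0),
                      info = data.frame(channel = c("L1", "L2", "L3"),
                                        imf = 1L, stat = "sd"),
                      m = 3L, k = 1L),
                 class = "relieff_weights")
  kept <- prune_negative(w)
  expect_equal(names(kept$weight), c("F1", "F3"))

  all_pos <- w; all_pos$weight <- abs(w$weight) + 0.01
  expect_equal(length(prune_negative(all_pos)$weight), 3)

  all_neg <- w; all_neg$weight <- -abs(w$weight) - 0.01
  expect_warning(out <- prune_negative(all_neg), "negative")
  expect_length(out$weight, 0)
})

test_that("channel ranking sums retained weights with label-order ties", {
  w <- structure(list(
    weight = c(a = 0.5, b = 0.4, c = 0.3, d = 0.6),
    info = data.frame(channel = c("L2", "L2", "R1", "L5"),
                      imf = 1L, stat = "sd"),
    m = 4L, k = 1L), class = "relieff_weights")
  r <- rank_channels(w)
  expect_equal(r$channel[1], "L2")       # 0.9 beats 0.6 and 0.3
  expect_equal(r$total_weight, c(0.9, 0.6, 0.3))

  tie <- w
  tie$weight <- c(a = 0.3, b = 0.3, c = 0.6, d = 0.6)
  rt <- rank_channels(tie)                # L2 and L5 tie at 0.6 with R1
  expect_equal(rt$channel, c("L2", "L5", "R1")) # canonical label order
})

test_that("top-n selection restricts to channels and orders by weight", {
  set.seed(41)
  w <- structure(list(
    weight = stats::setNames(runif(120), paste0("f", 1:120)),
    info = data.frame(channel = rep(c("L1", "L2", "L3", "L4"), each = 30),
                      imf = rep(1:3, 40), stat = "sd"),
    m = 10L, k = 3L), class = "relieff_weights")
  sel25 <- select_top(w, channels = c("L2", "L4", "L1"), n = 25)
  expect_length(sel25, 25)
  expect_true(all(w$info$channel[match(sel25, names(w$weight))] %in%
                    c("L2", "L4", "L1")))
  expect_true(all(diff(w$weight[sel25]) <= 0))

  sel33 <- select_top(w, channels = c("L4", "L3"), n = 33)
  expect_length(sel33, 33)

  all_in <- select_top(w, channels = "L1", n = 30)
  expect_setequal(all_in, names(w$weight)[w$info$channel == "L1"])
  expect_error(select_top(w, channels = "L1", n = 31), "only 30")
})
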