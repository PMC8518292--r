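#' Min-max normalization of a feature table to \[0, 1\]
#'
#' Each feature is mapped linearly onto \[0, 1\]. The per-feature `(min,
#' max)` pairs are stored in the result (attribute `ranges`) so held-out
#' data can be transformed with the training parameters via
#' [apply_normalization()]. Constant features are mapped to 0 with a
#' warning.
#'
#' @param table a `feature_table`.
#' @return the normalized `feature_table`, with attribute `ranges`.
#' @export
minmax_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  lo <- apply(table$features, 2, min)
  hi <- apply(table$features, 2, max)
  flat <- hi <= lo
  if (any(flat))
    warning(sum(flat), " constant feature(s) mapped to 0")
  rng <- hi - lo
  rng[flat] <- 1
  table$features <- sweep(sweep(table$features, 2, lo), 2, rng, "/")
  table$features[, flat] <- 0
  attr(table, "ranges") <- list(min = lo, max = hi)
  table
}

#' Apply stored min-max parameters to new data
#'
#' @param table a `feature_table` of held-out samples.
#' @param ranges the `ranges` attribute of a table returned by
#'   [minmax_normalize()].
#' @return the transformed `feature_table` (values clipped to \[0, 1\]).
#' @export
apply_normalization <- function(table, ranges) {
  rng <- ranges$max - ranges$min
  rng[rng <= 0] <- 1
  table$features <- sweep(sweep(table$features, 2, ranges$min), 2, rng, "/")
  table$features <- pmin(pmax(table$features, 0), 1)
  table
}

#' Multi-class reliefF feature weights
#'
#' The reliefF filter scores each feature by how well it separates nearest
#' neighbours of different classes. For each of `m` sampled instances R,
#' the k nearest same-class neighbours (hits) pull the weight down by their
#' mean feature difference, and for every other class C the k nearest
#' neighbours of that class (misses) push it up, weighted by the class
#' prior `p(C) / (1 - p(class(R)))`:
#'
#' `W(A) <- W(A) - sum_j diff(A,R,H_j)/(m k)
#'        + sum_C p(C)/(1-p(class(R))) sum_j diff(A,R,M_j(C))/(m k)`
#'
#' `diff` is the range-normalized absolute difference (plain absolute
#' difference after \[0,1\] normalization). Neighbours are found with the
#' Manhattan distance over all features (Euclidean available). By default
#' every instance is sampled exactly once in order (`m = n`), which makes
#' the weights deterministic; a smaller `m` samples without replacement
#' under `seed`.
#'
#' @param table a normalized `feature_table` (see [minmax_normalize()]).
#' @param m number of sampled instances; default `n` (all, in order).
#' @param k nearest neighbours per class.
#' @param seed seed for subsampling when `m < n`.
#' @param metric neighbour-search distance.
#' @return a `relieff_weights` object: list with `weight` (named numeric),
#'   `info` (feature metadata), `m`, `k`.
#' @export
relieff_weights <- function(table, m = NULL, k = 10L, seed = 1L,
                            metric = c("manhattan", "euclidean")) {
  stopifnot(inherits(table, "feature_table"))
  metric <- match.arg(metric)
  X <- table$features
  y <- table$label
  n <- nrow(X)
  classes <- levels(droplevels(y))
  y <- droplevels(y)
  if (length(classes) < 2) stop("reliefF needs at least 2 classes")
  counts <- table(y)
  if (any(counts <= k))
    stop("every class must have more than k = ", k, " members")
  if (is.null(m)) m <- n
  if (m > n) {
    warning("m > n; clamped to n = ", n)
    m <- n
  }
  idx <- if (m == n) seq_len(n) else with_seed(seed, sample.int(n, m))
  p <- as.numeric(counts) / n
  names(p) <- names(counts)

  D <- as.matrix(stats::dist(X, method = metric))
  W <- numeric(ncol(X))
  for (r in idx) {
    same <- which(y == y[r])
    same <- same[same != r]
    hits <- same[order(D[r, same])][seq_len(k)]
    hit_term <- colSums(abs(X[hits, , drop = FALSE] -
                              matrix(X[r, ], k, ncol(X), byrow = TRUE)))
    W <- W - hit_term / (m * k)
    for (cl in setdiff(names(p), as.character(y[r]))) {
      other <- which(y == cl)
      misses <- other[order(D[r, other])][seq_len(min(k, length(other)))]
      kk <- length(misses)
      miss_term <- colSums(abs(X[misses, , drop = FALSE] -
                                 matrix(X[r, ], kk, ncol(X), byrow = TRUE)))
      wC <- p[[cl]] / (1 - p[[as.character(y[r])]])
      W <- W + wC * miss_term * (k / kk) / (m * k)
    }
  }
  names(W) <- colnames(X)
  structure(list(weight = W, info = table$info, m = m, k = k),
            class = "relieff_weights")
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat(sprintf("<relieff_weights> %d feature(s), m = %d, k = %d\n",
              length(x$weight), x$m, x$k))
  top <- sort(x$weight, decreasing = TRUE)[seq_len(min(5, length(x$weight)))]
  cat("  top:", paste(sprintf("%s=%.4f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Drop features with negative reliefF weight
#'
#' Features whose weight is below zero separate same-class neighbours more
#' than different-class ones and are eliminated; weight exactly 0 is kept.
#'
#' @param w a `relieff_weights` object.
#' @return a `relieff_weights` object restricted to `W >= 0` features.
#' @export
prune_negative <- function(w) {
  stopifnot(inherits(w, "relieff_weights"))
  keep <- w$weight >= 0
  if (!any(keep)) warning("all feature weights are negative; nothing retained")
  w$weight <- w$weight[keep]
  w$info <- w$info[keep, , drop = FALSE]
  w
}

#' Rank channels by summed retained feature weight
#'
#' Adds up the (pruned, non-negative) weights of every feature belonging to
#' each channel and orders the channels by that total, largest first. Ties
#' break deterministically by canonical channel-label order (L1..L6,
#' R1..R6).
#'
#' @param w a pruned `relieff_weights` object (see [prune_negative()]).
#' @return a `channel_ranking`: data.frame with `channel`, `total_weight`,
#'   `rank`.
#' @export
rank_channels <- function(w) {
  stopifnot(inherits(w, "relieff_weights"), !is.null(w$info))
  chans <- unique(w$info$channel)
  canon <- intersect(channel_labels(), chans)
  canon <- c(canon, setdiff(chans, canon))
  total <- vapply(canon, function(ch)
    sum(w$weight[w$info$channel == ch]), numeric(1))
  ord <- order(-total, match(canon, canon)) # stable: ties keep label order
  out <- data.frame(channel = canon[ord], total_weight = total[ord],
                    rank = seq_along(canon), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_ranking", "data.frame")
  out
}

#' Select the top-weighted features within chosen channels
#'
#' @param w a `relieff_weights` object (typically pruned).
#' @param channels channel labels to restrict to; `NULL` keeps all.
#' @param n number of features to select.
#' @return character vector of `n` feature names, in decreasing weight
#'   order.
#' @export
select_top <- function(w, channels = NULL, n) {
  stopifnot(inherits(w, "relieff_weights"))
  keep <- if (is.null(channels)) rep(TRUE, length(w$weight))
          else w$info$channel %in% channels
  ww <- w$weight[keep]
  if (n > length(ww))
    stop("requested ", n, " features but only ", length(ww),
         " retained in the chosen channels")
  names(sort(ww, decreasing = TRUE))[seq_len(n)]
}
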