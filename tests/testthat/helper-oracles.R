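# Independent oracle implementations used only to cross-check the package.
# Written deliberately as plain, naive R with base/stats primitives and no
# shared code with the implementation under test.

# --- EMD oracle -------------------------------------------------------------

oracle_extrema <- function(x) {
  n <- length(x)
  maxima <- integer(0)
  minima <- integer(0)
  prev <- 0
  for (i in 1:(n - 1)) {
    d <- x[i + 1] - x[i]
    s <- sign(d)
    if (s == 0) next
    if (prev > 0 && s < 0) maxima <- c(maxima, i)
    if (prev < 0 && s > 0) minima <- c(minima, i)
    prev <- s
  }
  list(maxima = maxima, minima = minima)
}

oracle_envelope_of <- function(idx, x) {
  n <- length(x)
  # mirror the two nearest extrema about each end (0-based positions to
  # match sample-time interpretation)
  pos <- idx - 1
  val <- x[idx]
  left <- which(pos > 0)[1:2]
  left <- left[!is.na(left)]
  if (length(left) == 0) {
    lp <- -1; lv <- val[1]
  } else {
    lp <- rev(-pos[left]); lv <- rev(val[left])
  }
  right <- rev(which(pos < n - 1))
  right <- right[seq_len(min(2, length(right)))]
  if (length(right) == 0) {
    rp <- n; rv <- val[length(val)]
  } else {
    rp <- 2 * (n - 1) - pos[right]; rv <- val[right]
  }
  xs <- c(lp, pos, rp)
  ys <- c(lv, val, rv)
  f <- stats::splinefun(xs, ys, method = "natural")
  f(0:(n - 1))
}

oracle_mean_env <- function(x) {
  e <- oracle_extrema(x)
  if (length(e$maxima) < 2 || length(e$minima) < 2) return(NULL)
  up <- oracle_envelope_of(e$maxima, x)
  lo <- oracle_envelope_of(e$minima, x)
  (up + lo) / 2
}

oracle_sift <- function(x, sd_tol = 0.2, max_sift = 50) {
  m <- x
  for (it in 1:max_sift) {
    env <- oracle_mean_env(m)
    if (is.null(env)) break
    sd_crit <- sum(env^2) / sum(m^2)
    m <- m - env
    if (sd_crit < sd_tol) break
  }
  m
}

oracle_emd <- function(x, max_imfs = 20) {
  resid <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    e <- oracle_extrema(resid)
    if (length(e$maxima) < 2 || length(e$minima) < 2) break
    imf <- oracle_sift(resid)
    imfs[[length(imfs) + 1]] <- imf
    resid <- resid - imf
  }
  list(imfs = imfs, residual = resid)
}

# --- reliefF / relief oracle ------------------------------------------------

# Literal brute-force transcription of the multi-class weight update:
# for every sampled instance, k nearest hits and k nearest misses per
# opposite class (Manhattan distance), range-normalized absolute diff.
oracle_relieff <- function(X, y, k, m = nrow(X)) {
  n <- nrow(X)
  p <- table(y) / n
  W <- numeric(ncol(X))
  for (r in 1:m) {
    d <- apply(X, 1, function(row) sum(abs(row - X[r, ])))
    for (A in 1:ncol(X)) {
      hits <- setdiff(which(y == y[r]), r)
      hits <- hits[order(d[hits])][1:k]
      W[A] <- W[A] - sum(abs(X[hits, A] - X[r, A])) / (m * k)
      for (cl in setdiff(levels(y), as.character(y[r]))) {
        idx <- which(y == cl)
        misses <- idx[order(d[idx])][1:k]
        W[A] <- W[A] +
          (p[[cl]] / (1 - p[[as.character(y[r])]])) *
          sum(abs(X[misses, A] - X[r, A])) / (m * k)
      }
    }
  }
  W
}

# Classic binary relief (Kira & Rendell): single nearest hit and miss,
# every instance sampled once.
oracle_relief_binary <- function(X, y) {
  n <- nrow(X)
  W <- numeric(ncol(X))
  for (r in 1:n) {
    d <- apply(X, 1, function(row) sum(abs(row - X[r, ])))
    same <- setdiff(which(y == y[r]), r)
    other <- which(y != y[r])
    hit <- same[which.min(d[same])]
    miss <- other[which.min(d[other])]
    W <- W - abs(X[hit, ] - X[r, ]) / n + abs(X[miss, ] - X[r, ]) / n
  }
  as.numeric(W)
}

# --- statistics oracle ------------------------------------------------------

# Textbook formulas computed through a different algebraic route
# (raw-moment identities rather than centred sums).
oracle_stats <- function(x) {
  n <- length(x)
  m1 <- sum(x) / n
  m2 <- sum(x^2) / n
  v <- m2 - m1^2
  s <- sqrt(max(v, 0))
  kurt <- if (s > 0) sum(((x - m1) / s)^4) / n else 0
  skew <- if (s > 0) sum(((x - m1) / s)^3) / n else 0
  med <- {
    xs <- sort(x)
    if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  }
  c(sd = s, var = v, kurtosis = kurt, max = max(x), median = med,
    mean = m1, min = min(x), energy = sum(x * x), skewness = skew)
}

# --- AUC oracle -------------------------------------------------------------

oracle_auc <- function(positive, score) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
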