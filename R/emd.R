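new_imf_set <- function(imfs, residual) {
  structure(list(imfs = imfs, residual = residual,
                 source_length = length(residual)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, %d samples\n",
              ncol(x$imfs), x$source_length))
  invisible(x)
}

#' Number of intrinsic mode functions in an IMF set
#' @param x an `imf_set`.
#' @return integer count of IMFs (residual excluded).
#' @export
n_imfs <- function(x) ncol(x$imfs)

#' Reconstruct the source signal from an IMF set
#'
#' The decomposition is complete by construction: the IMFs plus the
#' residual telescope back to the input (exactly for plain EMD; within the
#' averaged-noise tolerance for the ensemble variant).
#'
#' @param x an `imf_set`.
#' @return numeric vector of `source_length` samples.
#' @export
reconstruct <- function(x) {
  stopifnot(inherits(x, "imf_set"))
  if (ncol(x$imfs) == 0) return(x$residual)
  rowSums(x$imfs) + x$residual
}

#' Upper, lower and mean envelopes of a signal
#'
#' Cubic splines (natural, with the two nearest extrema mirrored about each
#' end) through the local maxima and minima; the mean envelope is their
#' average. This is the elementary step of EMD sifting.
#'
#' @param x numeric vector with at least 2 maxima and 2 minima.
#' @return list with `upper`, `lower` and `mean`, each of `length(x)`.
#' @export
envelopes <- function(x) {
  cpp_envelopes(as.numeric(x))
}

#' Extract a single IMF candidate by sifting
#'
#' Repeatedly subtracts the mean envelope until the Cauchy criterion
#' `sum((m_prev - m_cur)^2) / sum(m_prev^2) < sd_tol` is met or `max_sift`
#' iterations are reached.
#'
#' @param x numeric vector.
#' @param sd_tol Cauchy stop threshold.
#' @param max_sift hard cap on sifting iterations.
#' @return numeric vector: the first IMF of `x`.
#' @export
sift <- function(x, sd_tol = 0.2, max_sift = 50L) {
  cpp_sift(as.numeric(x), sd_tol, as.integer(max_sift))
}

#' Empirical mode decomposition
#'
#' Successively sifts IMFs out of the running residual until the residual
#' is monotone (fewer than 2 maxima or minima) or `max_imfs` modes have
#' been extracted. The decomposition is exactly complete: the IMFs and the
#' final residual sum back to the input.
#'
#' @param x numeric vector.
#' @param max_imfs maximum number of IMFs to extract.
#' @param sd_tol,max_sift sifting stop parameters, see [sift()].
#' @return an `imf_set` with `imfs` (samples x modes matrix) and
#'   `residual`. A constant input yields zero IMFs and `residual = x`.
#' @examples
#' t <- seq(0, 1, by = 1 / 500)
#' x <- sin(2 * pi * 50 * t) + sin(2 * pi * 5 * t)
#' d <- emd(x)
#' max(abs(reconstruct(d) - x))
#' @export
emd <- function(x, max_imfs = 20L, sd_tol = 0.2, max_sift = 50L) {
  res <- cpp_emd(as.numeric(x), as.integer(max_imfs), sd_tol,
                 as.integer(max_sift))
  new_imf_set(res$imfs, res$residual)
}

#' Ensemble empirical mode decomposition
#'
#' Runs EMD on `ensemble_size` noise-perturbed copies of the signal
#' (`x + noise_std * white noise`) and averages mode k across members,
#' which suppresses the mode mixing plain EMD is prone to. Members that
#' produce fewer than `n_imf` modes contribute zeros in the missing modes;
#' modes beyond `n_imf` are folded, together with each member's trend, into
#' the returned residual. The output therefore always has exactly `n_imf`
#' IMFs.
#'
#' The input is standardised to unit variance before decomposition (so
#' `noise_std` is interpreted on the normalised amplitude scale) and
#' rescaled afterwards; set `standardize = FALSE` to add noise on the raw
#' scale.
#'
#' @param x numeric vector.
#' @param noise_std standard deviation of the ensemble noise.
#' @param ensemble_size number of noisy realisations averaged.
#' @param n_imf number of IMFs returned.
#' @param seed integer seed for the ensemble noise.
#' @param standardize standardise the input to unit variance first.
#' @param sd_tol,max_sift sifting stop parameters, see [sift()].
#' @return an `imf_set` with exactly `n_imf` IMFs. Reconstruction holds to
#'   the averaged-noise tolerance `noise_std / sqrt(ensemble_size)` (RMS).
#' @export
eemd <- function(x, noise_std = 0.015, ensemble_size = 100L, n_imf = 10L,
                 seed = 1L, standardize = TRUE, sd_tol = 0.2,
                 max_sift = 50L) {
  stopifnot(ensemble_size >= 1, n_imf >= 1)
  x <- as.numeric(x)
  n <- length(x)
  mu <- 0
  sc <- 1
  if (standardize) {
    mu <- mean(x)
    sc <- stats::sd(x)
    if (!is.finite(sc) || sc == 0) sc <- 1
    x <- (x - mu) / sc
  }
  acc_imfs <- matrix(0, n, n_imf)
  acc_resid <- numeric(n)
  with_seed(seed, {
    for (m in seq_len(ensemble_size)) {
      noisy <- if (noise_std > 0) x + noise_std * stats::rnorm(n) else x
      d <- cpp_emd(noisy, 1000L, sd_tol, as.integer(max_sift))
      k <- min(ncol(d$imfs), n_imf)
      if (k > 0)
        acc_imfs[, seq_len(k)] <- acc_imfs[, seq_len(k)] +
          d$imfs[, seq_len(k), drop = FALSE]
      extra <- if (ncol(d$imfs) > n_imf)
        rowSums(d$imfs[, (n_imf + 1L):ncol(d$imfs), drop = FALSE])
      else numeric(n)
      acc_resid <- acc_resid + extra + d$residual
    }
  })
  imfs <- acc_imfs / ensemble_size * sc
  residual <- acc_resid / ensemble_size * sc + mu
  new_imf_set(imfs, residual)
}
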