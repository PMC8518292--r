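#' Analytic signal of an IMF
#'
#' Discrete Hilbert transform via the FFT (negative frequencies zeroed,
#' positive doubled). The instantaneous amplitude is the modulus, the phase
#' the unwrapped argument, and the instantaneous frequency the forward
#' difference of the phase scaled to Hz, clipped to \[0, fs/2\] with the
#' final value repeated so all series have `length(x)` samples.
#'
#' @param x numeric vector (one IMF).
#' @param fs sampling rate in Hz.
#' @return an `analytic_imf`: list with `amplitude`, `phase`, `inst_freq`,
#'   `fs`.
#' @export
analytic_signal <- function(x, fs) {
  x <- as.numeric(x)
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  amplitude <- Mod(z)
  phase <- unwrap_phase(Arg(z))
  freq <- diff(phase) / (2 * pi) * fs
  freq <- pmin(pmax(freq, 0), fs / 2)
  inst_freq <- c(freq, freq[length(freq)])
  structure(list(amplitude = amplitude, phase = phase,
                 inst_freq = inst_freq, fs = fs),
            class = "analytic_imf")
}

unwrap_phase <- function(p) {
  d <- diff(p)
  jumps <- round(d / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}

#' Hilbert marginal spectrum of an IMF
#'
#' Accumulates the instantaneous amplitude into the frequency bin of the
#' concurrent instantaneous frequency, scaled by the sample interval: the
#' discrete time integral of the Hilbert spectrum, giving each frequency's
#' global amplitude contribution. Default binning is 1 Hz from 0 to the
#' Nyquist frequency.
#'
#' @param a an `analytic_imf` from [analytic_signal()].
#' @param bin_hz bin width in Hz.
#' @param f_max upper frequency limit; defaults to fs/2.
#' @return a `marginal_spectrum`: list with `freqs` (bin centres, Hz) and
#'   `amplitude` (accumulated amplitude per bin).
#' @export
marginal_spectrum <- function(a, bin_hz = 1, f_max = NULL) {
  stopifnot(inherits(a, "analytic_imf"), bin_hz > 0)
  if (is.null(f_max)) f_max <- a$fs / 2
  n_bins <- max(1L, ceiling(f_max / bin_hz))
  edges <- seq(0, by = bin_hz, length.out = n_bins + 1L)
  bin <- pmin(pmax(floor(a$inst_freq / bin_hz), 0), n_bins - 1L) + 1L
  dt <- 1 / a$fs
  amp <- numeric(n_bins)
  tab <- tapply(a$amplitude * dt, bin, sum)
  amp[as.integer(names(tab))] <- as.numeric(tab)
  structure(list(freqs = edges[-length(edges)] + bin_hz / 2, amplitude = amp),
            class = "marginal_spectrum")
}

#' Instantaneous energy density across IMFs
#'
#' The frequency integral of the squared Hilbert spectrum at each time:
#' discretely, the sum over IMFs of the squared instantaneous amplitude.
#'
#' @param analytic_list list of `analytic_imf` objects (all IMFs of one
#'   segment).
#' @return numeric vector `IE(t)`, one value per sample, non-negative.
#' @export
instantaneous_energy <- function(analytic_list) {
  stopifnot(length(analytic_list) > 0)
  Reduce(`+`, lapply(analytic_list, function(a) a$amplitude^2))
}

#' The ten summary statistics of a marginal-spectrum amplitude vector
#'
#' Population (divisor N) standard deviation and variance; energy as the
#' sum of squares; non-excess kurtosis `E[((X-mu)/sigma)^4]` and skewness
#' `E[((X-mu)/sigma)^3]`; maximum, median, mode, mean, minimum. The mode of
#' continuous amplitudes is the centre of the tallest histogram bin
#' (Freedman-Diaconis widths, ties toward the lower bin). A degenerate
#' (constant) vector gets kurtosis and skewness 0 with the `degenerate`
#' attribute set.
#'
#' @param x numeric vector (marginal-spectrum amplitudes, or any sample).
#' @return named numeric vector of the 10 statistics, in the fixed order
#'   `sd, var, kurtosis, max, median, mode, mean, min, energy, skewness`.
#' @examples
#' imf_statistics(c(1, 2, 3, 4))
#' @export
imf_statistics <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) > 0)
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  sdev <- sqrt(v)
  degenerate <- sdev == 0
  if (degenerate) {
    kurt <- 0
    skew <- 0
  } else {
    z <- (x - mu) / sdev
    kurt <- mean(z^4)
    skew <- mean(z^3)
  }
  out <- c(sd = sdev, var = v, kurtosis = kurt, max = max(x),
           median = stats::median(x), mode = amplitude_mode(x), mean = mu,
           min = min(x), energy = sum(x^2), skewness = skew)
  attr(out, "degenerate") <- degenerate
  out
}

# Histogram mode: Freedman-Diaconis bin width, centre of the tallest bin,
# ties broken toward the lower bin.
amplitude_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  iqr <- stats::IQR(x)
  bw <- 2 * iqr / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(range(x)) / ceiling(sqrt(length(x)))
  breaks <- seq(min(x), max(x) + bw, by = bw)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  i <- which.max(counts) # which.max takes the first (lowest) maximal bin
  breaks[i] + bw / 2
}

stat_names <- function() {
  c("sd", "var", "kurtosis", "max", "median", "mode",
    "mean", "min", "energy", "skewness")
}

#' Extract the HHT feature vector of one preprocessed recording
#'
#' Per channel: EEMD into `n_imf` IMFs, Hilbert marginal spectrum of each
#' IMF, then the ten summary statistics of each spectrum -- 10 x 10 = 100
#' features per channel, 1200 for a full 12-channel recording. Features are
#' ordered channel-major, then IMF, then statistic, and named
#' `<channel>_imf<k>_<stat>`.
#'
#' @param segments list of `lung_segment` (one per channel) from
#'   [preprocess_recording()] or [segment_recording()].
#' @param n_imf number of IMFs per channel.
#' @param noise_std,ensemble_size,seed EEMD parameters, see [eemd()].
#' @param bin_hz marginal-spectrum bin width in Hz.
#' @param domain `"marginal"` (default) computes the statistics on the
#'   Hilbert marginal-spectrum amplitudes of each IMF; `"time"` computes
#'   them on the IMF's time samples instead.
#' @return named numeric feature vector with attributes `subject_id`,
#'   `label`, and `info` (a data.frame mapping each feature to its
#'   channel, IMF and statistic).
#' @export
extract_features <- function(segments, n_imf = 10L, noise_std = 0.015,
                             ensemble_size = 100L, seed = 1L, bin_hz = 1,
                             domain = c("marginal", "time")) {
  domain <- match.arg(domain)
  stopifnot(length(segments) >= 1)
  sn <- stat_names()
  vals <- numeric(0)
  info <- list()
  for (seg in segments) {
    dec <- eemd(seg$waveform, noise_std = noise_std,
                ensemble_size = ensemble_size, n_imf = n_imf, seed = seed)
    for (k in seq_len(n_imf)) {
      imf <- dec$imfs[, k]
      x <- if (domain == "marginal") {
        marginal_spectrum(analytic_signal(imf, seg$fs), bin_hz = bin_hz)$amplitude
      } else {
        imf
      }
      st <- imf_statistics(x)
      names(st) <- paste0(seg$channel, "_imf", k, "_", sn)
      vals <- c(vals, st)
      info[[length(info) + 1L]] <- data.frame(
        channel = seg$channel, imf = k, stat = sn,
        stringsAsFactors = FALSE)
    }
  }
  attr(vals, "subject_id") <- segments[[1]]$subject_id
  attr(vals, "label") <- segments[[1]]$label
  attr(vals, "info") <- do.call(rbind, info)
  vals
}

#' Assemble feature vectors into a feature table
#'
#' @param feature_list list of vectors from [extract_features()] (all with
#'   identical feature layout).
#' @return a `feature_table`: list with `features` (samples x features
#'   matrix), `info` (per-feature channel/IMF/statistic metadata), `label`
#'   (factor) and `subject_id`.
#' @export
feature_table <- function(feature_list) {
  stopifnot(length(feature_list) >= 1)
  nm <- names(feature_list[[1]])
  for (fv in feature_list)
    if (!identical(names(fv), nm))
      stop("all feature vectors must share the same feature layout")
  mat <- do.call(rbind, lapply(feature_list, as.numeric))
  colnames(mat) <- nm
  structure(
    list(features = mat,
         info = attr(feature_list[[1]], "info"),
         label = factor(vapply(feature_list, function(f) attr(f, "label"), "")),
         subject_id = vapply(feature_list, function(f) attr(f, "subject_id"), "")),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d sample(s) x %d feature(s); classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s (%d)", levels(x$label), table(x$label)),
                    collapse = ", ")))
  invisible(x)
}

#' Serialize a feature table to CSV
#'
#' Header `subject,label,<channel>_imf<k>_<stat>,...`, one row per sample.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject = table$subject_id,
                   label = as.character(table$label),
                   table$features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, -(1:2), drop = FALSE])
  parts <- strsplit(colnames(mat), "_")
  info <- data.frame(
    channel = vapply(parts, `[[`, "", 1),
    imf = as.integer(sub("^imf", "", vapply(parts, `[[`, "", 2))),
    stat = vapply(parts, function(p) paste(p[-(1:2)], collapse = "_"), ""),
    stringsAsFactors = FALSE
  )
  structure(list(features = mat, info = info,
                 label = factor(df$label), subject_id = df$subject),
            class = "feature_table")
}
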