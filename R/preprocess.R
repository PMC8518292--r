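new_lung_segment <- function(waveform, fs, channel, subject_id, label) {
  structure(
    list(waveform = waveform, fs = fs, channel = channel,
         subject_id = subject_id, label = label),
    class = "lung_segment"
  )
}

#' @export
print.lung_segment <- function(x, ...) {
  cat(sprintf("<lung_segment> %s %s (%s): %d samples @ %g Hz\n",
              x$subject_id, x$channel, x$label, length(x$waveform), x$fs))
  invisible(x)
}

# Short-time RMS envelope (moving window, centred); edges padded by the
# nearest interior value.
st_rms <- function(x, fs, window_s = 0.05) {
  w <- max(3L, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  e <- stats::filter(x^2, rep(1 / w, w), sides = 2)
  e <- as.numeric(e)
  half <- (w - 1L) %/% 2L
  e[seq_len(half)] <- e[half + 1L]
  e[(length(e) - half + 1L):length(e)] <- e[length(e) - half]
  sqrt(pmax(e, 0))
}

#' Locate the cough peak used for channel synchronisation
#'
#' Recordings open with a deliberate cough; its broadband burst is the
#' loudest event early in the recording and synchronises the channels. The
#' peak is found on a smoothed short-time RMS envelope of the cross-channel
#' mean energy within a search window at the start of the recording, so one
#' index serves every channel.
#'
#' @param recording a `lung_recording`.
#' @param search_s search window from the start, in seconds.
#' @param window_s RMS smoothing window, in seconds.
#' @return the 1-based sample index of the envelope maximum.
#' @export
detect_cough_peak <- function(recording, search_s = 5, window_s = 0.05) {
  stopifnot(inherits(recording, "lung_recording"))
  fs <- recording$fs
  pow <- Reduce(`+`, lapply(recording$waveform, function(x) x^2)) /
    length(recording$waveform)
  if (all(pow == 0)) stop("silent recording: no cough detectable")
  env <- st_rms(sqrt(pow), fs, window_s)
  lim <- min(length(env), round(search_s * fs))
  coarse <- which.max(env[seq_len(lim)])
  # refine to the raw-energy maximum inside the envelope window, so the
  # returned index is the actual loudest sample rather than a plateau edge
  half <- round(window_s * fs / 2)
  lo <- max(1L, coarse - half)
  hi <- min(lim, coarse + half)
  lo - 1L + which.max(pow[lo:hi])
}

#' Choose the segmentation start after the cough
#'
#' Operationalises "first inhalation after the cough" as the first rise of
#' the smoothed energy envelope following its post-cough minimum: after the
#' cough peak the envelope decays through the burst tail, reaches a minimum
#' in the pause before the next breath, and rises again as inhalation
#' begins. That rise point is returned.
#'
#' @inheritParams detect_cough_peak
#' @param settle_s window after the cough peak, in seconds, in which the
#'   post-cough minimum is sought.
#' @return 1-based sample index at which segmentation should start.
#' @export
segmentation_start <- function(recording, search_s = 5, window_s = 0.05,
                               settle_s = 2) {
  fs <- recording$fs
  peak <- detect_cough_peak(recording, search_s, window_s)
  pow <- Reduce(`+`, lapply(recording$waveform, function(x) x^2)) /
    length(recording$waveform)
  env <- st_rms(sqrt(pow), fs, window_s)
  from <- peak + round(0.15 * fs)           # skip the burst itself
  to <- min(length(env), peak + round(settle_s * fs))
  if (from >= to) return(peak)
  trough <- from - 1L + which.min(env[from:to])
  # first sustained rise after the trough (envelope above trough + 10% of
  # the local dynamic range)
  thr <- env[trough] + 0.1 * (max(env[trough:to]) - env[trough])
  rise <- which(env[trough:to] > thr)
  if (length(rise) == 0) return(trough)
  trough + rise[1] - 1L
}

#' Cut a recording into fixed-length per-channel segments
#'
#' All channels are cut at the same start index (segmentation is
#' channel-synchronous; the cough provides the common reference). The
#' default length of 15 s gives 60 000 samples at 4000 Hz, enough to span
#' two to three respiratory cycles.
#'
#' @param recording a `lung_recording`.
#' @param start 1-based sample index of the first sample to keep.
#' @param duration_s segment length in seconds.
#' @return list of `lung_segment`, one per channel, each of exactly
#'   `round(fs * duration_s)` samples.
#' @export
segment_recording <- function(recording, start, duration_s = 15) {
  stopifnot(inherits(recording, "lung_recording"), start >= 1)
  fs <- recording$fs
  n <- round(fs * duration_s)
  len <- length(recording$waveform[[1]])
  if (start + n - 1 > len)
    stop(sprintf("segment of %d samples starting at %d exceeds recording length %d",
                 n, start, len))
  lapply(recording$channels, function(ch) {
    new_lung_segment(recording$waveform[[ch]][start:(start + n - 1L)],
                     fs, ch, recording$subject_id, recording$label)
  })
}

highpass_vec <- function(x, fs, cutoff_hz, order, zero_phase) {
  if (cutoff_hz >= fs / 2)
    stop("high-pass cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "high")
  if (zero_phase) signal::filtfilt(bf, x)
  else as.numeric(signal::filter(bf, x))
}

#' Butterworth high-pass filter for DC-offset removal
#'
#' A 7.5 Hz first-order Butterworth high-pass strips the DC offset and
#' sub-acoustic drift while leaving the lung-sound band essentially
#' untouched. Applied forward-backward (zero phase) by default to avoid
#' onset phase distortion on short segments; a causal forward-only pass is
#' available.
#'
#' @param x a `lung_segment` or numeric vector.
#' @param fs sampling rate in Hz (ignored when `x` is a segment).
#' @param cutoff_hz cutoff frequency in Hz.
#' @param order filter order.
#' @param zero_phase apply forward-backward (`TRUE`, default) or a single
#'   causal pass (`FALSE`).
#' @return an object of the same type as `x`, same length.
#' @export
highpass <- function(x, fs = NULL, cutoff_hz = 7.5, order = 1,
                     zero_phase = TRUE) {
  if (inherits(x, "lung_segment")) {
    x$waveform <- highpass_vec(x$waveform, x$fs, cutoff_hz, order, zero_phase)
    x
  } else {
    stopifnot(!is.null(fs))
    highpass_vec(x, fs, cutoff_hz, order, zero_phase)
  }
}

#' Additive Gaussian noise augmentation
#'
#' Minority-class segments are replicated as noisy copies:
#' `output = input + noise_factor * n` with `n` i.i.d. standard normal.
#'
#' @param x a `lung_segment` or numeric vector.
#' @param noise_factor standard deviation of the added noise.
#' @param seed integer seed, for reproducible copies.
#' @return an object of the same type as `x`.
#' @export
augment_noise <- function(x, noise_factor = 0.06, seed = NULL) {
  stopifnot(noise_factor >= 0)
  wav <- if (inherits(x, "lung_segment")) x$waveform else x
  noisy <- if (noise_factor == 0) {
    wav
  } else if (is.null(seed)) {
    wav + noise_factor * stats::rnorm(length(wav))
  } else {
    with_seed(seed, wav + noise_factor * stats::rnorm(length(wav)))
  }
  if (inherits(x, "lung_segment")) {
    x$waveform <- noisy
    x
  } else {
    noisy
  }
}

#' Group GOLD COPD grades into clinical severity classes
#'
#' COPD0 and COPD1 are mild, COPD2 and COPD3 are moderate, COPD4 is severe
#' -- the three-way grouping used in clinical practice.
#'
#' @param label character vector of grades `COPD0`..`COPD4`.
#' @return character vector of `"mild"`, `"moderate"`, `"severe"`.
#' @examples
#' group_labels(c("COPD0", "COPD3", "COPD4"))
#' @export
group_labels <- function(label) {
  map <- c(COPD0 = "mild", COPD1 = "mild",
           COPD2 = "moderate", COPD3 = "moderate",
           COPD4 = "severe")
  bad <- setdiff(unique(label), names(map))
  if (length(bad))
    stop("unknown COPD grade(s): ", paste(bad, collapse = ", "))
  unname(map[label])
}

#' Segment, filter and label a recording in one call
#'
#' Convenience wrapper: locate the post-cough start, cut all channels to
#' `duration_s`, and high-pass filter each segment.
#'
#' @inheritParams segment_recording
#' @inheritParams highpass
#' @param start optional fixed start index; when `NULL`, found with
#'   [segmentation_start()].
#' @return list of filtered `lung_segment`.
#' @export
preprocess_recording <- function(recording, duration_s = 15, start = NULL,
                                 cutoff_hz = 7.5, order = 1,
                                 zero_phase = TRUE) {
  if (is.null(start)) start <- segmentation_start(recording)
  segs <- segment_recording(recording, start, duration_s)
  lapply(segs, highpass, cutoff_hz = cutoff_hz, order = order,
         zero_phase = zero_phase)
}
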