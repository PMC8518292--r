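#' Canonical auscultation channel labels
#'
#' Twelve posterior auscultation sites: six on the left lung (L1-L6) and six
#' on the right (R1-R6), the layout used by multi-channel digital
#' stethoscope databases.
#'
#' @return character vector of the 12 channel labels.
#' @export
channel_labels <- function() {
  c(paste0("L", 1:6), paste0("R", 1:6))
}

# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

new_lung_recording <- function(subject_id, channels, waveform, fs, label) {
  stopifnot(length(channels) == length(waveform),
            !anyDuplicated(channels), fs > 0)
  lens <- lengths(waveform)
  if (length(unique(lens)) > 1) stop("all channels must have the same length")
  structure(
    list(subject_id = subject_id, channels = channels,
         waveform = waveform, fs = fs, label = label),
    class = "lung_recording"
  )
}

#' @export
print.lung_recording <- function(x, ...) {
  n <- length(x$waveform[[1]])
  cat(sprintf("<lung_recording> subject %s, label %s\n", x$subject_id, x$label))
  cat(sprintf("  %d channel(s) [%s], %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), paste(x$channels, collapse = ","),
              n, x$fs, n / x$fs))
  invisible(x)
}

#' Define an adventitious-sound class for the synthetic generator
#'
#' A severity class is characterised by zero or more sustained tonal
#' components above 400 Hz (the band where continuous adventitious lung
#' sounds of COPD patients concentrate), localised to a subset of channels.
#'
#' @param freqs centre frequencies in Hz of the sustained components
#'   (each must exceed 400 Hz); may be empty for a class with no
#'   adventitious component.
#' @param amps peak amplitudes, one per frequency.
#' @param channels channel labels carrying the components.
#' @return a list describing the class.
#' @export
synthetic_class <- function(freqs = numeric(0), amps = numeric(0),
                            channels = character(0)) {
  stopifnot(length(freqs) == length(amps))
  if (length(freqs) && any(freqs <= 400))
    stop("adventitious component frequencies must exceed 400 Hz")
  if (length(freqs) && length(channels) == 0)
    stop("a class with adventitious components must name affected channels")
  list(freqs = freqs, amps = amps, channels = channels)
}

#' Specification for the synthetic lung-sound generator
#'
#' Bundles the acquisition parameters (channel count, sampling rate,
#' duration), the acoustic scene (cough burst for channel synchronisation,
#' quasi-periodic breath noise, white noise floor) and the per-class
#' adventitious components. Defaults mirror the clinical acquisition
#' protocol the pipeline targets: 12 channels at 4000 Hz, recordings of at
#' least 17 s opened by a cough, severity grouped as mild / moderate /
#' severe with continuous components above 400 Hz on the affected sites.
#'
#' @param n_channels number of channels, 1-12 (taken from L1..L6, R1..R6 in
#'   order).
#' @param fs sampling rate in Hz.
#' @param duration recording length in seconds, at least 17.
#' @param classes named list of [synthetic_class()] definitions.
#' @param cough_time centre of the cough burst, seconds from start.
#' @param breath_rate breathing rate in cycles per minute.
#' @param breath_amplitude RMS-scale amplitude of the breath-cycle noise.
#' @param noise_floor amplitude of the additive white noise floor.
#' @return a `synthetic_spec` list.
#' @examples
#' spec <- synthetic_spec(fs = 2000, duration = 17)
#' rec <- generate_recording(spec, "severe", seed = 1)
#' rec
#' @export
synthetic_spec <- function(n_channels = 12L,
                           fs = 4000,
                           duration = 20,
                           classes = default_classes(),
                           cough_time = 1.0,
                           breath_rate = 16,
                           breath_amplitude = 0.2,
                           noise_floor = 0.01) {
  stopifnot(n_channels >= 1, n_channels <= 12, fs > 0)
  if (duration < 17)
    stop("recordings must be at least 17 s long")
  if (cough_time <= 0.3 || cough_time > duration - 1)
    stop("cough_time must lie inside the recording (after 0.3 s)")
  all_freqs <- unlist(lapply(classes, `[[`, "freqs"))
  if (length(all_freqs) && max(all_freqs) >= fs / 2)
    stop("component frequencies must be below the Nyquist frequency fs/2")
  chans <- channel_labels()[seq_len(n_channels)]
  for (cl in names(classes)) {
    bad <- setdiff(classes[[cl]]$channels, chans)
    if (length(bad))
      stop("class '", cl, "' names channels outside the spec: ",
           paste(bad, collapse = ","))
  }
  structure(
    list(n_channels = as.integer(n_channels), fs = fs, duration = duration,
         classes = classes, cough_time = cough_time,
         breath_rate = breath_rate, breath_amplitude = breath_amplitude,
         noise_floor = noise_floor),
    class = "synthetic_spec"
  )
}

#' Default severity classes for the synthetic generator
#'
#' Mild disease carries no sustained adventitious component; moderate and
#' severe carry one continuous component above 400 Hz on the four
#' left-posterior sites L1-L4, with amplitude increasing with severity.
#'
#' @param channels affected channels for the diseased classes.
#' @return named list of three [synthetic_class()] definitions.
#' @export
default_classes <- function(channels = c("L1", "L2", "L3", "L4")) {
  list(
    mild     = synthetic_class(),
    moderate = synthetic_class(freqs = 550, amps = 0.15, channels = channels),
    severe   = synthetic_class(freqs = 750, amps = 0.25, channels = channels)
  )
}

# Band-limited breath-cycle noise: white noise band-passed to the lung-sound
# band, amplitude-modulated at the breathing rate.
breath_noise <- function(n, fs, rate_cpm, amplitude, phase) {
  lo <- 100
  hi <- min(1000, 0.45 * fs)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x <- x / stats::sd(x)
  t <- (seq_len(n) - 1) / fs
  env <- 0.35 + 0.65 * sin(pi * rate_cpm / 60 * t + phase)^2
  amplitude * env * x
}

#' Generate one synthetic multi-channel lung-sound recording
#'
#' The recording contains (a) a broadband cough burst shared across all
#' channels (the synchronisation event real acquisitions open with),
#' (b) quasi-periodic band-limited breath noise on every channel, (c) the
#' class's sustained adventitious components added only on its affected
#' channels, and (d) a white noise floor. Identical `(spec, class_label,
#' seed)` yield bit-identical waveforms.
#'
#' @param spec a [synthetic_spec()].
#' @param class_label one of `names(spec$classes)`.
#' @param seed integer seed.
#' @param subject_id subject identifier stored in the recording.
#' @return a `lung_recording`.
#' @export
generate_recording <- function(spec, class_label, seed,
                               subject_id = paste0(class_label, "_", seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!class_label %in% names(spec$classes))
    stop("unknown class label '", class_label, "'")
  cls <- spec$classes[[class_label]]
  fs <- spec$fs
  n <- round(fs * spec$duration)
  t <- (seq_len(n) - 1) / fs
  chans <- channel_labels()[seq_len(spec$n_channels)]

  with_seed(seed, {
    # one cough for all channels: it is the cross-channel sync event
    cough_len <- round(0.3 * fs)
    cough <- stats::rnorm(cough_len) *
      0.5 * (1 - cos(2 * pi * seq_len(cough_len) / (cough_len + 1))) # Hann
    cough <- 10 * spec$breath_amplitude * cough / max(abs(cough))
    c0 <- round(spec$cough_time * fs) - round(cough_len / 2)

    waveform <- list()
    for (ch in chans) {
      x <- breath_noise(n, fs, spec$breath_rate, spec$breath_amplitude,
                        phase = stats::runif(1, 0, pi))
      idx <- seq(c0 + 1, c0 + cough_len)
      x[idx] <- x[idx] + cough
      if (ch %in% cls$channels && length(cls$freqs)) {
        for (k in seq_along(cls$freqs)) {
          x <- x + cls$amps[k] * sin(2 * pi * cls$freqs[k] * t +
                                       stats::runif(1, 0, 2 * pi))
        }
      }
      x <- x + spec$noise_floor * stats::rnorm(n)
      waveform[[ch]] <- x
    }
    new_lung_recording(subject_id, chans, waveform, fs, class_label)
  })
}

#' Generate a balanced labelled synthetic dataset
#'
#' Per-recording seeds are derived deterministically from the master seed,
#' so a fixed master seed reproduces the whole dataset.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_class recordings per class.
#' @param seed master seed.
#' @param classes class labels to generate; defaults to all classes in the
#'   spec.
#' @return list of `lung_recording` objects.
#' @export
generate_dataset <- function(spec, n_per_class, seed,
                             classes = names(spec$classes)) {
  stopifnot(n_per_class >= 1)
  out <- list()
  i <- 0L
  for (cl in classes) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      rec_seed <- (as.integer(seed) + 97L * i) %% 2147483629L
      out[[i]] <- generate_recording(spec, cl, seed = rec_seed,
                                     subject_id = sprintf("%s_%02d", cl, j))
    }
  }
  out
}
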