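#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings used for auscultation
#' recordings: PCM 16-bit, PCM 24-bit, and IEEE float 32-bit, single channel.
#' Integer samples are rescaled to \[-1, 1).
#'
#' @param path path to a `.wav` file.
#' @return a list with `samples` (numeric vector) and `fs` (sampling rate, Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)

  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, size = 2, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, size = 2, endian = "little"),
        fs           = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (fmt$n_channels != 1L) stop("only mono WAV is supported, got ", fmt$n_channels, " channels")
      bytes <- fmt$bits / 8L
      n <- size %/% bytes
      if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", n, size = 4, endian = "little")
      } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
        samples <- readBin(con, "integer", n, size = 2, signed = TRUE, endian = "little") / 32768
      } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
        raw <- readBin(con, "raw", size)
        b <- matrix(as.integer(raw), nrow = 3)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        samples <- ifelse(v >= 8388608, v - 16777216, v) / 8388608
      } else {
        stop("unsupported WAV encoding: format ", fmt$audio_format, ", ", fmt$bits, " bits")
      }
      return(list(samples = samples, fs = fmt$fs))
    } else {
      readBin(con, "raw", size + size %% 2L) # skip unknown chunk (padded to even)
    }
  }
}

#' Write a mono WAV file
#'
#' @param samples numeric vector of amplitudes.
#' @param fs sampling rate in Hz.
#' @param path output path.
#' @param bits 16 for PCM (samples clipped to \[-1, 1\]) or 32 for IEEE float.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path, bits = 16L) {
  stopifnot(fs > 0, bits %in% c(16L, 32L))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes <- bits %/% 8L
  data_size <- n * bytes
  audio_format <- if (bits == 32L) 3L else 1L

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_format, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32L) {
    writeBin(as.numeric(samples), con, size = 4, endian = "little")
  } else {
    x <- pmin(pmax(samples, -1), 32767 / 32768)
    writeBin(as.integer(round(x * 32768)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Write a recording as per-channel WAV files plus a label manifest
#'
#' One mono file per channel, named `<subject>_<channel>.wav`, and a CSV
#' manifest `labels.csv` with columns `subject_id,label` (appended to if it
#' already exists), matching the layout used by public multi-channel
#' auscultation databases.
#'
#' @param recording a `lung_recording` (see [generate_recording()]).
#' @param dir output directory, created if needed.
#' @param bits sample encoding passed to [write_wav()].
#' @return the written WAV paths, invisibly.
#' @export
write_recording <- function(recording, dir, bits = 16L) {
  stopifnot(inherits(recording, "lung_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (ch in recording$channels) {
    p <- file.path(dir, paste0(recording$subject_id, "_", ch, ".wav"))
    write_wav(recording$waveform[[ch]], recording$fs, p, bits = bits)
    paths <- c(paths, p)
  }
  manifest <- file.path(dir, "labels.csv")
  row <- data.frame(subject_id = recording$subject_id, label = recording$label)
  if (file.exists(manifest)) {
    prev <- utils::read.csv(manifest, colClasses = "character")
    prev <- prev[prev$subject_id != recording$subject_id, , drop = FALSE]
    row <- rbind(prev, row)
  }
  utils::write.csv(row, manifest, row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a recording from per-channel WAV files and the label manifest
#'
#' @param dir directory holding `<subject>_<channel>.wav` files and `labels.csv`.
#' @param subject_id subject to load.
#' @param channels channel labels to read; defaults to whatever files exist,
#'   in canonical L1..L6, R1..R6 order.
#' @return a `lung_recording`.
#' @export
read_recording <- function(dir, subject_id, channels = NULL) {
  if (is.null(channels)) {
    files <- list.files(dir, pattern = paste0("^", subject_id, "_(L|R)[1-6]\\.wav$"))
    channels <- sub("\\.wav$", "", sub(paste0("^", subject_id, "_"), "", files))
    channels <- intersect(channel_labels(), channels)
  }
  if (length(channels) == 0) stop("no channel WAV files for subject ", subject_id, " in ", dir)
  waveform <- list()
  fs <- NULL
  for (ch in channels) {
    w <- read_wav(file.path(dir, paste0(subject_id, "_", ch, ".wav")))
    if (is.null(fs)) fs <- w$fs
    if (w$fs != fs) stop("channels of one subject must share a sampling rate")
    waveform[[ch]] <- w$samples
  }
  manifest <- file.path(dir, "labels.csv")
  label <- NA_character_
  if (file.exists(manifest)) {
    lab <- utils::read.csv(manifest, colClasses = "character")
    hit <- lab$label[lab$subject_id == subject_id]
    if (length(hit)) label <- hit[[1]]
  }
  new_lung_recording(subject_id, channels, waveform, fs, label)
}
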