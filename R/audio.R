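#' Labeled mono waveform with cohort provenance
#'
#' The basic audio container used throughout the pipeline: a mono waveform
#' in `[-1, 1]` tagged with the subject, session and speech task that
#' produced it.
#'
#' @param samples numeric vector of samples in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param subject_id,session_id,task provenance identifiers.
#' @param is_calibration_silence logical; `TRUE` for the per-session
#'   calibration-silence recording used by spectral subtraction.
#' @param parent_id optional identifier shared by fragments cut from a
#'   common over-long parent file (their x-vectors are averaged back
#'   together).
#' @return An object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate, subject_id = NA_character_,
                          session_id = NA_character_, task = NA_character_,
                          is_calibration_silence = FALSE, parent_id = NULL) {
  if (length(samples) < 1L) stop_pdvoice("audio_segment needs >= 1 sample")
  if (sample_rate <= 0) stop_pdvoice("sample_rate must be positive")
  structure(list(
    samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
    subject_id = subject_id, session_id = session_id, task = task,
    is_calibration_silence = isTRUE(is_calibration_silence),
    parent_id = parent_id
  ), class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment %s/%s/%s: %.3f s @ %g Hz%s>\n",
              x$subject_id, x$session_id, x$task,
              segment_duration(x), x$sample_rate,
              if (x$is_calibration_silence) " [calibration]" else ""))
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param segment an [audio_segment()].
#' @export
segment_duration <- function(segment) {
  length(segment$samples) / segment$sample_rate
}

#' Write a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer (16-bit PCM, one channel).  Samples are clipped
#' to `[-1, 1]` before quantization.
#'
#' @param segment an [audio_segment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path) {
  x <- pmax(-1, pmin(1, segment$samples))
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  sr <- as.integer(segment$sample_rate)
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(sr * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV file
#'
#' Counterpart to [write_wav()]; supports the plain PCM subset it writes.
#'
#' @param path WAV file path.
#' @inheritParams audio_segment
#' @return An [audio_segment()] with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path, subject_id = NA_character_,
                     session_id = NA_character_, task = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop_pdvoice("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop_pdvoice("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop_pdvoice("no data chunk in ", path)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        stop_pdvoice("only mono 16-bit PCM WAV is supported")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = size %/% 2, size = 2,
                     endian = "little", signed = TRUE)
      return(audio_segment(pcm / 32767, sample_rate,
                           subject_id = subject_id, session_id = session_id,
                           task = task))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}

## Resample an audio segment with the signal package's polyphase resampler,
## reducing a rational rate change to small integer factors.
resample_segment <- function(segment, new_rate) {
  if (new_rate == segment$sample_rate) return(segment)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  p <- as.integer(new_rate); q <- as.integer(segment$sample_rate)
  d <- g(p, q); p <- p %/% d; q <- q %/% d
  y <- signal::resample(segment$samples, p, q)
  out <- segment
  out$samples <- as.numeric(y)
  out$sample_rate <- new_rate
  out
}
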