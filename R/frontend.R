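#' MFCC extraction configuration
#'
#' Frame/filterbank settings for Mel-frequency cepstral coefficient
#' extraction.  Defaults follow the baseline branch (20 ms windows, 10 ms
#' step, 23 Mel filters, 19 cepstra plus log-energy, deltas appended); the
#' x-vector branch uses 25 ms windows, no deltas, and 23 or 30 cepstra
#' depending on channel (see [mfcc_preset()]).
#'
#' @param sample_rate waveform sampling rate in Hz.
#' @param window_ms,step_ms analysis frame length and hop in ms.
#' @param n_filters number of Mel-spaced triangular filters.
#' @param fmin_hz,fmax_hz filterbank frequency range.
#' @param n_ceps number of cepstral coefficients kept (DCT-II coefficients
#'   1..n_ceps; coefficient 0 is excluded, log-energy is used instead).
#' @param include_log_energy prepend frame log-energy (computed on the raw
#'   frame, 16-bit-integer sample scale, natural log).
#' @param add_deltas append delta and delta-delta coefficients.
#' @param preemphasis pre-emphasis coefficient.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(sample_rate, window_ms = 20, step_ms = 10,
                        n_filters = 23, fmin_hz = 20, fmax_hz = 7000,
                        n_ceps = 19, include_log_energy = TRUE,
                        add_deltas = TRUE, preemphasis = 0.97) {
  stopifnot(fmin_hz >= 0, fmin_hz < fmax_hz, fmax_hz <= sample_rate / 2,
            n_ceps <= n_filters, step_ms <= window_ms)
  structure(list(sample_rate = sample_rate, window_ms = window_ms,
                 step_ms = step_ms, n_filters = n_filters,
                 fmin_hz = fmin_hz, fmax_hz = fmax_hz, n_ceps = n_ceps,
                 include_log_energy = include_log_energy,
                 add_deltas = add_deltas, preemphasis = preemphasis),
            class = "mfcc_config")
}

#' Standard MFCC presets for the two branches and channels
#'
#' @param branch `"gmm"` (baseline: 20 ms windows, 19 cepstra + log-energy
#'   + deltas) or `"xvector"` (25 ms windows, no deltas; 23 cepstra with a
#'   20--3700 Hz filterbank for telephone, 30 cepstra with 20--7600 Hz for
#'   high quality).
#' @param channel `"high_quality"` or `"telephone"`.
#' @param sample_rate waveform rate; defaults to 16000 (high quality) or
#'   8000 (telephone).
#' @return An [mfcc_config()].
#' @export
mfcc_preset <- function(branch = c("gmm", "xvector"),
                        channel = c("high_quality", "telephone"),
                        sample_rate = NULL) {
  branch <- match.arg(branch)
  channel <- match.arg(channel)
  if (is.null(sample_rate))
    sample_rate <- if (channel == "telephone") 8000 else 16000
  if (branch == "gmm") {
    if (channel == "high_quality") {
      mfcc_config(sample_rate, window_ms = 20, n_filters = 23,
                  fmin_hz = 20, fmax_hz = min(7000, sample_rate / 2),
                  n_ceps = 19, add_deltas = TRUE)
    } else {
      mfcc_config(sample_rate, window_ms = 20, n_filters = 23,
                  fmin_hz = 300, fmax_hz = 3700, n_ceps = 19,
                  add_deltas = TRUE)
    }
  } else {
    if (channel == "high_quality") {
      mfcc_config(sample_rate, window_ms = 25, n_filters = 30,
                  fmin_hz = 20, fmax_hz = min(7600, sample_rate / 2),
                  n_ceps = 30, add_deltas = FALSE)
    } else {
      mfcc_config(sample_rate, window_ms = 25, n_filters = 23,
                  fmin_hz = 20, fmax_hz = 3700, n_ceps = 23,
                  add_deltas = FALSE)
    }
  }
}

feature_dim <- function(config) {
  base <- config$n_ceps + as.integer(config$include_log_energy)
  base * (if (config$add_deltas) 3L else 1L)
}

new_feature_matrix <- function(values, frame_times, config,
                               provenance = list()) {
  structure(list(values = values, frame_times = frame_times,
                 config = config, provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d frames x %d dims>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

## HTK Mel scale.
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

## Triangular Mel filterbank as an (nfft/2 + 1) x n_filters matrix.
mel_filterbank <- function(config, nfft) {
  n_bins <- nfft %/% 2 + 1
  freqs <- (seq_len(n_bins) - 1) * config$sample_rate / nfft
  edges <- mel_to_hz(seq(hz_to_mel(config$fmin_hz), hz_to_mel(config$fmax_hz),
                         length.out = config$n_filters + 2))
  fb <- matrix(0, n_bins, config$n_filters)
  for (j in seq_len(config$n_filters)) {
    lo <- edges[j]; mid <- edges[j + 1]; hi <- edges[j + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[, j] <- pmax(0, pmin(up, down))
  }
  fb
}

## Orthonormal DCT-II matrix rows k (0-based) applied to n_filters inputs.
dct_matrix <- function(n_filters, rows) {
  m <- outer(rows, seq_len(n_filters) - 0.5,
             function(k, n) cos(pi * k * n / n_filters))
  scale <- ifelse(rows == 0, sqrt(1 / n_filters), sqrt(2 / n_filters))
  m * scale
}

frame_signal <- function(x, win, step) {
  n_frames <- floor((length(x) - win) / step) + 1L
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * step, `+`)
  matrix(x[idx], nrow = win)
}

#' Compute MFCC features for an audio segment
#'
#' Per frame: raw-frame log-energy (optional), per-frame pre-emphasis,
#' Hamming window, power spectrum, Mel triangular filterbank, log, and an
#' orthonormal DCT-II keeping coefficients `1..n_ceps`.  Delta and
#' delta-delta coefficients (regression over +/-2 frames) are appended
#' when `config$add_deltas` is set.
#'
#' @param segment an [audio_segment()].
#' @param config an [mfcc_config()] with matching sample rate.
#' @return A `feature_matrix` whose columns are
#'   `[log-energy, c1..c_nceps, (deltas, delta-deltas)]`.
#' @export
compute_mfcc <- function(segment, config) {
  stopifnot(inherits(segment, "audio_segment"),
            inherits(config, "mfcc_config"))
  if (segment$sample_rate != config$sample_rate)
    stop_pdvoice("segment rate ", segment$sample_rate,
                 " != config rate ", config$sample_rate)
  fs <- config$sample_rate
  win <- round(config$window_ms / 1000 * fs)
  step <- round(config$step_ms / 1000 * fs)
  if (length(segment$samples) < win)
    stop_pdvoice("segment shorter than one analysis window")
  frames <- frame_signal(segment$samples, win, step)
  n_frames <- ncol(frames)
  ## raw-frame log-energy on the 16-bit integer sample scale
  log_e <- log(pmax(colSums((frames * 32767)^2), .Machine$double.eps))
  ## per-frame pre-emphasis then Hamming window
  pre <- frames - config$preemphasis * rbind(frames[1, ], frames[-win, ])
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  pre <- pre * w
  nfft <- 2^ceiling(log2(win))
  padded <- rbind(pre, matrix(0, nfft - win, n_frames))
  spec <- stats::mvfft(padded)
  power <- Mod(spec[seq_len(nfft %/% 2 + 1), , drop = FALSE])^2
  fb <- mel_filterbank(config, nfft)
  fbank <- log(pmax(crossprod(fb, power), .Machine$double.eps))
  dct <- dct_matrix(config$n_filters, seq_len(config$n_ceps))
  ceps <- t(dct %*% fbank)
  values <- if (config$include_log_energy) cbind(log_e, ceps) else ceps
  colnames(values) <- NULL
  if (config$add_deltas) values <- append_deltas(values)
  frame_times <- ((seq_len(n_frames) - 1L) * step + win / 2) / fs
  new_feature_matrix(values, frame_times, config,
                     provenance = list(subject_id = segment$subject_id,
                                       session_id = segment$session_id,
                                       task = segment$task,
                                       parent_id = segment$parent_id))
}

## Delta regression over +/- 2 frames with replicated edges; returns
## cbind(static, delta, delta-delta).
append_deltas <- function(values) {
  delta_of <- function(m) {
    n <- nrow(m)
    pad <- function(i) m[pmax(1L, pmin(n, i)), , drop = FALSE]
    num <- (pad(seq_len(n) + 1L) - pad(seq_len(n) - 1L)) +
      2 * (pad(seq_len(n) + 2L) - pad(seq_len(n) - 2L))
    num / 10
  }
  d1 <- delta_of(values)
  cbind(values, d1, delta_of(d1))
}

#' Energy-based voice activity detection
#'
#' A frame is kept iff its log-energy exceeds
#' `abs_floor + mean_scale * mean(log-energy)` over the file.
#'
#' @param features a `feature_matrix` whose first column is log-energy.
#' @param abs_floor absolute threshold term (natural-log energy units on
#'   the 16-bit sample scale).
#' @param mean_scale multiplier of the file-mean log-energy.
#' @return Logical vector, one entry per frame (`TRUE` = keep).
#' @export
energy_vad <- function(features, abs_floor = 5, mean_scale = 0.5) {
  stopifnot(inherits(features, "feature_matrix"))
  if (!features$config$include_log_energy)
    stop_pdvoice("energy_vad needs features with log-energy")
  log_e <- features$values[, 1]
  log_e > abs_floor + mean_scale * mean(log_e)
}

#' Sliding-window cepstral mean subtraction
#'
#' Subtracts from each cepstral coefficient its mean over a centered
#' sliding window (default 300 ms), canceling linear convolutional channel
#' effects.  The window shrinks at file edges.  Applied to the static
#' cepstral coefficients only -- not to log-energy, and before delta
#' computation.
#'
#' @param features a `feature_matrix` without deltas.
#' @param window_ms sliding window length in ms.
#' @return The `feature_matrix` with mean-subtracted cepstra.
#' @export
apply_cms <- function(features, window_ms = 300) {
  stopifnot(inherits(features, "feature_matrix"))
  if (features$config$add_deltas)
    stop_pdvoice("apply_cms must run before deltas are appended")
  half <- floor(window_ms / features$config$step_ms / 2)
  v <- features$values
  cols <- if (features$config$include_log_energy) {
    seq(2L, ncol(v))
  } else {
    seq_len(ncol(v))
  }
  n <- nrow(v)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  cs <- rbind(0, apply(v[, cols, drop = FALSE], 2, cumsum))
  means <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1)
  v[, cols] <- v[, cols, drop = FALSE] - means
  features$values <- v
  features
}

#' Split audio into duration-bounded pieces
#'
#' In `"matched"` mode the input is tiled without overlap into pieces of
#' at most `max_s` seconds; a final remainder shorter than `min_s` is
#' merged into the previous piece when the merged piece stays within
#' `max_s`, kept on its own when it is at least 25 ms, and dropped
#' otherwise.  In `"mismatched"` mode any duration in `[0.025, 100]` s is
#' returned unsplit; longer inputs are cut into equal fragments shorter
#' than 100 s that share a `parent_id` so their x-vectors can be averaged.
#' Inputs shorter than 25 ms yield an empty list in both modes.
#'
#' @param segment an [audio_segment()].
#' @param min_s,max_s matched-mode duration bounds in seconds.
#' @param mode `"matched"` or `"mismatched"`.
#' @return A list of [audio_segment()] pieces tiling the input.
#' @export
split_segments <- function(segment, min_s = 1, max_s = 5,
                           mode = c("matched", "mismatched")) {
  mode <- match.arg(mode)
  fs <- segment$sample_rate
  n <- length(segment$samples)
  dur <- n / fs
  min_frag <- 0.025
  if (dur < min_frag) return(list())
  piece <- function(from, to, parent = NULL) {
    out <- segment
    out$samples <- segment$samples[from:to]
    out$parent_id <- parent
    out
  }
  if (mode == "mismatched") {
    if (dur <= 100) return(list(segment))
    k <- floor(dur / 100) + 1L
    parent <- paste(segment$subject_id, segment$session_id, segment$task,
                    sep = "/")
    bounds <- round(seq(0, n, length.out = k + 1L))
    return(lapply(seq_len(k), function(i) {
      piece(bounds[i] + 1L, bounds[i + 1L], parent)
    }))
  }
  max_n <- round(max_s * fs)
  min_n <- round(min_s * fs)
  starts <- seq(1L, n, by = max_n)
  ends <- pmin(starts + max_n - 1L, n)
  lens <- ends - starts + 1L
  k <- length(starts)
  if (k > 1L && lens[k] < min_n) {
    if (lens[k - 1L] + lens[k] <= max_n) {
      ends[k - 1L] <- ends[k]
      starts <- starts[-k]; ends <- ends[-k]; lens <- lens[-k]
      k <- k - 1L
    } else if (lens[k] < min_frag * fs) {
      starts <- starts[-k]; ends <- ends[-k]
      k <- k - 1L
    }
  }
  lapply(seq_len(k), function(i) piece(starts[i], ends[i]))
}

#' Spectral subtraction against a calibration-silence noise estimate
#'
#' Boll-style short-time magnitude-domain subtraction: the mean noise
#' magnitude spectrum is estimated from the calibration silence, scaled by
#' `oversubtraction` and subtracted from each frame's magnitude spectrum,
#' flooring the result at `floor` times the input magnitude; phase is
#' preserved and frames are overlap-added back to the input length.
#'
#' @param segment noisy [audio_segment()].
#' @param calibration calibration-silence [audio_segment()] at the same
#'   sample rate, at least one analysis frame long.
#' @param oversubtraction scale on the subtracted noise magnitude.
#' @param floor spectral floor as a fraction of the input magnitude
#'   (`floor = 1`, `oversubtraction = 0` is the identity).
#' @param frame_ms,overlap analysis frame length (ms) and fractional
#'   overlap.
#' @return The denoised [audio_segment()], same length as the input.
#' @export
spectral_subtract <- function(segment, calibration, oversubtraction = 1.5,
                              floor = 0.02, frame_ms = 32, overlap = 0.5) {
  if (segment$sample_rate != calibration$sample_rate)
    stop_pdvoice("segment and calibration sample rates differ")
  fs <- segment$sample_rate
  win <- 2^round(log2(frame_ms / 1000 * fs))
  hop <- round(win * (1 - overlap))
  if (length(calibration$samples) < win)
    stop_pdvoice("calibration shorter than one analysis frame")
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / win)  # periodic Hann
  stft_mag <- function(x) {
    fr <- frame_signal(x, win, hop) * w
    stats::mvfft(fr)
  }
  noise_mag <- rowMeans(Mod(stft_mag(calibration$samples)))
  n <- length(segment$samples)
  ## pad a full window on both sides so every original sample has complete
  ## overlap-add coverage (edge frames otherwise divide by a vanishing
  ## window sum and explode)
  x <- c(numeric(win), segment$samples, numeric(win))
  spec <- stft_mag(x)
  mag <- Mod(spec)
  new_mag <- pmax(mag - oversubtraction * noise_mag, floor * mag)
  ratio <- ifelse(mag > 0, new_mag / mag, 0)
  rec <- Re(stats::mvfft(spec * ratio, inverse = TRUE)) / win
  out <- numeric(length(x))
  wsum <- numeric(length(x))
  for (j in seq_len(ncol(rec))) {
    idx <- (j - 1L) * hop + seq_len(win)
    out[idx] <- out[idx] + rec[, j] * w
    wsum[idx] <- wsum[idx] + w^2
  }
  out <- ifelse(wsum > 1e-6, out / pmax(wsum, 1e-6), 0)
  res <- segment
  res$samples <- out[win + seq_len(n)]
  res
}

#' Full front-end feature extraction for one segment
#'
#' Convenience chain: optional spectral subtraction, static MFCC
#' extraction, VAD mask computation, sliding-window CMS, delta appending
#' (if configured), and removal of silent frames.  Downstream modules
#' consume only the kept frames.
#'
#' @param segment an [audio_segment()].
#' @param config an [mfcc_config()].
#' @param calibration optional calibration silence for
#'   [spectral_subtract()].
#' @param vad apply energy VAD frame removal.
#' @param cms apply cepstral mean subtraction.
#' @param vad_abs_floor,vad_mean_scale VAD thresholds.
#' @return A `feature_matrix` of kept frames.
#' @export
extract_features <- function(segment, config, calibration = NULL,
                             vad = TRUE, cms = TRUE, vad_abs_floor = 5,
                             vad_mean_scale = 0.5) {
  if (!is.null(calibration))
    segment <- spectral_subtract(segment, calibration)
  static_config <- config
  static_config$add_deltas <- FALSE
  feats <- compute_mfcc(segment, static_config)
  keep <- if (vad) {
    energy_vad(feats, abs_floor = vad_abs_floor,
               mean_scale = vad_mean_scale)
  } else rep(TRUE, nrow(feats$values))
  if (cms) feats <- apply_cms(feats)
  if (config$add_deltas) {
    feats$values <- append_deltas(feats$values)
    feats$config$add_deltas <- TRUE
  }
  feats$values <- feats$values[keep, , drop = FALSE]
  feats$frame_times <- feats$frame_times[keep]
  feats
}
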