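test_that("frame count and feature dimensions follow the configuration", {
  seg <- tone_segment(dur = 1.0)           # 16000 samples
  cfg <- mfcc_preset("gmm", "high_quality")
  f <- compute_mfcc(seg, cfg)
  expect_equal(nrow(f$values), 99)         # floor((16000-320)/160) + 1
  expect_equal(ncol(f$values), 60)         # (19 + 1) x 3 with deltas
  expect_equal(ncol(compute_mfcc(
    audio_segment(stats::rnorm(8000) * 0.01, 8000),
    mfcc_preset("xvector", "telephone"))$values), 24)
  expect_equal(ncol(compute_mfcc(
    audio_segment(stats::rnorm(16000) * 0.01, 16000),
    mfcc_preset("xvector", "high_quality"))$values), 31)
  expect_error(compute_mfcc(audio_segment(numeric(100) + 1e-4, 16000), cfg),
               "shorter")
})

test_that("MFCC extraction is deterministic and translation-covariant", {
  seg <- noise_segment(dur = 0.8, seed = 11)
  cfg <- mfcc_preset("gmm", "high_quality")
  f1 <- compute_mfcc(seg, cfg)
  expect_identical(f1$values, compute_mfcc(seg, cfg)$values)
  ## shifting the waveform by exactly one step shifts frames by one
  step <- round(cfg$step_ms / 1000 * cfg$sample_rate)
  shifted <- audio_segment(seg$samples[-seq_len(step)], seg$sample_rate)
  f2 <- compute_mfcc(shifted, cfg)
  n <- nrow(f2$values)
  ## compare away from both ends: delta-delta regressions replicate edge
  ## frames over a +/-4 halo, so those frames differ by design
  mid <- 5:(n - 4)
  expect_equal(f2$values[mid, ], f1$values[mid + 1, ], tolerance = 1e-10)
})

test_that("a pure tone drives the Mel filter nearest its frequency", {
  seg <- tone_segment(freq = 1000)
  cfg <- mfcc_config(16000, n_filters = 23, fmin_hz = 20, fmax_hz = 7000,
                     n_ceps = 19)
  win <- round(cfg$window_ms / 1000 * 16000)
  nfft <- 2^ceiling(log2(win))
  fb <- pdvoice:::mel_filterbank(cfg, nfft)
  x <- seg$samples[seq_len(win)] * (0.54 - 0.46 * cos(2 * pi *
                                                        (seq_len(win) - 1) /
                                                        (win - 1)))
  spec <- Mod(stats::fft(c(x, numeric(nfft - win)))[seq_len(nfft / 2 + 1)])^2
  fb_out <- as.numeric(crossprod(fb, spec))
  centers <- pdvoice:::mel_to_hz(seq(pdvoice:::hz_to_mel(20),
                                     pdvoice:::hz_to_mel(7000),
                                     length.out = 25))[2:24]
  expect_equal(which.max(fb_out), which.min(abs(centers - 1000)))
})

test_that("cepstra match a direct DCT-II matrix-product oracle", {
  seg <- noise_segment(dur = 0.2, seed = 3)
  cfg <- mfcc_config(16000, n_ceps = 19, n_filters = 23, fmax_hz = 7000,
                     include_log_energy = FALSE, add_deltas = FALSE)
  f <- compute_mfcc(seg, cfg)
  ## recompute one frame's cepstra with explicit cosine sums
  win <- 320; nfft <- 512
  x <- seg$samples[seq_len(win)]
  pre <- x - 0.97 * c(x[1], x[-win])
  pre <- pre * (0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1)))
  spec <- Mod(stats::fft(c(pre, numeric(nfft - win)))[1:(nfft / 2 + 1)])^2
  fbank <- log(pmax(as.numeric(
    crossprod(pdvoice:::mel_filterbank(cfg, nfft), spec)),
    .Machine$double.eps))
  oracle <- vapply(1:19, function(k) {
    sqrt(2 / 23) * sum(fbank * cos(pi * k * (seq_len(23) - 0.5) / 23))
  }, numeric(1))
  expect_equal(unname(f$values[1, ]), oracle, tolerance = 1e-10)
})

test_that("silence yields near-constant rows at the dither floor", {
  seg <- audio_segment(stats::rnorm(16000) * 1e-6, 16000)
  f <- compute_mfcc(seg, mfcc_preset("gmm", "high_quality"))
  log_e <- f$values[, 1]
  expect_lt(max(log_e), 3)          # far below any speech frame energy
  expect_lt(sd(log_e), 0.5)
})

test_that("energy VAD implements its threshold rule and recovers bursts", {
  seg <- noise_segment(dur = 0.5, seed = 7)
  cfg <- mfcc_config(16000, add_deltas = FALSE)
  f <- compute_mfcc(seg, cfg)
  ## degenerate thresholds
  expect_true(all(energy_vad(f, abs_floor = -Inf, mean_scale = 0)))
  ## identical energies with abs_floor > 0, mean_scale 1: all removed
  f2 <- f
  f2$values[, 1] <- 5
  expect_false(any(energy_vad(f2, abs_floor = 0.1, mean_scale = 1)))
  ## constructed speech/silence alternation recovered >= 95%
  fs <- 16000
  on_s <- 0.30; off_s <- 0.30
  pattern <- rep(c(rep(0.1, on_s * fs), rep(1e-5, off_s * fs)), 4)
  x <- pattern * withr::with_seed(13, stats::rnorm(length(pattern)))
  fa <- compute_mfcc(audio_segment(x, fs), cfg)
  keep <- energy_vad(fa)
  truth <- vapply(fa$frame_times, function(t) {
    (t %% (on_s + off_s)) < on_s
  }, logical(1))
  expect_gte(mean(keep == truth), 0.95)
  expect_length(keep, nrow(fa$values))
})

test_that("CMS subtracts the centered sliding mean exactly", {
  cfg <- mfcc_config(16000, add_deltas = FALSE)
  seg <- noise_segment(dur = 1, seed = 5)
  f <- compute_mfcc(seg, cfg)
  out <- apply_cms(f, window_ms = 300)
  ## independent naive oracle: per-frame centered mean, shrinking at edges
  half <- 15
  v <- f$values
  for (j in 2:ncol(v)) {
    for (t in seq_len(nrow(v))) {
      w <- max(1, t - half):min(nrow(v), t + half)
      expect_equal(out$values[t, j], v[t, j] - mean(v[w, j]),
                   tolerance = 1e-10)
    }
  }
  ## constant features -> all-zero cepstra
  fc <- f
  fc$values[] <- 2
  expect_true(all(abs(apply_cms(fc)$values[, -1]) < 1e-12))
  ## linear ramp -> interior output ~ 0
  fr <- f
  fr$values[, 2] <- seq_len(nrow(f$values))
  res <- apply_cms(fr)$values[(half + 1):(nrow(f$values) - half), 2]
  expect_lt(max(abs(res)), 1e-8)
  ## CMS never touches log-energy and refuses delta features
  expect_equal(out$values[, 1], v[, 1])
  fd <- compute_mfcc(seg, mfcc_preset("gmm", "high_quality"))
  expect_error(apply_cms(fd), "before deltas")
})

test_that("segment splitting tiles, bounds durations, and flags fragments", {
  fs <- 8000
  seg10 <- audio_segment(stats::rnorm(10 * fs) * 0.1, fs)
  pieces <- split_segments(seg10, 1, 5)
  durs <- vapply(pieces, segment_duration, numeric(1))
  expect_true(all(durs >= 1 & durs <= 5))
  expect_equal(sum(durs), 10)
  ## a 10 ms input disappears
  expect_length(split_segments(audio_segment(numeric(80) + 0.1, fs)), 0)
  ## 6 s splits into 5 + 1 (remainder >= min kept)
  d6 <- vapply(split_segments(audio_segment(numeric(6 * fs) + 0.1, fs)),
               segment_duration, numeric(1))
  expect_equal(d6, c(5, 1))
  ## sub-minimum remainder: kept on its own (>= 25 ms) when merging would
  ## overflow max_s
  seg55 <- audio_segment(numeric(5.5 * fs) + 0.1, fs)
  d55 <- vapply(split_segments(seg55, 1, 5), segment_duration, numeric(1))
  expect_equal(d55, c(5, 0.5))
  ## mismatched mode: 250 s fragments into >= 3 pieces < 100 s, one parent
  long <- audio_segment(numeric(250 * fs) + 0.1, fs, subject_id = "S1",
                        session_id = "a", task = "reading")
  frags <- split_segments(long, mode = "mismatched")
  expect_gte(length(frags), 3)
  expect_true(all(vapply(frags, segment_duration, numeric(1)) < 100))
  parents <- vapply(frags, function(p) p$parent_id, character(1))
  expect_length(unique(parents), 1)
  expect_equal(sum(vapply(frags, function(p) length(p$samples),
                          numeric(1))), length(long$samples))
})

test_that("spectral subtraction denoises and degrades to identity", {
  fs <- 16000
  calib <- noise_segment(dur = 5, fs = fs, amp = 0.02, seed = 100)
  noise <- noise_segment(dur = 2, fs = fs, amp = 0.02, seed = 200)
  ## matched stationary noise: mean power drops by >= 10 dB
  den <- spectral_subtract(noise, calib)
  drop_db <- 10 * log10(mean(noise$samples^2) / mean(den$samples^2))
  expect_gte(drop_db, 10)
  expect_length(den$samples, length(noise$samples))
  ## clean tone + that noise: narrow-band SNR strictly increases
  tone <- tone_segment(freq = 500, dur = 2, fs = fs, amp = 0.05)
  noisy <- audio_segment(tone$samples + noise$samples, fs)
  den2 <- spectral_subtract(noisy, calib)
  band_power <- function(x) {
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) / length(x) * fs
    in_band <- f > 480 & f < 520
    c(sig = sum(sp[in_band]), rest = sum(sp[f > 1000 & f < 7000]))
  }
  snr_before <- {p <- band_power(noisy$samples); p["sig"] / p["rest"]}
  snr_after <- {p <- band_power(den2$samples); p["sig"] / p["rest"]}
  expect_gt(snr_after, snr_before)
  ## identity limit: no subtraction, unit floor
  ident <- spectral_subtract(noisy, calib, oversubtraction = 0, floor = 1)
  expect_equal(ident$samples, noisy$samples, tolerance = 1e-6)
  ## mismatched rates are rejected
  expect_error(spectral_subtract(noisy, noise_segment(fs = 8000)), "rates")
})

test_that("extract_features chains the front end and keeps frames aligned", {
  co <- small_cohort()
  seg <- Filter(function(s) !s$is_calibration_silence, co$segments)[[1]]
  calib <- Filter(function(s) s$is_calibration_silence &&
                    s$subject_id == seg$subject_id, co$segments)[[1]]
  cfg <- mfcc_preset("gmm", "high_quality")
  f <- extract_features(seg, cfg, calibration = calib)
  expect_equal(ncol(f$values), 60)
  expect_equal(length(f$frame_times), nrow(f$values))
  ## VAD removed the silent portion
  f_novad <- extract_features(seg, cfg, calibration = calib, vad = FALSE)
  expect_lt(nrow(f$values), nrow(f_novad$values))
})
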