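#' Data augmentation policy
#'
#' Settings of the four-way corruption scheme used to triple the training
#' set: reverberation, additive noise (a new excerpt inserted every
#' second), background music, and babble (3--7 summed voices).  For each
#' input, all four corrupted copies are produced and `keep_copies` of
#' them are kept at random.
#'
#' @param snr_noise,snr_music,snr_babble SNR ranges in dB from which each
#'   copy's SNR is drawn.
#' @param noise_insertion_period_s seconds between noise-excerpt
#'   insertions.
#' @param babble_count_range inclusive range of summed babble voices
#'   (within 3--7).
#' @param keep_copies corrupted copies kept per input (<= 4).
#' @param seed integer seed.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(snr_noise = c(0, 15), snr_music = c(5, 15),
                           snr_babble = c(5, 15),
                           noise_insertion_period_s = 1,
                           babble_count_range = c(3, 7), keep_copies = 2,
                           seed = 1) {
  stopifnot(keep_copies <= 4, keep_copies >= 0,
            babble_count_range[1] >= 3, babble_count_range[2] <= 7,
            babble_count_range[1] <= babble_count_range[2])
  structure(list(snr_noise = snr_noise, snr_music = snr_music,
                 snr_babble = snr_babble,
                 noise_insertion_period_s = noise_insertion_period_s,
                 babble_count_range = babble_count_range,
                 keep_copies = as.integer(keep_copies),
                 seed = as.integer(seed)),
            class = "augment_policy")
}

#' Convolve a segment with a room impulse response
#'
#' Full convolution truncated to the input length and peak-normalized to
#' the input peak, simulating reverberation.
#'
#' @param segment an [audio_segment()].
#' @param rir numeric impulse response (at the segment's rate).
#' @param rir_rate optional RIR sampling rate; must match the segment's
#'   when given.
#' @return The reverberated [audio_segment()].
#' @export
reverberate <- function(segment, rir, rir_rate = NULL) {
  if (!is.null(rir_rate) && rir_rate != segment$sample_rate)
    stop_pdvoice("RIR sample rate does not match the segment")
  n <- length(segment$samples)
  y <- stats::convolve(segment$samples, rev(rir), type = "open")[seq_len(n)]
  peak_in <- max(abs(segment$samples))
  peak_out <- max(abs(y))
  if (peak_out > 0 && peak_in > 0) y <- y * (peak_in / peak_out)
  out <- segment
  out$samples <- y
  out
}

## Crop or tile `v` to exactly `n` samples, random start.
fit_length <- function(v, n) {
  if (length(v) >= n) {
    start <- sample.int(length(v) - n + 1L, 1)
    v[start + seq_len(n) - 1L]
  } else {
    rep_len(v[c(seq_along(v), rev(seq_along(v)))], n)  # ping-pong tile
  }
}

scale_to_snr <- function(signal, noise, snr_db) {
  ps <- mean(signal^2)
  pn <- mean(noise^2)
  if (pn == 0) return(noise)
  noise * sqrt(ps / (pn * 10^(snr_db / 10)))
}

#' Add noise, music, or babble to a segment
#'
#' `kind = "noise"` inserts a freshly drawn noise excerpt every
#' `noise_insertion_period_s` seconds; `"music"` adds one continuous
#' music excerpt; `"babble"` sums 3--7 randomly selected voices and adds
#' the mixture.  Each copy's SNR is drawn once from the policy's range
#' for that kind.  Output length equals input length; samples are
#' clipped to `[-1, 1]`.
#'
#' @param segment an [audio_segment()].
#' @param bank a [generate_noise_bank()] at the segment's sample rate.
#' @param kind `"noise"`, `"music"`, or `"babble"`.
#' @param policy an [augment_policy()].
#' @param seed seed for excerpt/SNR draws (defaults to the policy seed).
#' @return The corrupted [audio_segment()] with an `augmentation`
#'   provenance field.
#' @export
add_noise <- function(segment, bank, kind = c("noise", "music", "babble"),
                      policy = augment_policy(), seed = NULL) {
  kind <- match.arg(kind)
  if (bank$sample_rate != segment$sample_rate)
    stop_pdvoice("noise bank rate ", bank$sample_rate,
                 " != segment rate ", segment$sample_rate)
  source_list <- switch(kind, noise = bank$noises, music = bank$musics,
                        babble = bank$babble_voices)
  if (length(source_list) == 0) stop_pdvoice("empty noise bank for ", kind)
  n <- length(segment$samples)
  fs <- segment$sample_rate
  with_seed(child_seed(seed %||% policy$seed, "add", kind), {
    babble_k <- NA_integer_
    track <- switch(kind,
      noise = {
        period <- max(1L, round(policy$noise_insertion_period_s * fs))
        tr <- numeric(n)
        starts <- seq(1L, n, by = period)
        for (st in starts) {
          len <- min(period, n - st + 1L)
          exc <- source_list[[sample.int(length(source_list), 1)]]
          tr[st + seq_len(len) - 1L] <- fit_length(exc, len)
        }
        tr
      },
      music = fit_length(source_list[[sample.int(length(source_list), 1)]],
                         n),
      babble = {
        k <- sample(seq(policy$babble_count_range[1],
                        policy$babble_count_range[2]), 1)
        picks <- sample.int(length(source_list), k,
                            replace = k > length(source_list))
        babble_k <- k
        Reduce(`+`, lapply(picks, function(i) {
          fit_length(source_list[[i]], n)
        }))
      })
    snr_range <- switch(kind, noise = policy$snr_noise,
                        music = policy$snr_music,
                        babble = policy$snr_babble)
    snr <- stats::runif(1, snr_range[1], snr_range[2])
    out <- segment
    out$samples <- pmax(-1, pmin(1, segment$samples +
                                   scale_to_snr(segment$samples, track,
                                                snr)))
    out$augmentation <- list(kind = kind, snr_db = snr,
                             n_voices = babble_k)
    out
  })
}

#' Augment a training set with 2-of-4 random corruption
#'
#' For each input segment, produces the four corrupted copies
#' (reverberation, noise, music, babble), keeps `policy$keep_copies` of
#' them picked uniformly without replacement, and returns the originals
#' followed by the kept copies -- with the default `keep_copies = 2`,
#' tripling the set size.  Deterministic in the policy seed.  Intended
#' for training-side data only; test subjects are never augmented.
#'
#' @param segments list of [audio_segment()].
#' @param bank a [generate_noise_bank()] at the segments' sample rate.
#' @param policy an [augment_policy()].
#' @return List of segments of length `length(segments) *
#'   (1 + keep_copies)`.
#' @export
augment_dataset <- function(segments, bank, policy = augment_policy()) {
  if (length(segments) == 0) stop_pdvoice("no segments to augment")
  out <- segments
  if (policy$keep_copies == 0) return(out)
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    seed_i <- child_seed(policy$seed, "aug", i)
    copies <- list(
      reverb = with_seed(child_seed(seed_i, "rir"), {
        r <- reverberate(seg, bank$rirs[[sample.int(length(bank$rirs), 1)]])
        r$augmentation <- list(kind = "reverb")
        r
      }),
      noise = add_noise(seg, bank, "noise", policy, seed = seed_i),
      music = add_noise(seg, bank, "music", policy, seed = seed_i),
      babble = add_noise(seg, bank, "babble", policy, seed = seed_i))
    kept <- with_seed(child_seed(seed_i, "pick"), {
      sample(names(copies), policy$keep_copies)
    })
    out <- c(out, unname(copies[kept]))
  }
  out
}
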