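## Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Small high-quality cohort with a strong class effect.
small_cohort <- function() {
  cached("small_cohort", function() {
    generate_cohort(synth_cohort_config(
      n_pd = 3, n_hc = 3, sessions_per_subject = 1, task_duration_s = 4,
      effect_size = 3, seed = 301))
  })
}

## Pure tone segment.
tone_segment <- function(freq = 1000, dur = 1, fs = 16000, amp = 0.1) {
  t <- seq_len(round(dur * fs)) / fs
  audio_segment(amp * sin(2 * pi * freq * t), fs)
}

## Seeded white-noise segment.
noise_segment <- function(dur = 1, fs = 16000, amp = 0.05, seed = 1) {
  n <- round(dur * fs)
  audio_segment(amp * withr::with_seed(seed, stats::rnorm(n)), fs)
}

## Standard battery results, shared between the calibration and ensemble
## acceptance tests.
battery_results <- function() {
  cached("battery", function() {
    do.call(rbind, lapply(1:3, function(s) {
      b <- standard_battery(seed = s)
      b$seed <- s
      b
    }))
  })
}

## Toy 8-speaker cohort features + trained desk-scale TDNN, shared by the
## network-contract tests.
toy_speaker_setup <- function() {
  cached("toy_tdnn", function() {
    cohort <- generate_cohort(synth_cohort_config(
      n_pd = 0, n_hc = 8, sessions_per_subject = 2, task_duration_s = 6,
      subject_sd = 0.15, effect_size = 0, seed = 21))
    cfg <- mfcc_preset("xvector", "high_quality")
    feats <- list(); labs <- character(0)
    for (seg in Filter(function(s) !s$is_calibration_silence,
                       cohort$segments)) {
      for (p in split_segments(seg)) {
        f <- extract_features(p, cfg)
        if (nrow(f$values) >= 15) {
          feats[[length(feats) + 1L]] <- f
          labs <- c(labs, seg$subject_id)
        }
      }
    }
    chunks <- sample_training_chunks(feats, labs, chunks_per_segment = 5,
                                     seed = 2)
    net <- build_tdnn(tdnn_config_small(31, 8, scale = 8), seed = 3)
    net <- train_tdnn(net, chunks$chunks, chunks$labels, epochs = 15,
                      lr = 2e-3, seed = 4)
    list(cohort = cohort, features = feats, labels = labs,
         chunks = chunks, net = net)
  })
}

## Independent naive dmvnorm (log), used as an oracle for PLDA scoring.
naive_dmvnorm_log <- function(x, mu, S) {
  d <- length(x)
  -0.5 * (d * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            as.numeric(t(x - mu) %*% solve(S) %*% (x - mu)))
}

## Independent O(n^2) EER oracle: exhaustive threshold sweep with the
## same crossing-interpolation convention, written as explicit loops.
brute_force_eer <- function(scores, labels) {
  pos <- scores[labels == "PD"]
  neg <- scores[labels == "HC"]
  ts <- c(-Inf, sort(unique(scores)), Inf)
  fpr <- numeric(length(ts)); fnr <- numeric(length(ts))
  for (i in seq_along(ts)) {
    fp <- 0; fn <- 0
    for (s in neg) if (s >= ts[i]) fp <- fp + 1
    for (s in pos) if (s < ts[i]) fn <- fn + 1
    fpr[i] <- fp / length(neg)
    fnr[i] <- fn / length(pos)
  }
  k <- which(fnr >= fpr)[1]
  if (k == 1 || fnr[k] == fpr[k]) return(fpr[k])
  a <- (fpr[k - 1] - fnr[k - 1]) /
    ((fpr[k - 1] - fnr[k - 1]) + (fnr[k] - fpr[k]))
  fpr[k - 1] + a * (fpr[k] - fpr[k - 1])
}
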