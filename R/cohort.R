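#' Configuration for a synthetic voice cohort
#'
#' Describes a single-gender cohort of Parkinson's disease (PD) and healthy
#' control (HC) speakers whose voices are synthesized by a seeded
#' source-filter scheme.  The generator stands in for clinical recordings:
#' each subject draws base voice parameters (pitch, formant center
#' frequencies, aspiration-noise level, pitch-modulation depth) from
#' gender-specific log-normal distributions, and PD-labeled subjects
#' receive a deterministic parameter shift emulating hypokinetic
#' dysarthria: formants compressed toward their centroid (vowel
#' centralization), raised aspiration noise (breathiness), and reduced
#' pitch modulation (monopitch).
#'
#' @param n_pd,n_hc number of PD and HC subjects.
#' @param gender `"M"` or `"F"`; cohorts are single-gender, as models are
#'   always trained per gender.
#' @param sessions_per_subject recording sessions per subject.
#' @param tasks character vector drawn from `"repetition"`,
#'   `"free_speech"`, `"ddk"`, `"reading"`.
#' @param task_duration_s duration of each task recording in seconds.
#' @param channel `"high_quality"` (wide-band microphone) or `"telephone"`
#'   (300--3400 Hz band-limited, resampled to 8 kHz).
#' @param sample_rate output rate in Hz.  Must be 8000 for the telephone
#'   channel; 16000 (default) or 96000 for high quality.
#' @param effect_size class separation of the shifted voice parameters, in
#'   units of the between-subject SD (`subject_sd`); 0 means the PD label
#'   carries no acoustic signal.
#' @param subject_sd between-subject SD of log voice parameters.
#' @param session_sd between-session SD of channel gain/tilt/noise.
#' @param frame_sd short-time SD of the excitation amplitude (log scale).
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return An object of class `synth_cohort_config`.
#' @export
synth_cohort_config <- function(n_pd = 10, n_hc = 10, gender = c("M", "F"),
                                sessions_per_subject = 1,
                                tasks = "free_speech",
                                task_duration_s = 10,
                                channel = c("high_quality", "telephone"),
                                sample_rate = NULL,
                                effect_size = 1,
                                subject_sd = 0.1, session_sd = 0.05,
                                frame_sd = 0.05, seed = 1) {
  gender <- match.arg(gender)
  channel <- match.arg(channel)
  valid_tasks <- c("repetition", "free_speech", "ddk", "reading")
  if (!all(tasks %in% valid_tasks))
    stop_pdvoice("unknown task(s): ", paste(setdiff(tasks, valid_tasks),
                                           collapse = ", "))
  if (channel == "telephone" && "reading" %in% tasks)
    stop_pdvoice("the telephone protocol has no reading task")
  if (is.null(sample_rate))
    sample_rate <- if (channel == "telephone") 8000 else 16000
  if (channel == "telephone" && sample_rate != 8000)
    stop_pdvoice("telephone channel requires sample_rate = 8000")
  if (channel == "high_quality" && !sample_rate %in% c(16000, 96000))
    stop_pdvoice("high_quality channel requires sample_rate 16000 or 96000")
  stopifnot(n_pd >= 0, n_hc >= 0, sessions_per_subject >= 1,
            task_duration_s > 0, effect_size >= 0,
            subject_sd >= 0, session_sd >= 0, frame_sd >= 0)
  structure(list(
    n_pd = as.integer(n_pd), n_hc = as.integer(n_hc), gender = gender,
    sessions_per_subject = as.integer(sessions_per_subject),
    tasks = tasks, task_duration_s = task_duration_s, channel = channel,
    sample_rate = sample_rate, effect_size = effect_size,
    subject_sd = subject_sd, session_sd = session_sd, frame_sd = frame_sd,
    seed = as.integer(seed)
  ), class = "synth_cohort_config")
}

## Gender-specific base voice parameters (Hz / linear amplitude units).
voice_base_params <- function(gender) {
  if (gender == "M") {
    list(f0 = 120, formants = c(500, 1500, 2500, 3500),
         bandwidths = c(90, 110, 170, 250),
         aspiration = 0.05, pitch_mod = 0.05)
  } else {
    list(f0 = 210, formants = c(550, 1650, 2750, 3850),
         bandwidths = c(100, 120, 180, 260),
         aspiration = 0.05, pitch_mod = 0.06)
  }
}

## Draw one subject's voice parameters.  PD subjects get the deterministic
## hypokinetic-dysarthria proxy shift of `effect_size` subject-SDs.
draw_subject_voice <- function(config, label) {
  base <- voice_base_params(config$gender)
  s <- config$subject_sd
  lf <- log(base$formants) + stats::rnorm(4, 0, s)
  lf0 <- log(base$f0) + stats::rnorm(1, 0, s)
  lasp <- log(base$aspiration) + stats::rnorm(1, 0, s)
  lpm <- log(base$pitch_mod) + stats::rnorm(1, 0, s)
  if (label == "PD" && config$effect_size > 0) {
    shift <- config$effect_size * s
    centroid <- mean(log(base$formants))
    lf <- lf + shift * sign(centroid - log(base$formants))
    lasp <- lasp + shift
    lpm <- lpm - shift
  }
  list(f0 = exp(lf0), formants = exp(lf), bandwidths = base$bandwidths,
       aspiration = exp(lasp), pitch_mod = exp(lpm))
}

## Two-pole resonator (formant) filter at center frequency f, bandwidth bw.
formant_filter <- function(x, f, bw, fs) {
  r <- exp(-pi * bw / fs)
  theta <- 2 * pi * f / fs
  a <- c(1, -2 * r * cos(theta), r^2)
  as.numeric(signal::filter(signal::Arma(b = 1 - 2 * r * cos(theta) + r^2,
                                         a = a), x))
}

## Synthesize one voiced task segment at rate fs (before channel effects).
synth_voice <- function(voice, duration_s, fs, frame_sd) {
  n <- round(duration_s * fs)
  ctrl_rate <- 100
  m <- max(2L, ceiling(duration_s * ctrl_rate))
  smooth <- function(v, k = 15) {
    z <- as.numeric(stats::filter(v, rep(1 / k, k), sides = 2))
    z[is.na(z)] <- 0
    z
  }
  ## slow log-f0 modulation with SD voice$pitch_mod
  w <- smooth(stats::rnorm(m))
  sdw <- stats::sd(w); if (sdw > 0) w <- w / sdw * voice$pitch_mod
  f0_ctrl <- voice$f0 * exp(w)
  t_ctrl <- (seq_len(m) - 1) / ctrl_rate
  t_smp <- (seq_len(n) - 1) / fs
  f0_t <- stats::approx(t_ctrl, f0_ctrl, t_smp, rule = 2)$y
  ## glottal impulse train from the running phase
  phase <- cumsum(f0_t / fs)
  pulses <- c(0, diff(floor(phase))) > 0
  excitation <- as.numeric(pulses)
  ## short-time amplitude variability
  amp_ctrl <- exp(stats::rnorm(m, 0, frame_sd))
  amp_t <- stats::approx(t_ctrl, amp_ctrl, t_smp, rule = 2)$y
  ## syllabic gating: speech bursts alternating with short pauses
  syl_rate <- stats::runif(1, 3, 4.5)
  gate_raw <- as.numeric(sin(2 * pi * syl_rate * t_smp +
                               stats::runif(1, 0, 2 * pi)) > -0.4)
  k <- max(3L, round(0.02 * fs))
  gate <- as.numeric(stats::filter(gate_raw, rep(1 / k, k), sides = 2))
  gate[is.na(gate)] <- 0
  ## glottal spectral tilt (-6 dB/oct) on the voiced source
  voiced <- as.numeric(signal::filter(signal::Arma(b = 0.1, a = c(1, -0.97)),
                                      excitation))
  breath <- stats::rnorm(n) * voice$aspiration
  source_sig <- (voiced + breath) * amp_t * gate
  y <- source_sig
  for (i in seq_along(voice$formants)) {
    if (voice$formants[i] < 0.45 * fs) {
      y <- formant_filter(y, voice$formants[i], voice$bandwidths[i], fs)
    }
  }
  rms <- sqrt(mean(y^2))
  if (rms > 0) y <- y * (0.05 / rms)
  y
}

## Per-session channel: gain, first-order spectral tilt, and a stationary
## noise floor whose level is shared with the calibration silence.
draw_session_channel <- function(config) {
  list(gain = exp(stats::rnorm(1, 0, config$session_sd)),
       tilt = tanh(stats::rnorm(1, 0, config$session_sd)),
       noise_level = 1e-3 * exp(stats::rnorm(1, 0, config$session_sd)),
       noise_seed = sample.int(2^31 - 2, 1))
}

apply_channel <- function(x, channel_state, fs, config, noise_stream) {
  y <- x - channel_state$tilt * c(0, x[-length(x)])
  y <- y * channel_state$gain
  y <- y + stats::rnorm(length(y), 0, channel_state$noise_level)
  if (config$channel == "telephone") {
    bp <- signal::butter(4, c(300, 3400) / (fs / 2), type = "pass")
    y <- signal::filtfilt(bp, y)
    seg <- audio_segment(y, fs)
    y <- resample_segment(seg, config$sample_rate)$samples
  }
  pmax(-1, pmin(1, y))
}

#' Generate a synthetic voice cohort
#'
#' Synthesizes every subject/session/task recording of the cohort described
#' by `config`, plus one 5 s calibration-silence segment per session
#' (channel noise only), fully reproducibly from `config$seed`.
#'
#' @param config a [synth_cohort_config()].
#' @return A list of class `voice_cohort` with elements `subjects` (a
#'   data frame: `subject_id`, `label`, `gender`), `segments` (a list of
#'   [audio_segment()]), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synth_cohort_config"))
  fs_gen <- if (config$channel == "telephone") 16000 else config$sample_rate
  labels <- c(rep("PD", config$n_pd), rep("HC", config$n_hc))
  ids <- sprintf("%s_%s_%03d", labels, config$gender,
                 c(seq_len(config$n_pd), seq_len(config$n_hc)))
  subjects <- data.frame(subject_id = ids, label = labels,
                         gender = config$gender, stringsAsFactors = FALSE)
  segments <- list()
  with_seed(config$seed, {
    for (i in seq_along(ids)) {
      voice <- draw_subject_voice(config, labels[i])
      for (s in seq_len(config$sessions_per_subject)) {
        ses_id <- sprintf("ses%02d", s)
        chan <- draw_session_channel(config)
        for (task in config$tasks) {
          raw <- synth_voice(voice, config$task_duration_s, fs_gen,
                             config$frame_sd)
          out <- apply_channel(raw, chan, fs_gen, config)
          segments[[length(segments) + 1L]] <- audio_segment(
            out, config$sample_rate, subject_id = ids[i],
            session_id = ses_id, task = task)
        }
        sil <- apply_channel(numeric(round(5 * fs_gen)), chan, fs_gen, config)
        segments[[length(segments) + 1L]] <- audio_segment(
          sil, config$sample_rate, subject_id = ids[i], session_id = ses_id,
          task = "calibration", is_calibration_silence = TRUE)
      }
    }
  })
  structure(list(subjects = subjects, segments = segments, config = config),
            class = "voice_cohort")
}

#' @export
print.voice_cohort <- function(x, ...) {
  cat(sprintf("<voice_cohort: %d PD + %d HC (%s), %d segments, %s @ %g Hz>\n",
              sum(x$subjects$label == "PD"), sum(x$subjects$label == "HC"),
              x$config$gender, length(x$segments), x$config$channel,
              x$config$sample_rate))
  invisible(x)
}

#' Write a cohort to WAV files with a manifest
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest data frame (`subject_id`, `label`, `gender`,
#'   `session`, `task`, `path`), also written to `manifest.csv` in `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(cohort$segments), function(i) {
    seg <- cohort$segments[[i]]
    fn <- sprintf("%s_%s_%s.wav", seg$subject_id, seg$session_id, seg$task)
    write_wav(seg, file.path(dir, fn))
    lab <- cohort$subjects$label[match(seg$subject_id,
                                       cohort$subjects$subject_id)]
    data.frame(subject_id = seg$subject_id, label = lab,
               gender = cohort$config$gender, session = seg$session_id,
               task = seg$task, path = fn, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Generate a synthetic noise and impulse-response bank
#'
#' Surrogate for the MUSAN-style corpora used in data augmentation:
#' colored-noise bursts, harmonic music surrogates, synthetic babble
#' voices, and exponentially decaying room impulse responses.
#'
#' @param sample_rate bank sampling rate in Hz.
#' @param seed integer seed; banks are bit-identical given the same seed.
#' @param n_noises,n_musics,n_babble,n_rirs entry counts (defaults meet the
#'   minimum bank sizes the augmentation policy expects).
#' @return An object of class `noise_bank` with elements `rirs`, `noises`,
#'   `musics`, `babble_voices` (lists of numeric vectors) and
#'   `sample_rate`.
#' @export
generate_noise_bank <- function(sample_rate, seed = 1, n_noises = 8,
                                n_musics = 4, n_babble = 8, n_rirs = 4) {
  stopifnot(sample_rate > 0)
  fs <- sample_rate
  with_seed(child_seed(seed, "noise_bank"), {
    noises <- lapply(seq_len(n_noises), function(i) {
      n <- round(stats::runif(1, 1, 3) * fs)
      a <- stats::runif(1, -0.9, 0.9)
      x <- as.numeric(signal::filter(signal::Arma(b = 1, a = c(1, -a)),
                                     stats::rnorm(n)))
      x / max(abs(x)) * 0.5
    })
    musics <- lapply(seq_len(n_musics), function(i) {
      dur <- stats::runif(1, 4, 6)
      t <- seq(0, dur, by = 1 / fs)
      f0 <- stats::runif(1, 100, 400)
      x <- numeric(length(t))
      for (h in seq_len(sample(3:5, 1))) {
        x <- x + stats::runif(1, 0.3, 1) *
          sin(2 * pi * f0 * h * t + stats::runif(1, 0, 2 * pi))
      }
      x <- x * (0.6 + 0.4 * sin(2 * pi * stats::runif(1, 1, 3) * t))
      x / max(abs(x)) * 0.5
    })
    babble <- lapply(seq_len(n_babble), function(i) {
      voice <- list(
        f0 = stats::runif(1, 100, 240),
        formants = c(500, 1500, 2500, 3500) * exp(stats::rnorm(4, 0, 0.12)),
        bandwidths = c(90, 110, 170, 250),
        aspiration = 0.05, pitch_mod = 0.05)
      x <- synth_voice(voice, 4, fs, 0.05)
      x / max(abs(x)) * 0.5
    })
    rirs <- lapply(seq_len(n_rirs), function(i) {
      tau <- stats::runif(1, 0.05, 0.25)
      n <- round(0.4 * fs)
      t <- (seq_len(n) - 1) / fs
      h <- stats::rnorm(n) * exp(-t / tau)
      h[1] <- 1
      h / sqrt(sum(h^2))
    })
    structure(list(rirs = rirs, noises = noises, musics = musics,
                   babble_voices = babble, sample_rate = fs),
              class = "noise_bank")
  })
}

#' Resample every entry of a noise bank
#'
#' Used to reuse a wide-band bank for the 8 kHz telephone branch.
#'
#' @param bank a [generate_noise_bank()] result.
#' @param new_rate target rate in Hz.
#' @return A `noise_bank` at `new_rate`.
#' @export
resample_noise_bank <- function(bank, new_rate) {
  if (new_rate == bank$sample_rate) return(bank)
  rs <- function(x) resample_segment(audio_segment(x, bank$sample_rate),
                                     new_rate)$samples
  structure(list(rirs = lapply(bank$rirs, function(h) {
    h2 <- rs(h); h2 / sqrt(sum(h2^2))
  }),
  noises = lapply(bank$noises, rs), musics = lapply(bank$musics, rs),
  babble_voices = lapply(bank$babble_voices, rs), sample_rate = new_rate),
  class = "noise_bank")
}

#' Sample a labeled population from the PLDA generative model
#'
#' Draws vectors from `x = mu + F h + G w + eps`, `eps ~ N(0, Sigma)`
#' (diagonal `Sigma`), with a per-class latent `h` and per-sample latent
#' `w`, and returns both the samples and the true parameters.  Used to
#' validate the PLDA back-end against known ground truth.
#'
#' @param n_classes,per_class number of classes and samples per class.
#' @param dim observation dimension.
#' @param F_rank,G_rank ranks of the between-class (`F`) and within-class
#'   (`G`) factor loadings; `F_rank + G_rank <= dim` is required.
#' @param seed integer seed.
#' @param mu,F,G,Sigma optional true parameters; drawn at random when
#'   `NULL` (`Sigma` is a diagonal vector).
#' @return A list: `x` (n x dim matrix), `labels`, and the true `mu`, `F`,
#'   `G`, `Sigma`, `h`.
#' @export
generate_plda_population <- function(n_classes, per_class, dim, F_rank,
                                     G_rank, seed = 1, mu = NULL, F = NULL,
                                     G = NULL, Sigma = NULL) {
  if (F_rank + G_rank > dim)
    stop_pdvoice("F_rank + G_rank must not exceed dim")
  with_seed(child_seed(seed, "plda_pop"), {
    if (is.null(mu)) mu <- stats::rnorm(dim)
    if (is.null(F)) F <- matrix(stats::rnorm(dim * F_rank), dim, F_rank)
    if (F_rank == 0) F <- matrix(0, dim, 0)
    if (is.null(G)) G <- matrix(stats::rnorm(dim * G_rank, sd = 0.7),
                                dim, G_rank)
    if (G_rank == 0) G <- matrix(0, dim, 0)
    if (is.null(Sigma)) Sigma <- stats::runif(dim, 0.1, 0.5)
    h <- matrix(stats::rnorm(n_classes * F_rank), n_classes, F_rank)
    n <- n_classes * per_class
    labels <- rep(seq_len(n_classes), each = per_class)
    w <- matrix(stats::rnorm(n * G_rank), n, G_rank)
    eps <- matrix(stats::rnorm(n * dim), n, dim) %*% diag(sqrt(Sigma), dim)
    x <- matrix(mu, n, dim, byrow = TRUE) + h[labels, , drop = FALSE] %*%
      t(F) + w %*% t(G) + eps
    list(x = x, labels = labels, mu = mu, F = F, G = G, Sigma = Sigma, h = h)
  })
}
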