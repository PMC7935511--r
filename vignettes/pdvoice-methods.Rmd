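---
title: "Detecting early Parkinson's disease from speech: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting early Parkinson's disease from speech: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pdvoice)
```

## The problem

Hypokinetic dysarthria -- reduced prosody, breathier phonation, imprecise
articulation -- is among the earliest motor signs of Parkinson's disease
(PD).  Because articulation shapes the vocal-tract transfer function, its
degradation is visible in the spectral envelope of speech, which is what
Mel-frequency cepstral coefficients (MFCCs) summarize.  `pdvoice`
implements two complete classification branches that map a subject's
recordings to a PD-vs-healthy-control (HC) score in (0, 1), and an
ensemble evaluation protocol that turns per-run scores into a stable
subject-level decision.  Models are always trained per gender: pooling
genders inflates within-class variance and masks the disease effect, so
the runner never does it silently.

## Branch 1: MFCC-GMM baseline

Per frame (20 ms window, 10 ms step) the front end extracts log-energy
plus 19 MFCCs from a 23-filter Mel filterbank (20--7000 Hz for wide-band
microphone audio, 300--3700 Hz for telephone audio), appends delta and
delta-delta regressions, removes silent frames with an energy VAD, and
applies 300 ms sliding-window cepstral mean subtraction (CMS).  The
pooled voiced frames of each training group are modeled by a
diagonal-covariance Gaussian mixture (20 components for the high-quality
channel, 50 for telephone, where more sessions are available) fitted by
EM from a seeded k-means start.  A test subject's score is

$$s = \sigma\big(\alpha\,(\overline{\log p}_{\mathrm{PD}} -
\overline{\log p}_{\mathrm{HC}})\big),$$

the sigmoid of the difference of frame-averaged log-likelihoods under
the two class models.  Averaging over frames makes the statistic
independent of recording length; the sigmoid slope $\alpha$ only
calibrates scores and cannot change the equal error rate (EER), which is
invariant to monotone transforms.

## Branch 2: x-vectors

A time-delay neural network (TDNN) ingests per-frame features (25 ms
windows; 23 cepstra with a 20--3700 Hz filterbank for telephone, 30 with
20--7600 Hz for wide-band; no deltas -- temporal context is the
network's job).  Five frame-level layers with dilated splicing
($\{-2..2\}$, $\{-2,0,2\}$, $\{-3,0,3\}$, $\{0\}$, $\{0\}$; receptive
field 15 frames) feed a statistics-pooling layer (per-dimension mean and
population SD), then two segment-level layers and a softmax over
training labels.  The x-vector is the pre-ReLU activation of the first
segment-level layer: a fixed-length embedding of a variable-length
segment.  At full width the dimension chain is 5K → 512 → (1536) 512 →
(1536) 512 → 512 → 1500 → pooling 3000 → 512 → 512 → N.

Recordings are tiled into 1--5 s pieces (matched mode; a mismatched mode
accepts any duration in 25 ms -- 100 s and averages the x-vectors of
fragments cut from files longer than 100 s).  Back-ends compare a test
x-vector to the training-group mean x-vectors of each class:

* **cosine** -- cosine similarity to each reference;
* **lda_cosine** -- cosine in a 2-D Fisher discriminant space
  (within-class whitening then between-class eigendecomposition);
* **plda** -- the log-likelihood ratio of the "same class latent"
  hypothesis under the generative model
  $x = \mu + F h + G w + \epsilon$, $\epsilon \sim N(0, \Sigma)$
  (diagonal $\Sigma$; class latent $h$, speaker/session latent $w$),
  scored in closed form through the two-covariance identities
  (between $FF^\top$, within $GG^\top + \Sigma$), preceded by an LDA
  dimension reduction (default 16).

The subject score is again a sigmoid of the similarity difference,
averaged over the subject's segments.

## Ensemble protocol

Training sets in this design are small and class-imbalanced, so a
single split is noisy.  The evaluator draws 40 (configurable) random
class-balanced training groups without replacement; every run tests all
remaining subjects.  Each subject's final score $\Lambda_j$ is the mean
of the scores from runs where that subject was out of training
(out-of-bag), which the implementation asserts structurally.  Per-run
DET curves are kept, and the EER of their probit-domain average
estimates the single-model performance, so the aggregated-vs-single
comparison can be reproduced.  EER uses a threshold sweep with linear
interpolation at the FPR/FNR crossing -- necessary because subject
counts are small and error rates move in coarse steps.

## The synthetic cohort

The clinical recordings behind this methodology cannot be shipped, so
the package grows its own: a seeded source-filter synthesizer.  Each
subject draws pitch, four formant frequencies, aspiration level and
pitch-modulation depth from gender-specific log-normal distributions
(relative SD `subject_sd`, default 0.1).  PD-labeled subjects receive a
deterministic shift of `effect_size` subject-SDs: formants compressed
toward their centroid (vowel centralization), aspiration raised
(breathiness), pitch modulation reduced (monopitch).  Sessions perturb
channel gain, spectral tilt and a stationary noise floor
(`session_sd`); the excitation amplitude carries short-time variability
(`frame_sd`).  Speech alternates syllabic bursts with pauses, giving
the VAD real work.  The telephone channel band-limits to 300--3400 Hz
before resampling to 8 kHz; each session ends with 5 s of pure channel
noise, the calibration silence consumed by spectral subtraction.

`effect_size` is a simulation knob in units of between-subject SD, not
a clinical estimate -- no quantitative description of the acoustic
effect magnitude of early PD exists to calibrate against.  What the
generator does establish: at `effect_size = 0` the label is
exchangeable, so any correct pipeline must hit EER ≈ 0.5; at
`effect_size = 3` per-subject MFCC means separate by > 2 pooled SD, so
a correct pipeline must perform well; and EER must fall as the effect
grows.  Passing these tests shows the machinery is sound, not that
synthetic voices capture clinical dysarthria: the synthesizer makes no
attempt at perceptual realism, task-specific phonetics, or the
articulatory dynamics of real speech.

## Numerical and design choices

* **Spectral subtraction** operates on short-time magnitude spectra
  (32 ms, 50% overlap, Hann analysis with least-squares overlap-add),
  subtracting the calibration-estimated noise magnitude and flooring at
  `floor` times the input magnitude, so `oversubtraction = 0, floor = 1`
  is the identity.  The default oversubtraction is 1.5: at 1.0,
  magnitude-domain subtraction of the *mean* noise spectrum leaves the
  upper half of the Rayleigh-distributed magnitude fluctuations intact,
  and residual noise power only drops by ~9 dB; mild Berouti-style
  oversubtraction removes that fluctuation shoulder (~15 dB on matched
  stationary noise) at negligible cost to speech bins.
* **Feature order**: CMS runs on static cepstra before deltas, and VAD
  frame removal is applied after delta computation, so deltas always
  come from true temporal neighbors.  Whether CMS precedes deltas is
  genuinely open; this choice keeps the channel correction out of the
  dynamic features.  Log-energy is computed on the raw frame at the
  16-bit integer sample scale (natural log), making the VAD's absolute
  floor (default 5.0) meaningful; the mean-relative term has scale 0.5.
* **DCT**: orthonormal DCT-II keeping coefficients 1..n; coefficient 0
  is dropped because log-energy is carried separately.  Pre-emphasis
  0.97 and a Hamming window follow the convention of the speech toolkit
  lineage this pipeline mirrors.
* **GMM EM**: variance floor at 1e-3 of the global per-dimension
  variance (collapse triggers a warning, never a crash), tolerance 1e-4
  on the mean log-likelihood, monotonicity asserted every iteration.
* **PLDA EM** uses exact Gaussian posteriors (the class latent is
  integrated in closed form; sample latents are handled by the chain
  rule) and a moment-based initialization -- within-class covariance
  eigenvectors for $G$, bias-corrected class-mean covariance for $F$ --
  because random initializations visibly find poor local optima of the
  marginal likelihood.  With two classes the class subspace is rank 1
  by default.
* **LDA** ridge-regularizes the within-class scatter by
  $10^{-6}\,\mathrm{tr}(S_w)/d$; with two classes the second of the
  "two-dimensional" discriminant directions comes from the whitening
  eigenbasis, and `dim_out` is configurable.
* **Statistics pooling** uses the population (biased) SD; the
  convention is unobservable downstream but is frozen here for
  reproducibility.
* **TDNN training** is plain Adam on softmax cross-entropy over 2--4 s
  chunks, implemented directly in base R matrix algebra with exact
  backpropagation through the pooling layer (verified against numerical
  gradients).  No batch normalization; seeded and bit-reproducible on
  one thread.  The full 512-wide network is built for the dimension
  contract; experiments use a width-divided desk profile (default /8).
* **Augmentation** draws one SNR per corrupted copy (noise [0, 15] dB,
  music/babble [5, 15] dB) and re-draws the noise excerpt every second
  at that fixed SNR; babble sums 3--7 voices.  Augmented copies feed
  only training-side models.
* **Ensemble x-vector branch**: the TDNN extractor is trained once per
  cohort on speaker identities -- never on PD labels -- and only the
  back-ends are refitted per run.  This mirrors using a fixed
  pretrained extractor with per-split back-end training and keeps the
  out-of-bag aggregation honest.

## Problem sizes

The standard battery (`standard_battery()`) uses 12 PD + 12 HC subjects,
two sessions of 6 s free speech each, 12 ensemble runs with 8+8 training
subjects, 8 GMM components, and a /8-width TDNNs -- sizes chosen so the
full grid (two branches × effect sizes 0, 1, 3 × three seeds) remains a
desk-scale computation while every subject is expected to be tested
about four times per plan.  The component-recovery analyses use n =
20000 frames (GMM), n = 5000 vectors in 1000 classes (PLDA), and 160
training chunks over 8 speakers (TDNN).

## Known limitations

* Synthetic voices validate the pipeline, not the clinical claim; EERs
  from the battery say nothing about performance on real dysarthric
  speech.
* The G.711 codec chain of real telephone acquisition is not simulated,
  only the band-limit and sample rate.
* The desk-scale TDNN sees dozens of speakers, not thousands; its
  embeddings are far weaker than those of a production x-vector system,
  which is why back-end comparisons on the battery should be read as
  directional only.
* Score fusion across tasks and alternative distance measures are out
  of scope.
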