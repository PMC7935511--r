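# pdvoice

Classification of early-stage Parkinson's disease (PD) from voice
recordings, for researchers working on digital speech biomarkers.
Hypokinetic dysarthria alters the spectral envelope of speech;
`pdvoice` implements, end to end and fully seeded, the two standard
cepstral classification branches and the ensemble protocol used to
evaluate them on small clinical cohorts:

* **MFCC-GMM baseline** — per-class diagonal-covariance Gaussian
  mixtures over voiced MFCC frames (log-energy + 19 cepstra + deltas;
  energy VAD; 300 ms sliding cepstral mean subtraction; spectral
  subtraction against a per-session calibration silence), scored per
  subject by `sigmoid(mean log p_PD − mean log p_HC)`.
* **x-vector branch** — a time-delay neural network (frame-level
  dilated splicing, statistics pooling of per-dimension mean and SD,
  segment-level layers; the x-vector is the 512-dim pre-ReLU activation
  of the first segment-level layer) with cosine, LDA + cosine, and PLDA
  (`x = μ + F h + G w + ε`, diagonal Σ) back-ends against class-mean
  reference x-vectors.
* **Ensemble evaluation** — repeated random subsampling with
  class-balanced training groups (40 runs by default), out-of-bag
  per-subject score averaging, EER/DET metrics, and probit-domain DET
  averaging for the aggregated-vs-single-model comparison.
* **Data augmentation** — Kaldi-style reverberation / noise / music /
  babble corruption, keeping 2 of 4 copies (3× the training set).
* **Synthetic cohorts** — a seeded source-filter voice synthesizer
  with a controllable PD effect (formant centralization, breathiness,
  monopitch) standing in for clinical recordings that cannot be
  shipped, plus a synthetic noise/RIR bank.

## Worked example

```r
library(pdvoice)

cohort_cfg <- synth_cohort_config(
  n_pd = 12, n_hc = 12, sessions_per_subject = 2,
  task_duration_s = 6, effect_size = 3, seed = 11)

run_experiment(experiment_config(
  cohort_cfg, branch = "gmm", n_runs = 12, gmm_components = 8, seed = 1))
#> <experiment_result: branch gmm, aggregated EER 0.000,
#>  mean per-run EER 0.000, single-model EER 0.020>

run_experiment(experiment_config(
  cohort_cfg, branch = "xvector", backend = "lda_cosine",
  n_runs = 12, epochs = 10, seed = 1))
#> <experiment_result: branch xvector+lda_cosine, aggregated EER 0.083,
#>  mean per-run EER 0.167, single-model EER 0.069>
```

With a strong synthetic effect (`effect_size = 3`, i.e. the PD voice
parameters shifted by three between-subject SDs) both branches separate
the classes nearly perfectly; the x-vector numbers also show the
ensemble effect — the out-of-bag aggregated model (EER 8.3%) beats the
average single run (16.7%). At `effect_size = 0` the PD label carries
no acoustic information and both branches calibrate to EER ≈ 0.5 (with
24 subjects a single draw scatters around chance in steps of 1/12; the
acceptance checks average three seeds). The fixed grid over effect
sizes {0, 1, 3} for both branches is exposed as
`standard_battery(seed)`:

```r
standard_battery(seed = 1)
#>    branch effect_size aggregated_eer mean_run_eer single_model_eer
#> 1     gmm           0      0.5000000    0.5416667       0.54359323
#> 2 xvector           0      0.6666667    0.5416667       0.55411439
#> 3     gmm           1      0.1666667    0.1250000       0.05689135
#> 4 xvector           1      0.2500000    0.4375000       0.40778353
#> 5     gmm           3      0.0000000    0.0000000       0.02043123
#> 6 xvector           3      0.0000000    0.1666667       0.08642950
```

## Documentation

The methods vignette (`vignettes/pdvoice-methods.Rmd`) describes the
models, the synthetic-cohort design and its limits, and every numerical
convention (EER interpolation, pooling SD, CMS ordering, spectral
subtraction floors) in detail.
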