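Package: pdvoice
Title: Early Parkinson's Disease Detection from Speech with MFCC-GMM and
    X-Vector Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for classifying early-stage Parkinson's
    disease from voice recordings using two branches: a baseline that
    models Mel-frequency cepstral coefficient (MFCC) distributions of
    patient and control groups with diagonal-covariance Gaussian mixture
    models scored by a sigmoid log-likelihood ratio, and an x-vector
    branch that extracts fixed-length speaker embeddings from a
    time-delay neural network with statistics pooling and classifies
    them against class-mean references with cosine similarity, linear
    discriminant analysis, or probabilistic linear discriminant analysis
    back-ends.  Includes spectral subtraction, energy-based voice
    activity detection, sliding-window cepstral mean subtraction,
    Kaldi-style reverberation/noise/music/babble data augmentation, a
    repeated-random-subsampling ensemble evaluator with equal-error-rate
    and detection-error-tradeoff metrics, and a seeded source-filter
    synthetic voice cohort generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
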