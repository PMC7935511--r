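## Per-subject calibration lookup: session -> calibration segment.
calibration_index <- function(cohort) {
  idx <- list()
  for (seg in cohort$segments) {
    if (seg$is_calibration_silence)
      idx[[paste(seg$subject_id, seg$session_id, sep = "/")]] <- seg
  }
  idx
}

task_segments <- function(cohort, task) {
  Filter(function(s) !s$is_calibration_silence && s$task == task,
         cohort$segments)
}

#' Build the MFCC-GMM branch pipeline for one cohort and task
#'
#' Precomputes each subject's pooled voiced frames (per-session spectral
#' subtraction on the high-quality channel, MFCC + deltas, VAD, CMS) and
#' exposes the `train`/`score` interface consumed by [run_ensemble()]:
#' per run, one PD and one HC diagonal GMM are trained on the run's
#' training groups and test subjects are scored by the sigmoid
#' log-likelihood ratio.
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param task which speech task to model.
#' @param n_components Gaussians per class model (`NULL`: 20 for the
#'   high-quality channel, 50 for telephone).
#' @param sigmoid_scale sigmoid slope for score calibration.
#' @param spectral_subtraction denoise with the session calibration
#'   silence (defaults to on for the high-quality channel only, matching
#'   the acquisition protocols).
#' @param max_iter,tol GMM EM settings.
#' @return A pipeline list (`train`, `score`, `features`).
#' @export
make_gmm_pipeline <- function(cohort, task = cohort$config$tasks[1],
                              n_components = NULL, sigmoid_scale = 1,
                              spectral_subtraction =
                                cohort$config$channel == "high_quality",
                              max_iter = 30, tol = 1e-4) {
  channel <- cohort$config$channel
  if (is.null(n_components))
    n_components <- if (channel == "telephone") 50 else 20
  cfg <- mfcc_preset("gmm", channel, cohort$config$sample_rate)
  calib <- calibration_index(cohort)
  feats <- list()
  for (seg in task_segments(cohort, task)) {
    cal <- if (spectral_subtraction)
      calib[[paste(seg$subject_id, seg$session_id, sep = "/")]] else NULL
    f <- extract_features(seg, cfg, calibration = cal)
    sid <- seg$subject_id
    feats[[sid]] <- rbind(feats[[sid]], f$values)
  }
  list(
    branch = "gmm",
    n_components = n_components,
    features = feats,
    train = function(train_pd, train_hc, run_seed = 1) {
      pool <- function(ids) do.call(rbind, feats[ids])
      pd <- train_gmm(pool(train_pd), n_components, max_iter = max_iter,
                      tol = tol, seed = child_seed(run_seed, "pd"))
      hc <- train_gmm(pool(train_hc), n_components, max_iter = max_iter,
                      tol = tol, seed = child_seed(run_seed, "hc"))
      gmm_pair(pd, hc, gender = cohort$config$gender)
    },
    score = function(model, subject_id) {
      x <- feats[[subject_id]]
      if (is.null(x) || nrow(x) == 0) return(NA_real_)
      score_subject_gmm(model, x, sigmoid_scale = sigmoid_scale)
    })
}

#' Build the x-vector branch pipeline for one cohort and task
#'
#' Splits each recording into duration-bounded pieces, extracts features,
#' trains a compact TDNN once per cohort in speaker-identification mode
#' (no PD labels are used by the extractor), and precomputes one x-vector
#' per piece.  The returned `train`/`score` interface then fits only the
#' back-end per ensemble run: class-mean references plus, depending on
#' `backend`, a 2-D LDA for cosine scoring or an LDA dimension reduction
#' followed by PLDA.  With `augment = TRUE`, augmented copies of the
#' training subjects' audio contribute extra x-vectors to back-end
#' training (test subjects are never augmented).
#'
#' @inheritParams make_gmm_pipeline
#' @param backend `"cosine"`, `"lda_cosine"`, or `"plda"`.
#' @param segment_mode `"matched"` (1--5 s pieces) or `"mismatched"`
#'   (25 ms -- 100 s).
#' @param tdnn_scale width divisor of the desk-scale TDNN.
#' @param epochs,lr TDNN training settings.
#' @param augment augment back-end training data.
#' @param bank noise bank for augmentation (`NULL`: generated at the
#'   cohort rate from `seed`).
#' @param lda_dim discriminant dimension for `lda_cosine`.
#' @param plda_reduce_dim LDA pre-reduction dimension before PLDA.
#' @param seed seed of TDNN initialization/training and augmentation.
#' @return A pipeline list (`train`, `score`, `xvectors`, `tdnn`).
#' @export
make_xvector_pipeline <- function(cohort, task = cohort$config$tasks[1],
                                  backend = c("cosine", "lda_cosine",
                                              "plda"),
                                  segment_mode = c("matched", "mismatched"),
                                  tdnn_scale = 8, epochs = 12, lr = 2e-3,
                                  augment = FALSE, bank = NULL,
                                  lda_dim = 2, plda_reduce_dim = 16,
                                  sigmoid_scale = 1,
                                  spectral_subtraction =
                                    cohort$config$channel == "high_quality",
                                  seed = 1) {
  backend <- match.arg(backend)
  segment_mode <- match.arg(segment_mode)
  channel <- cohort$config$channel
  cfg <- mfcc_preset("xvector", channel, cohort$config$sample_rate)
  calib <- calibration_index(cohort)
  piece_features <- function(seg) {
    cal <- if (spectral_subtraction)
      calib[[paste(seg$subject_id, seg$session_id, sep = "/")]] else NULL
    pieces <- split_segments(seg, mode = segment_mode)
    fs <- lapply(pieces, function(p) extract_features(p, cfg,
                                                      calibration = cal))
    Filter(function(f) nrow(f$values) >= 15, fs)
  }
  segs <- task_segments(cohort, task)
  feats <- unlist(lapply(segs, piece_features), recursive = FALSE)
  subj_of <- vapply(feats, function(f) f$provenance$subject_id,
                    character(1))
  ## TDNN trained once, on speaker identity
  chunks <- sample_training_chunks(feats, subj_of, chunks_per_segment = 2,
                                   seed = child_seed(seed, "chunks"))
  net <- build_tdnn(tdnn_config_small(feature_dim(cfg),
                                      length(unique(chunks$labels)),
                                      scale = tdnn_scale),
                    seed = child_seed(seed, "init"))
  net <- train_tdnn(net, chunks$chunks, chunks$labels,
                    label_mode = "speaker", epochs = epochs, lr = lr,
                    seed = child_seed(seed, "train"))
  xv_of <- function(feature_list) {
    vecs <- extract_for_file(net, feature_list)
    do.call(rbind, lapply(vecs, as.numeric))
  }
  xv <- xv_of(feats)
  xv_aug <- NULL; aug_subj <- NULL
  if (augment) {
    if (is.null(bank)) bank <- generate_noise_bank(
      cohort$config$sample_rate, seed = child_seed(seed, "bank"))
    policy <- augment_policy(seed = child_seed(seed, "aug"))
    aug_segs <- augment_dataset(segs, bank, policy)
    aug_segs <- aug_segs[-seq_along(segs)]  # corrupted copies only
    aug_feats <- unlist(lapply(aug_segs, piece_features),
                        recursive = FALSE)
    if (length(aug_feats)) {
      xv_aug <- xv_of(aug_feats)
      aug_subj <- vapply(aug_feats, function(f) f$provenance$subject_id,
                         character(1))
    }
  }
  label_of <- stats::setNames(cohort$subjects$label,
                              cohort$subjects$subject_id)
  list(
    branch = "xvector", backend = backend, tdnn = net, xvectors = xv,
    xvector_subjects = subj_of,
    train = function(train_pd, train_hc, run_seed = 1) {
      ids <- c(train_pd, train_hc)
      in_train <- subj_of %in% ids
      x <- xv[in_train, , drop = FALSE]
      lab <- label_of[subj_of[in_train]]
      if (!is.null(xv_aug)) {
        ia <- aug_subj %in% ids
        x <- rbind(x, xv_aug[ia, , drop = FALSE])
        lab <- c(lab, label_of[aug_subj[ia]])
      }
      refs <- compute_references(x, lab, gender = cohort$config$gender)
      lda <- NULL; plda <- NULL
      if (backend == "lda_cosine") {
        lda <- fit_lda(x, lab, dim_out = lda_dim)
      } else if (backend == "plda") {
        red_dim <- min(plda_reduce_dim, ncol(x), nrow(x) - 2)
        lda <- fit_lda(x, lab, dim_out = red_dim)
        plda <- fit_plda(lda_project(lda, x), lab, rank_F = 1,
                         rank_G = red_dim - 1, iters = 20,
                         seed = child_seed(run_seed, "plda"))
      }
      list(refs = refs, lda = lda, plda = plda)
    },
    score = function(model, subject_id) {
      rows <- which(subj_of == subject_id)
      if (length(rows) == 0) return(NA_real_)
      seg_scores <- vapply(rows, function(i) {
        score_xvector(model$refs, xv[i, ], method = backend,
                      lda = model$lda, plda = model$plda,
                      sigmoid_scale = sigmoid_scale)
      }, numeric(1))
      score_subject(seg_scores)
    })
}

#' Experiment configuration
#'
#' Bundles a cohort configuration with the branch, back-end and ensemble
#' settings of one experimental cell.  Presets follow the study grid:
#' the telephone channel has no reading task and defaults to 50 GMM
#' components, the high-quality channel to 20; genders are never pooled
#' (a cohort is single-gender by construction).
#'
#' @param cohort a [synth_cohort_config()].
#' @param branch `"gmm"` or `"xvector"`.
#' @param backend x-vector back-end (`"cosine"`, `"lda_cosine"`,
#'   `"plda"`); ignored for the GMM branch.
#' @param task task to analyze (default: first cohort task).
#' @param n_runs ensemble runs (default 40).
#' @param n_train_pd,n_train_hc class-balanced training-group sizes
#'   (default: two thirds of the smaller class).
#' @param segment_mode `"matched"` or `"mismatched"` piece durations.
#' @param augment augment back-end training data.
#' @param gmm_components GMM component override (`NULL` = channel
#'   default).
#' @param tdnn_scale,epochs,lr desk-scale TDNN settings.
#' @param seed master seed of the experiment.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort, branch = c("gmm", "xvector"),
                              backend = c("lda_cosine", "cosine", "plda"),
                              task = NULL, n_runs = 40,
                              n_train_pd = NULL, n_train_hc = NULL,
                              segment_mode = c("matched", "mismatched"),
                              augment = FALSE, gmm_components = NULL,
                              tdnn_scale = 8, epochs = 12, lr = 2e-3,
                              seed = 1) {
  branch <- match.arg(branch)
  backend <- match.arg(backend)
  segment_mode <- match.arg(segment_mode)
  stopifnot(inherits(cohort, "synth_cohort_config"))
  if (is.null(task)) task <- cohort$tasks[1]
  if (!task %in% cohort$tasks)
    stop_pdvoice("task ", task, " is not generated by this cohort config")
  if (is.null(n_train_pd)) {
    n_bal <- max(1L, floor(2 / 3 * min(cohort$n_pd, cohort$n_hc)))
    n_train_pd <- n_bal; n_train_hc <- n_bal
  }
  structure(list(cohort = cohort, branch = branch, backend = backend,
                 task = task, n_runs = as.integer(n_runs),
                 n_train_pd = as.integer(n_train_pd),
                 n_train_hc = as.integer(n_train_hc),
                 segment_mode = segment_mode, augment = augment,
                 gmm_components = gmm_components,
                 tdnn_scale = tdnn_scale, epochs = epochs, lr = lr,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf))
  dput(unclass_recursive(config), file = tf)
  unname(tools::md5sum(tf))
}

#' Run one end-to-end experiment
#'
#' Generates the synthetic cohort, builds the configured branch pipeline,
#' draws the repeated-random-subsampling split plan, runs the ensemble,
#' and returns the evaluation summary.  Bit-reproducible given the
#' config's seeds on a single thread.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for score TSVs and a JSON summary.
#' @return A list of class `experiment_result`: `aggregated_eer`,
#'   `mean_run_eer`, `single_model_eer`, the full `score_table`,
#'   `config`, and `config_hash`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  cohort <- generate_cohort(config$cohort)
  pipeline <- if (config$branch == "gmm") {
    make_gmm_pipeline(cohort, task = config$task,
                      n_components = config$gmm_components)
  } else {
    make_xvector_pipeline(cohort, task = config$task,
                          backend = config$backend,
                          segment_mode = config$segment_mode,
                          tdnn_scale = config$tdnn_scale,
                          epochs = config$epochs, lr = config$lr,
                          augment = config$augment,
                          seed = child_seed(config$seed, "xvec"))
  }
  splits <- make_splits(cohort$subjects, config$n_train_pd,
                        config$n_train_hc, n_runs = config$n_runs,
                        seed = child_seed(config$seed, "splits"))
  table <- run_ensemble(pipeline, splits, cohort$subjects,
                        seed = child_seed(config$seed, "ensemble"))
  result <- structure(list(
    aggregated_eer = table$aggregated_eer,
    mean_run_eer = mean(table$per_run_eer, na.rm = TRUE),
    single_model_eer = table$single_model_eer,
    score_table = table, config = config,
    config_hash = config_hash(config)), class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_score_table(table, out_dir)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        list(aggregated_eer = result$aggregated_eer,
             mean_run_eer = result$mean_run_eer,
             single_model_eer = result$single_model_eer,
             branch = config$branch, backend = config$backend,
             task = config$task, n_runs = config$n_runs,
             config_hash = result$config_hash,
             seed = config$seed),
        file.path(out_dir, "summary.json"), auto_unbox = TRUE)
    }
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(paste0("<experiment_result: branch %s%s, aggregated EER ",
                     "%.3f, mean per-run EER %.3f, single-model EER ",
                     "%.3f>\n"),
              x$config$branch,
              if (x$config$branch == "xvector")
                paste0("+", x$config$backend) else "",
              x$aggregated_eer, x$mean_run_eer, x$single_model_eer))
  invisible(x)
}
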