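#' Repeated random subsampling split plan
#'
#' Draws `n_runs` independent class-balanced training groups without
#' replacement; in each run the test group contains all remaining
#' subjects.  Deterministic in `seed`.
#'
#' @param subjects data frame with columns `subject_id` and `label`
#'   (`"PD"`/`"HC"`).
#' @param n_train_pd,n_train_hc training-group sizes; must be equal
#'   (class-balanced) and leave at least one test subject per class.
#' @param n_runs number of runs (default 40).
#' @param seed integer seed.
#' @return An object of class `split_plan`: a list of runs, each with
#'   `train_pd`, `train_hc`, `test` id vectors.
#' @export
make_splits <- function(subjects, n_train_pd, n_train_hc, n_runs = 40,
                        seed = 1) {
  pd_ids <- subjects$subject_id[subjects$label == "PD"]
  hc_ids <- subjects$subject_id[subjects$label == "HC"]
  if (n_train_pd != n_train_hc)
    stop_pdvoice("training groups must be class-balanced ",
                 "(n_train_pd == n_train_hc)")
  if (n_train_pd >= length(pd_ids) || n_train_hc >= length(hc_ids))
    stop_pdvoice("training counts leave no test subjects in one class")
  if (n_train_pd < 1 || n_train_hc < 1)
    stop_pdvoice("training groups must be non-empty")
  runs <- with_seed(child_seed(seed, "splits"), {
    lapply(seq_len(n_runs), function(k) {
      train_pd <- sample(pd_ids, n_train_pd)
      train_hc <- sample(hc_ids, n_train_hc)
      list(train_pd = train_pd, train_hc = train_hc,
           test = setdiff(subjects$subject_id, c(train_pd, train_hc)))
    })
  })
  structure(list(runs = runs, n_runs = n_runs,
                 n_train_pd = n_train_pd, n_train_hc = n_train_hc,
                 seed = seed), class = "split_plan")
}

#' Expected number of times each subject is tested under a plan
#'
#' @param splits a [make_splits()] plan.
#' @param subjects the subject data frame the plan was built from.
#' @return Named numeric vector of per-class expected test counts.
#' @export
expected_test_counts <- function(splits, subjects) {
  n_pd <- sum(subjects$label == "PD")
  n_hc <- sum(subjects$label == "HC")
  c(PD = splits$n_runs * (1 - splits$n_train_pd / n_pd),
    HC = splits$n_runs * (1 - splits$n_train_hc / n_hc))
}

#' Equal error rate of labeled scores
#'
#' Sweeps the decision threshold over the observed scores (predict PD
#' when `score >= threshold`) and returns the error rate at which the
#' false-positive ratio equals the false-negative ratio, with linear
#' interpolation between adjacent sweep points where the two cross.
#'
#' @param scores numeric classification scores (higher = more PD-like).
#' @param labels `"PD"`/`"HC"` label per score (both must occur).
#' @return A list with `eer` and the crossing `threshold`.
#' @export
compute_eer <- function(scores, labels) {
  sweep <- det_sweep(scores, labels)
  eer_from_sweep(sweep)
}

det_sweep <- function(scores, labels) {
  pos <- scores[labels == "PD"]
  neg <- scores[labels == "HC"]
  if (length(pos) == 0 || length(neg) == 0)
    stop_pdvoice("both classes are required to compute error rates")
  ts <- c(-Inf, sort(unique(scores)), Inf)
  fpr <- vapply(ts, function(t) mean(neg >= t), numeric(1))
  fnr <- vapply(ts, function(t) mean(pos < t), numeric(1))
  list(thresholds = ts, fpr = fpr, fnr = fnr)
}

eer_from_sweep <- function(sweep) {
  fpr <- sweep$fpr; fnr <- sweep$fnr
  k <- which(fnr >= fpr)[1]
  if (fnr[k] == fpr[k] || k == 1L)
    return(list(eer = fpr[k], threshold = sweep$thresholds[k]))
  f1 <- fpr[k - 1]; g1 <- fnr[k - 1]
  f2 <- fpr[k]; g2 <- fnr[k]
  alpha <- (f1 - g1) / ((f1 - g1) + (g2 - f2))
  thr <- if (is.finite(sweep$thresholds[k]))
    sweep$thresholds[k] else sweep$thresholds[k - 1]
  list(eer = f1 + alpha * (f2 - f1), threshold = thr)
}

#' Detection error tradeoff curve
#'
#' Full (false-positive ratio, false-negative ratio) sweep over the score
#' thresholds, with the equal error rate attached.
#'
#' @inheritParams compute_eer
#' @return An object of class `det_curve` with `fpr`, `fnr`,
#'   `thresholds`, `eer`.
#' @export
det_curve <- function(scores, labels) {
  sweep <- det_sweep(scores, labels)
  e <- eer_from_sweep(sweep)
  structure(list(fpr = sweep$fpr, fnr = sweep$fnr,
                 thresholds = sweep$thresholds, eer = e$eer),
            class = "det_curve")
}

#' @export
print.det_curve <- function(x, ...) {
  cat(sprintf("<det_curve: %d points, EER %.3f>\n", length(x$fpr), x$eer))
  invisible(x)
}

#' Average DET curves and the EER of the averaged curve
#'
#' Resamples each curve's FNR on a common FPR grid in the probit
#' (normal-deviate) domain, averages pointwise, and computes the equal
#' error rate of the averaged curve -- the single-model performance
#' estimate of a repeated random subsampling cross-validation.
#'
#' @param curves list of [det_curve()] objects.
#' @param grid_n number of FPR grid points.
#' @param eps probability clamp for the probit transform.
#' @return A `det_curve` on the common grid with the averaged-curve EER.
#' @export
average_det <- function(curves, grid_n = 201, eps = 1e-4) {
  stopifnot(length(curves) >= 1)
  fpr_grid <- stats::pnorm(seq(stats::qnorm(eps), stats::qnorm(1 - eps),
                               length.out = grid_n))
  probit <- function(p) stats::qnorm(pmin(pmax(p, eps), 1 - eps))
  fnr_mat <- vapply(curves, function(cv) {
    o <- order(cv$fpr)
    x <- probit(cv$fpr[o]); y <- probit(cv$fnr[o])
    stats::approx(x, y, xout = stats::qnorm(fpr_grid), ties = mean,
                  rule = 2)$y
  }, numeric(grid_n))
  fnr_avg <- stats::pnorm(rowMeans(fnr_mat))
  ## EER: crossing of the averaged FNR with the FPR grid diagonal
  dd <- fnr_avg - fpr_grid
  k <- which(dd >= 0)
  eer <- if (length(k) == 0) {
    min(fpr_grid)
  } else {
    k <- max(k)  # fnr decreases with fpr: last grid point above diagonal
    if (k == grid_n || dd[k] == 0) {
      fpr_grid[k]
    } else {
      a <- dd[k] / (dd[k] - dd[k + 1])
      fpr_grid[k] + a * (fpr_grid[k + 1] - fpr_grid[k])
    }
  }
  structure(list(fpr = fpr_grid, fnr = fnr_avg, thresholds = NULL,
                 eer = eer), class = "det_curve")
}

#' Run the repeated random subsampling ensemble
#'
#' For each run of the plan, trains the pipeline on that run's
#' class-balanced training groups, scores every test subject, and finally
#' aggregates each subject's out-of-bag scores into a mean score
#' `Lambda_j`.  Per-run EERs and DET curves are logged for the
#' single-model comparison.
#'
#' @param pipeline a list with functions `train(train_pd, train_hc,
#'   run_seed)` returning a fitted run model, and
#'   `score(model, subject_id)` returning a score in (0, 1) or `NA` for
#'   an untestable subject (recorded and skipped in that subject's mean).
#' @param splits a [make_splits()] plan.
#' @param subjects the labeled subject data frame.
#' @param seed base seed for per-run training randomness.
#' @return An object of class `score_table`: `entries` (subject, run,
#'   score), `aggregated` (subject, label, score, n_tested), `per_run_eer`,
#'   `per_run_curves`, `aggregated_eer`, `single_model_eer` (EER of the
#'   probit-averaged DET curve), and `skipped`.
#' @export
run_ensemble <- function(pipeline, splits, subjects, seed = 1) {
  entries <- list()
  per_run_eer <- numeric(0)
  per_run_curves <- list()
  skipped <- list()
  label_of <- stats::setNames(subjects$label, subjects$subject_id)
  for (k in seq_along(splits$runs)) {
    run <- splits$runs[[k]]
    model <- pipeline$train(run$train_pd, run$train_hc,
                            run_seed = child_seed(seed, "run", k))
    scores <- vapply(run$test, function(sid) pipeline$score(model, sid),
                     numeric(1))
    ok <- !is.na(scores)
    if (any(!ok))
      skipped[[length(skipped) + 1L]] <- data.frame(
        run_id = k, subject_id = run$test[!ok])
    entries[[k]] <- data.frame(subject_id = run$test[ok], run_id = k,
                               score = scores[ok])
    run_labels <- label_of[run$test[ok]]
    if (any(run_labels == "PD") && any(run_labels == "HC")) {
      cv <- det_curve(scores[ok], run_labels)
      per_run_eer[k] <- cv$eer
      per_run_curves[[k]] <- cv
    } else {
      per_run_eer[k] <- NA_real_
    }
  }
  entries <- do.call(rbind, entries)
  agg <- stats::aggregate(score ~ subject_id, data = entries, FUN = mean)
  n_tested <- stats::aggregate(score ~ subject_id, data = entries,
                               FUN = length)
  agg$label <- label_of[agg$subject_id]
  agg$n_tested <- n_tested$score
  aggregated_eer <- compute_eer(agg$score, agg$label)$eer
  valid_curves <- per_run_curves[!vapply(per_run_curves, is.null,
                                         logical(1))]
  single_model_eer <- if (length(valid_curves))
    average_det(valid_curves)$eer else NA_real_
  structure(list(entries = entries, aggregated = agg,
                 per_run_eer = per_run_eer, per_run_curves = per_run_curves,
                 aggregated_eer = aggregated_eer,
                 single_model_eer = single_model_eer,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                 else NULL),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf(paste0("<score_table: %d runs, %d subjects, aggregated EER ",
                     "%.3f, mean per-run EER %.3f>\n"),
              max(x$entries$run_id), nrow(x$aggregated), x$aggregated_eer,
              mean(x$per_run_eer, na.rm = TRUE)))
  invisible(x)
}

#' Export a score table's entries and aggregation as TSV
#'
#' @param table a [run_ensemble()] `score_table`.
#' @param dir output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_score_table <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "scores.tsv")
  p2 <- file.path(dir, "aggregated.tsv")
  utils::write.table(table$entries, p1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$aggregated, p2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2))
}
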