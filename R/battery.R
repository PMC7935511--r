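#' Standard synthetic evaluation battery
#'
#' The package's fixed end-to-end validation setup: a single-gender
#' high-quality cohort of 12 PD and 12 HC speakers (2 sessions, 6 s of
#' free speech each), evaluated with the repeated random subsampling
#' ensemble (12 runs, 8+8 class-balanced training subjects) for both
#' branches -- the MFCC-GMM baseline (8 components at this data scale)
#' and the x-vector branch with the LDA + cosine back-end (desk-scale
#' TDNN).  One cohort is generated per effect size and shared by both
#' branches.
#'
#' @param seed battery seed (cohort, splits, and training all derive from
#'   it).
#' @param effect_sizes class separations to evaluate.
#' @param branches subset of `c("gmm", "xvector")`.
#' @param backend x-vector back-end.
#' @param n_runs ensemble runs per cell.
#' @return A data frame with one row per (branch, effect size):
#'   `aggregated_eer`, `mean_run_eer`, and `single_model_eer`.
#' @export
standard_battery <- function(seed = 1, effect_sizes = c(0, 1, 3),
                             branches = c("gmm", "xvector"),
                             backend = "lda_cosine", n_runs = 12) {
  rows <- list()
  for (es in effect_sizes) {
    cc <- synth_cohort_config(n_pd = 12, n_hc = 12,
                              sessions_per_subject = 2,
                              task_duration_s = 6, effect_size = es,
                              seed = child_seed(seed, "cohort", es))
    cohort <- generate_cohort(cc)
    splits <- make_splits(cohort$subjects, 8, 8, n_runs = n_runs,
                          seed = child_seed(seed, "splits", es))
    for (br in branches) {
      pipeline <- if (br == "gmm") {
        make_gmm_pipeline(cohort, n_components = 8)
      } else {
        make_xvector_pipeline(cohort, backend = backend, epochs = 10,
                              seed = child_seed(seed, "xvec", es))
      }
      tab <- run_ensemble(pipeline, splits, cohort$subjects,
                          seed = child_seed(seed, "ens", es, br))
      rows[[length(rows) + 1L]] <- data.frame(
        branch = br, effect_size = es,
        aggregated_eer = tab$aggregated_eer,
        mean_run_eer = mean(tab$per_run_eer, na.rm = TRUE),
        single_model_eer = tab$single_model_eer)
    }
  }
  do.call(rbind, rows)
}
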