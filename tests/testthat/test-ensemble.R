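fake_subjects <- function(n_pd, n_hc) {
  data.frame(
    subject_id = c(sprintf("PD%03d", seq_len(n_pd)),
                   sprintf("HC%03d", seq_len(n_hc))),
    label = c(rep("PD", n_pd), rep("HC", n_hc)))
}

test_that("split plans are balanced, disjoint, exhaustive and seeded", {
  subjects <- fake_subjects(74, 48)   # the male high-quality cohort sizes
  plan <- make_splits(subjects, 36, 36, seed = 3)
  expect_equal(plan$n_runs, 40)       # default run count
  for (run in plan$runs) {
    expect_length(intersect(run$train_pd, run$train_hc), 0)
    expect_length(run$test, 74 + 48 - 72)
    expect_length(intersect(run$test, c(run$train_pd, run$train_hc)), 0)
    ## test group composition: all remaining subjects, i.e. 38 PD / 12 HC
    test_labels <- subjects$label[match(run$test, subjects$subject_id)]
    expect_equal(sum(test_labels == "PD"), 38)
    expect_equal(sum(test_labels == "HC"), 12)
  }
  expect_identical(make_splits(subjects, 36, 36, seed = 3), plan)
  expect_false(identical(make_splits(subjects, 36, 36, seed = 4), plan))
  counts <- expected_test_counts(plan, subjects)
  expect_equal(unname(counts["PD"]), 40 * 38 / 74, tolerance = 1e-12)
})

test_that("infeasible or unbalanced split requests are rejected", {
  subjects <- fake_subjects(10, 10)
  expect_error(make_splits(subjects, 10, 10), "no test subjects")
  expect_error(make_splits(subjects, 6, 5), "class-balanced")
  expect_error(make_splits(subjects, 0, 0), "non-empty")
})

test_that("EER matches hand-computed examples and conventions", {
  e <- compute_eer(c(0.8, 0.9, 0.1, 0.2), rep(c("PD", "HC"), each = 2))
  expect_equal(e$eer, 0)
  e2 <- compute_eer(c(0.4, 0.6, 0.8, 0.1, 0.2, 0.5),
                    rep(c("PD", "HC"), each = 3))
  expect_equal(e2$eer, 1 / 3)
  ## all-tied scores: 0.5 by the crossing convention
  expect_equal(compute_eer(rep(0.5, 8), rep(c("PD", "HC"), 4))$eer, 0.5)
  expect_error(compute_eer(c(0.1, 0.9), c("PD", "PD")), "both classes")
  ## random labels on random scores: ~0.5
  n <- 10000
  sc <- withr::with_seed(51, stats::rnorm(n))
  lb <- withr::with_seed(52, sample(rep(c("PD", "HC"), n / 2)))
  expect_equal(compute_eer(sc, lb)$eer, 0.5, tolerance = 0.02)
})

test_that("EER equals the exhaustive brute-force sweep on random cases", {
  withr::with_seed(53, {
    for (i in 1:60) {
      n_pos <- sample(2:25, 1); n_neg <- sample(2:25, 1)
      sc <- c(stats::rnorm(n_pos, 0.3), stats::rnorm(n_neg))
      ## duplicate some scores to exercise tie handling
      if (i %% 3 == 0) sc <- round(sc, 1)
      lb <- c(rep("PD", n_pos), rep("HC", n_neg))
      expect_equal(compute_eer(sc, lb)$eer, brute_force_eer(sc, lb),
                   tolerance = 1e-12)
    }
  })
})

test_that("DET curves are monotone, consistent, and symmetric when due", {
  sc <- withr::with_seed(54, c(stats::rnorm(200, 1), stats::rnorm(200, -1)))
  lb <- rep(c("PD", "HC"), each = 200)
  cv <- det_curve(sc, lb)
  expect_true(all(diff(cv$fpr) <= 0))   # threshold ascending
  expect_true(all(diff(cv$fnr) >= 0))
  expect_equal(cv$eer, compute_eer(sc, lb)$eer)
  ## perfect separation touches the origin
  cvp <- det_curve(c(0.9, 0.8, 0.1, 0.2), rep(c("PD", "HC"), each = 2))
  expect_true(any(cvp$fpr == 0 & cvp$fnr == 0))
  ## symmetric score distributions: swapping classes mirrors the curve
  eer_fwd <- compute_eer(sc, lb)$eer
  eer_rev <- compute_eer(-sc, ifelse(lb == "PD", "HC", "PD"))$eer
  expect_equal(eer_fwd, eer_rev, tolerance = 1e-12)
})

test_that("DET averaging interpolates between nearby curves", {
  mk <- function(mu, seed) {
    sc <- withr::with_seed(seed, c(stats::rnorm(400, mu),
                                   stats::rnorm(400, 0)))
    det_curve(sc, rep(c("PD", "HC"), each = 400))
  }
  c1 <- mk(1.0, 61); c2 <- mk(1.2, 62)
  avg <- average_det(list(c1, c2))
  ## identical curves average to themselves
  same <- average_det(list(c1, c1))
  expect_equal(same$eer, average_det(list(c1))$eer, tolerance = 1e-12)
  ## the average lies pointwise between the two inputs
  both <- vapply(list(c1, c2), function(cv) {
    o <- order(cv$fpr)
    stats::approx(cv$fpr[o], cv$fnr[o], xout = avg$fpr, ties = mean,
                  rule = 2)$y
  }, numeric(length(avg$fpr)))
  lo <- pmin(both[, 1], both[, 2]); hi <- pmax(both[, 1], both[, 2])
  inner <- avg$fpr > 0.02 & avg$fpr < 0.98
  expect_true(all(avg$fnr[inner] >= lo[inner] - 0.02 &
                    avg$fnr[inner] <= hi[inner] + 0.02))
  ## averaged-curve EER close to the mean of the individual EERs
  expect_equal(avg$eer, mean(c(c1$eer, c2$eer)), tolerance = 0.02)
})

test_that("the ensemble aggregates only out-of-bag scores", {
  subjects <- fake_subjects(8, 8)
  true_scores <- stats::setNames(
    ifelse(subjects$label == "PD", 0.7, 0.3) +
      withr::with_seed(55, stats::rnorm(16, 0, 0.05)),
    subjects$subject_id)
  seen_train <- list()
  pipeline <- list(
    train = function(train_pd, train_hc, run_seed) {
      model <- list(train = c(train_pd, train_hc))
      seen_train[[length(seen_train) + 1L]] <<- model$train
      model
    },
    score = function(model, sid) {
      expect_false(sid %in% model$train)  # structural out-of-bag purity
      true_scores[[sid]]
    })
  plan <- make_splits(subjects, 5, 5, n_runs = 10, seed = 8)
  tab <- run_ensemble(pipeline, plan, subjects, seed = 1)
  ## every (subject, run) entry was out of that run's training groups
  for (i in seq_len(nrow(tab$entries))) {
    run <- plan$runs[[tab$entries$run_id[i]]]
    expect_false(tab$entries$subject_id[i] %in%
                   c(run$train_pd, run$train_hc))
  }
  expect_true(all(tab$aggregated$score > 0 & tab$aggregated$score < 1))
  expect_equal(tab$aggregated_eer, 0)  # well-separated constructed scores
})

test_that("constant and degenerate pipelines follow the conventions", {
  subjects <- fake_subjects(6, 6)
  plan <- make_splits(subjects, 4, 4, n_runs = 6, seed = 9)
  flat <- list(train = function(...) NULL,
               score = function(model, sid) 0.5)
  tab <- run_ensemble(flat, plan, subjects)
  expect_true(all(tab$aggregated$score == 0.5))
  expect_equal(tab$aggregated_eer, 0.5)
  ## an untestable subject is skipped and recorded
  skipping <- list(
    train = function(...) NULL,
    score = function(model, sid) {
      if (sid == "PD001") NA_real_ else stats::runif(1, 0.4, 0.6)
    })
  tab2 <- run_ensemble(skipping, plan, subjects, seed = 2)
  expect_false("PD001" %in% tab2$aggregated$subject_id)
  expect_true(all(tab2$skipped$subject_id == "PD001"))
})

test_that("score tables export to TSV", {
  subjects <- fake_subjects(4, 4)
  plan <- make_splits(subjects, 2, 2, n_runs = 3, seed = 10)
  pipeline <- list(train = function(...) NULL,
                   score = function(model, sid) stats::runif(1))
  tab <- run_ensemble(pipeline, plan, subjects, seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_score_table(tab, dir)
  expect_true(all(file.exists(file.path(dir, c("scores.tsv",
                                               "aggregated.tsv")))))
  back <- utils::read.delim(file.path(dir, "scores.tsv"))
  expect_equal(nrow(back), nrow(tab$entries))
})
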