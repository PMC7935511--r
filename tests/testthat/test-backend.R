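test_that("class references are per-class means with degeneracy flags", {
  x <- rbind(c(1, 0), c(0, 1), c(3, 3), c(5, 5))
  labels <- c("PD", "PD", "HC", "HC")
  refs <- compute_references(x, labels)
  expect_equal(refs$xvec_pd, c(0.5, 0.5))
  expect_equal(refs$xvec_hc, c(4, 4))
  ## mean of one and duplication invariance
  r1 <- compute_references(x[c(1, 3), ], c("PD", "HC"))
  expect_equal(r1$xvec_pd, x[1, ])
  rdup <- compute_references(rbind(x, x), rep(labels, 2))
  expect_equal(rdup$xvec_pd, refs$xvec_pd)
  ## symmetric class collapses to the zero vector and is flagged
  rsym <- compute_references(rbind(c(1, 1), c(-1, -1), c(2, 0), c(2, 0)),
                             c("PD", "PD", "HC", "HC"))
  expect_true(rsym$degenerate)
  expect_error(compute_references(x, rep("PD", 4)), "HC")
})

test_that("cosine similarity obeys its identities and rejects zeros", {
  v <- c(1, 2, -3)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, -v), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(v, 7 * v), 1)  # scale invariance
  expect_error(cosine_similarity(v, numeric(3)), "zero vector")
})

test_that("LDA finds the Fisher direction and handles degenerate scatter", {
  skip_if_not_installed("MASS")
  W <- matrix(c(2, 0.7, 0.7, 1), 2)
  x <- withr::with_seed(21, rbind(MASS::mvrnorm(300, c(0, 0), W),
                                  MASS::mvrnorm(300, c(2, 1), W)))
  labels <- rep(c("HC", "PD"), each = 300)
  ld <- fit_lda(x, labels, dim_out = 2)
  ## closed-form Fisher direction from the sample within-class scatter
  sw <- (crossprod(scale(x[1:300, ], scale = FALSE)) +
           crossprod(scale(x[301:600, ], scale = FALSE))) / 600
  fisher <- solve(sw, colMeans(x[301:600, ]) - colMeans(x[1:300, ]))
  cs <- abs(sum(ld$projection[, 1] * fisher)) /
    sqrt(sum(ld$projection[, 1]^2) * sum(fisher^2))
  expect_gt(cs, 0.999)
  ## agreement with an independent implementation
  mass_dir <- MASS::lda(x, grouping = labels)$scaling[, 1]
  cs2 <- abs(sum(ld$projection[, 1] * mass_dir)) /
    sqrt(sum(ld$projection[, 1]^2) * sum(mass_dir^2))
  expect_gt(cs2, 0.999)
  ## identical class means: no between-class signal
  x0 <- withr::with_seed(22, rbind(MASS::mvrnorm(100, c(0, 0), W),
                                   MASS::mvrnorm(100, c(0, 0), W)))
  ld0 <- fit_lda(x0, rep(c("HC", "PD"), each = 100), dim_out = 2)
  expect_lt(ld0$eigenvalues[1], 0.1)
  ## pre-whitened data with axis-aligned means projects axis-aligned
  xw <- withr::with_seed(23, rbind(
    matrix(stats::rnorm(400), 200, 2),
    cbind(stats::rnorm(200, 4), stats::rnorm(200))))
  ldw <- fit_lda(xw, labels[c(1:200, 301:500)], dim_out = 1)
  dir <- ldw$projection[, 1] / sqrt(sum(ldw$projection[, 1]^2))
  expect_gt(abs(dir[1]), 0.99)
  expect_error(fit_lda(x, rep("PD", 600)), "2 classes")
})

test_that("PLDA EM recovers the generative covariance structure", {
  pop <- generate_plda_population(1000, 5, dim = 8, F_rank = 2, G_rank = 3,
                                  seed = 5)
  m <- fit_plda(pop$x, pop$labels, rank_F = 2, rank_G = 3, iters = 40,
                seed = 2)
  expect_true(all(diff(m$loglik) > -1e-6))
  est <- tcrossprod(m$F) + tcrossprod(m$G) + diag(m$Sigma, 8)
  truth <- tcrossprod(pop$F) + tcrossprod(pop$G) + diag(pop$Sigma, 8)
  expect_lt(norm(est - truth, "F") / norm(truth, "F"), 0.10)
  expect_error(fit_plda(pop$x, pop$labels, rank_F = 5, rank_G = 5), "exceed")
})

test_that("PLDA scoring matches a direct Gaussian-density oracle", {
  pop <- generate_plda_population(20, 30, dim = 3, F_rank = 1, G_rank = 1,
                                  seed = 6)
  m <- fit_plda(pop$x, pop$labels, rank_F = 1, rank_G = 1, iters = 20)
  x1 <- c(0.3, -0.5, 1); x2 <- c(-1, 0.2, 0.4)
  ## symmetry
  expect_equal(plda_llr(m, x1, x2), plda_llr(m, x2, x1),
               tolerance = 1e-10)
  ## brute-force two-covariance oracle built from scratch in the test
  B <- tcrossprod(m$F); W <- tcrossprod(m$G) + diag(m$Sigma, 3)
  joint <- rbind(cbind(B + W, B), cbind(B, B + W))
  oracle <- naive_dmvnorm_log(c(x1, x2), rep(m$mu, 2), joint) -
    naive_dmvnorm_log(x1, m$mu, B + W) - naive_dmvnorm_log(x2, m$mu, B + W)
  expect_equal(plda_llr(m, x1, x2), oracle, tolerance = 1e-8)
  ## value at the mean equals the closed form there
  expect_equal(plda_llr(m, m$mu, m$mu),
               naive_dmvnorm_log(rep(m$mu, 2), rep(m$mu, 2), joint) -
                 2 * naive_dmvnorm_log(m$mu, m$mu, B + W),
               tolerance = 1e-8)
  ## same-class pairs outscore different-class pairs on average
  same <- c(); diff_ <- c()
  idx <- withr::with_seed(31, replicate(150, sample(nrow(pop$x), 2)))
  for (j in seq_len(ncol(idx))) {
    llr <- plda_llr(m, pop$x[idx[1, j], ], pop$x[idx[2, j], ])
    if (pop$labels[idx[1, j]] == pop$labels[idx[2, j]]) {
      same <- c(same, llr)
    } else {
      diff_ <- c(diff_, llr)
    }
  }
  expect_gt(mean(same), mean(diff_))
  expect_error(plda_llr(m, c(1, 2), x2), "dimension")
})

test_that("a rank-zero class subspace carries no class signal", {
  pop <- generate_plda_population(4, 50, dim = 4, F_rank = 1, G_rank = 2,
                                  seed = 8)
  m0 <- fit_plda(pop$x, pop$labels, rank_F = 0, rank_G = 3, iters = 15)
  llrs <- withr::with_seed(32, vapply(1:50, function(i) {
    a <- sample(nrow(pop$x), 2)
    plda_llr(m0, pop$x[a[1], ], pop$x[a[2], ])
  }, numeric(1)))
  expect_lt(max(abs(llrs)), 1e-8)  # B = 0 makes every pair equivalent
})

test_that("x-vector scoring composes similarity, sigmoid and symmetry", {
  refs <- compute_references(rbind(c(2, 0), c(0, 2)), c("PD", "HC"))
  ## equidistant vector scores exactly 0.5
  expect_equal(score_xvector(refs, c(1, 1), method = "cosine"), 0.5)
  ## the PD reference itself scores above 0.5
  s <- score_xvector(refs, c(2, 0), method = "cosine")
  expect_gt(s, 0.5)
  ## swapping references flips the score
  swapped <- compute_references(rbind(c(2, 0), c(0, 2)), c("HC", "PD"))
  expect_equal(score_xvector(swapped, c(2, 0), method = "cosine"), 1 - s,
               tolerance = 1e-12)
  expect_error(score_xvector(refs, c(2, 0), method = "lda_cosine"),
               "lda")
  expect_error(score_xvector(refs, c(2, 0), method = "plda"), "plda")
  ## subject aggregation
  expect_equal(score_subject(c(0.2, 0.8)), 0.5)
  expect_equal(score_subject(0.7), 0.7)
  expect_equal(score_subject(c(0.1, 0.5, 0.9)),
               score_subject(c(0.9, 0.1, 0.5)))
  expect_error(score_subject(numeric(0)), "no segment")
})

test_that("LDA-reduced scoring pipeline separates a separable population", {
  pop <- generate_plda_population(2, 80, dim = 10, F_rank = 1, G_rank = 3,
                                  seed = 12,
                                  F = matrix(c(4, rep(0, 9)), 10))
  labels <- ifelse(pop$labels == 1, "PD", "HC")
  lda <- fit_lda(pop$x, labels, dim_out = 4)
  pl <- fit_plda(lda_project(lda, pop$x), labels, rank_F = 1, rank_G = 3,
                 iters = 20)
  refs <- compute_references(pop$x, labels)
  scores <- vapply(seq_len(nrow(pop$x)), function(i) {
    score_xvector(refs, pop$x[i, ], method = "plda", lda = lda, plda = pl)
  }, numeric(1))
  expect_lt(compute_eer(scores, labels)$eer, 0.1)
})
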