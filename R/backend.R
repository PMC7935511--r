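#' Class-mean x-vector references
#'
#' Averages the training x-vectors within each class to obtain one
#' reference x-vector per class (PD and HC).
#'
#' @param xvectors numeric matrix (rows = x-vectors) or list of vectors.
#' @param labels class label per row, containing `"PD"` and `"HC"`.
#' @param gender optional gender tag carried in the references.
#' @return An object of class `class_references` with `xvec_pd`,
#'   `xvec_hc`; a zero-norm reference is flagged `degenerate`.
#' @export
compute_references <- function(xvectors, labels, gender = NA_character_) {
  x <- as_xvec_matrix(xvectors)
  stopifnot(nrow(x) == length(labels))
  if (!any(labels == "PD") || !any(labels == "HC"))
    stop_pdvoice("both PD and HC x-vectors are required")
  ref <- function(cls) colMeans(x[labels == cls, , drop = FALSE])
  out <- structure(list(xvec_pd = ref("PD"), xvec_hc = ref("HC"),
                        gender = gender), class = "class_references")
  out$degenerate <- sqrt(sum(out$xvec_pd^2)) < 1e-12 ||
    sqrt(sum(out$xvec_hc^2)) < 1e-12
  out
}

as_xvec_matrix <- function(xvectors) {
  if (is.matrix(xvectors)) return(xvectors)
  do.call(rbind, lapply(xvectors, as.numeric))
}

#' Cosine similarity between two vectors
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return The cosine of the angle between `a` and `b`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop_pdvoice("cosine similarity is undefined for a zero vector")
  sum(a * b) / (na * nb)
}

#' Fit a linear discriminant projection
#'
#' Solves the generalized eigenproblem of between-class versus
#' within-class scatter (within-class whitening followed by between-class
#' eigendecomposition), keeping the leading `dim_out` directions.  The
#' within-class scatter is ridge-regularized by `ridge * trace(Sw)/dim`
#' to handle singularity.
#'
#' @param xvectors matrix or list of training vectors.
#' @param labels class label per vector (>= 2 classes, >= 2 per class).
#' @param dim_out projected dimension (default 2, the two-dimensional
#'   discriminant space used for cosine scoring).
#' @param ridge ridge fraction for the within-class scatter.
#' @return An object of class `lda_transform`: `projection`
#'   (dim_in x dim_out), `class_means` (projected), `eigenvalues`.
#' @export
fit_lda <- function(xvectors, labels, dim_out = 2, ridge = 1e-6) {
  x <- as_xvec_matrix(xvectors)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop_pdvoice("LDA needs >= 2 classes")
  if (any(table(labels) < 2)) stop_pdvoice("LDA needs >= 2 vectors per class")
  d <- ncol(x)
  mu <- colMeans(x)
  sw <- matrix(0, d, d)
  sb <- matrix(0, d, d)
  for (cls in classes) {
    xc <- x[labels == cls, , drop = FALSE]
    mc <- colMeans(xc)
    cen <- sweep(xc, 2, mc)
    sw <- sw + crossprod(cen)
    sb <- sb + nrow(xc) * tcrossprod(mc - mu)
  }
  sw <- sw / nrow(x)
  sb <- sb / nrow(x)
  sw <- sw + diag(ridge * sum(diag(sw)) / d + 1e-12, d)
  ## simultaneous diagonalization: whiten Sw, then eigendecompose Sb
  ew <- eigen(sw, symmetric = TRUE)
  whiten <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, 1e-12)), d)
  m <- crossprod(whiten, sb) %*% whiten
  eb <- eigen((m + t(m)) / 2, symmetric = TRUE)
  dim_out <- min(dim_out, d)
  projection <- whiten %*% eb$vectors[, seq_len(dim_out), drop = FALSE]
  proj_means <- lapply(classes, function(cls) {
    as.numeric(colMeans(x[labels == cls, , drop = FALSE] %*% projection))
  })
  names(proj_means) <- classes
  structure(list(projection = projection, class_means = proj_means,
                 eigenvalues = eb$values[seq_len(dim_out)],
                 dim_out = dim_out, global_mean = mu),
            class = "lda_transform")
}

#' Project vectors through an LDA transform
#'
#' @param transform a [fit_lda()] result.
#' @param x a vector or matrix of row vectors.
#' @return The projected vector/matrix.
#' @export
lda_project <- function(transform, x) {
  if (is.matrix(x)) x %*% transform$projection
  else as.numeric(x %*% transform$projection)
}

#' Fit a PLDA model by EM
#'
#' Fits the probabilistic linear discriminant analysis generative model
#' `x = mu + F h + G w + eps`, `eps ~ N(0, Sigma)` with diagonal `Sigma`,
#' class latent `h` (shared within a class) and sample latent `w`, by
#' expectation-maximization with exact Gaussian posteriors.  The training
#' marginal log-likelihood is non-decreasing (asserted) and recorded.
#'
#' @param xvectors matrix or list of training vectors (typically already
#'   LDA-reduced).
#' @param labels class label per vector (>= 2 classes).
#' @param rank_F,rank_G ranks of the between-class and within-class
#'   loadings; `rank_F + rank_G <= dim`.
#' @param iters number of EM iterations.
#' @param seed initialization seed.
#' @return An object of class `plda_model`: `mu`, `F`, `G`, `Sigma`
#'   (diagonal vector), and the `loglik` trace.
#' @export
fit_plda <- function(xvectors, labels, rank_F = 1, rank_G = NULL,
                     iters = 30, seed = 1) {
  x <- as_xvec_matrix(xvectors)
  d <- ncol(x)
  if (is.null(rank_G)) rank_G <- d - rank_F
  if (rank_F + rank_G > d) stop_pdvoice("rank_F + rank_G must not exceed dim")
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) < 2) stop_pdvoice("PLDA needs >= 2 classes")
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  tot_var <- pmax(apply(xc, 2, stats::var), 1e-8)
  ## moment-based initialization: within-class covariance for (G, Sigma),
  ## bias-corrected covariance of class means for F; random inits are
  ## prone to poor local optima of the EM objective
  sw <- matrix(0, d, d)
  cm <- matrix(0, length(classes), d)
  for (ci in seq_along(classes)) {
    yc <- x[labels == classes[ci], , drop = FALSE]
    cm[ci, ] <- colMeans(yc)
    sw <- sw + crossprod(sweep(yc, 2, cm[ci, ]))
  }
  sw <- sw / nrow(x) + diag(1e-8, d)
  nbar <- nrow(x) / length(classes)
  sb <- stats::cov(cm) * (length(classes) - 1) / length(classes) - sw / nbar
  sb <- (sb + t(sb)) / 2
  loading_init <- function(S, rank) {
    if (rank == 0) return(matrix(0, d, 0))
    e <- eigen(S, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(rank)], 1e-6 * mean(tot_var))
    e$vectors[, seq_len(rank), drop = FALSE] %*% diag(sqrt(lam), rank)
  }
  F <- loading_init(sb, rank_F)
  G <- loading_init(sw * 0.5, rank_G)
  Sigma <- pmax(diag(sw) * 0.5, 1e-8)
  with_seed(child_seed(seed, "plda_init"), {
    ## tiny seeded jitter breaks exact symmetries without moving the init
    if (rank_F > 0) F <- F + stats::rnorm(length(F), sd = 1e-6)
    if (rank_G > 0) G <- G + stats::rnorm(length(G), sd = 1e-6)
  })
  by_class <- split(seq_len(nrow(x)), labels)
  loglik <- numeric(0)
  for (it in seq_len(iters)) {
    W <- tcrossprod(G) + diag(Sigma, d)        # within-class covariance
    Wi <- solve(W)
    FtWi <- crossprod(F, Wi)                   # rank_F x d
    Minv_w <- NULL
    if (rank_G > 0) {
      GtSi <- t(G) / rep(Sigma, each = rank_G) # rank_G x d
      Minv_w <- solve(diag(1, rank_G) + GtSi %*% G)
    }
    ll <- 0
    sum_yz <- matrix(0, d, rank_F + rank_G)
    sum_zz <- matrix(0, rank_F + rank_G, rank_F + rank_G)
    sum_res <- numeric(d)
    n_tot <- 0
    for (idx in by_class) {
      y <- xc[idx, , drop = FALSE]
      ni <- nrow(y)
      S <- colSums(y)
      ## posterior of the class latent h with w marginalized out
      if (rank_F > 0) {
        Ph <- diag(1, rank_F) + ni * (FtWi %*% F)
        Ch <- solve(Ph)
        Eh <- as.numeric(Ch %*% (FtWi %*% S))
        ld_Ph <- as.numeric(determinant(Ph)$modulus)
        b <- as.numeric(FtWi %*% S)
        b_term <- 0.5 * sum(b * as.numeric(Ch %*% b))
      } else {
        Ch <- matrix(0, 0, 0)
        Eh <- numeric(0)
        ld_Ph <- 0
        b_term <- 0
      }
      ## marginal log-likelihood of this class's block
      quad <- rowSums((y %*% Wi) * y)
      ll <- ll - 0.5 * sum(quad) - 0.5 * ni * determinant(W)$modulus -
        0.5 * ni * d * log(2 * pi) - 0.5 * ld_Ph + b_term
      ## per-sample posterior of w given h (chain rule, exact moments)
      r <- sweep(y, 2, as.numeric(F %*% Eh))   # residuals at E[h]
      if (rank_G > 0) {
        Ew <- r %*% t(GtSi) %*% Minv_w          # ni x rank_G
        A <- -Minv_w %*% GtSi %*% F             # d(E[w])/d(h) sensitivity
        Cw_extra <- A %*% Ch %*% t(A)
        Ehw <- Ch %*% t(A)                      # Cov(h, w_j | data)
      } else {
        Ew <- matrix(0, ni, 0)
        Cw_extra <- matrix(0, 0, 0)
        Ehw <- matrix(0, rank_F, 0)
      }
      ## accumulate sufficient statistics for the joint [F G] M-step
      Ez <- cbind(matrix(Eh, ni, rank_F, byrow = TRUE), Ew)
      sum_yz <- sum_yz + crossprod(y, Ez)
      Szz <- crossprod(Ez)
      ## add posterior covariances: h block ni*Ch, w block ni*Minv_w +
      ## ni*Cw_extra, cross blocks ni*Ehw
      hb <- seq_len(rank_F)
      wb <- rank_F + seq_len(rank_G)
      Szz[hb, hb] <- Szz[hb, hb] + ni * Ch
      if (rank_G > 0) {
        Szz[wb, wb] <- Szz[wb, wb] + ni * (Minv_w + Cw_extra)
        Szz[hb, wb] <- Szz[hb, wb] + ni * Ehw
        Szz[wb, hb] <- Szz[wb, hb] + ni * t(Ehw)
      }
      sum_zz <- sum_zz + Szz
      n_tot <- n_tot + ni
    }
    if (length(loglik) && ll < loglik[length(loglik)] - 1e-6 * abs(ll))
      stop_pdvoice("PLDA EM log-likelihood decreased")
    loglik <- c(loglik, as.numeric(ll))
    ## M-step: joint update of [F G], then diagonal Sigma
    B <- sum_yz %*% solve(sum_zz + diag(1e-10, nrow(sum_zz)))
    Fn <- B[, seq_len(rank_F), drop = FALSE]
    Gn <- B[, rank_F + seq_len(rank_G), drop = FALSE]
    Sigma_n <- (colSums(xc^2) - rowSums(B * sum_yz)) / n_tot
    F <- Fn; G <- Gn
    Sigma <- pmax(Sigma_n, 1e-8 * tot_var)
  }
  structure(list(mu = mu, F = F, G = G, Sigma = Sigma, rank_F = rank_F,
                 rank_G = rank_G, loglik = loglik), class = "plda_model")
}

#' PLDA same-class log-likelihood ratio
#'
#' Scores the hypothesis that two vectors share the same class latent `h`
#' against the hypothesis of independent latents, using the closed-form
#' Gaussian marginals of the model (two-covariance form: across-class
#' covariance `F F'`, within-class covariance `G G' + Sigma`).  Symmetric
#' in its two arguments.
#'
#' @param model a [fit_plda()] model.
#' @param x1,x2 vectors of the model dimension.
#' @return The log-likelihood ratio (higher = more likely same class).
#' @export
plda_llr <- function(model, x1, x2) {
  d <- length(model$mu)
  if (length(x1) != d || length(x2) != d)
    stop_pdvoice("vector dimension does not match the PLDA model")
  B <- tcrossprod(model$F)
  W <- tcrossprod(model$G) + diag(model$Sigma, d)
  T1 <- B + W
  joint <- rbind(cbind(T1, B), cbind(B, T1))
  ll_same <- dmvnorm_log(c(x1, x2), c(model$mu, model$mu), joint)
  ll_ind <- dmvnorm_log(x1, model$mu, T1) + dmvnorm_log(x2, model$mu, T1)
  ll_same - ll_ind
}

#' Score one x-vector against the class references
#'
#' `sigmoid(sigmoid_scale * (sim(x, ref_PD) - sim(x, ref_HC)))`, where
#' `sim` is cosine similarity (optionally in LDA space) or the PLDA
#' log-likelihood ratio.  A score above 0.5 points to PD.
#'
#' @param references a [compute_references()] object.
#' @param x the test x-vector.
#' @param method `"cosine"`, `"lda_cosine"`, or `"plda"`.
#' @param lda [fit_lda()] transform (required for `"lda_cosine"`; for
#'   `"plda"`, an optional dimension-reduction applied to x and the
#'   references before scoring).
#' @param plda [fit_plda()] model (required for `"plda"`); must be fitted
#'   in the same (possibly LDA-reduced) space it is scored in.
#' @param sigmoid_scale sigmoid slope (EER-invariant calibration).
#' @return A score in (0, 1).
#' @export
score_xvector <- function(references, x,
                          method = c("cosine", "lda_cosine", "plda"),
                          lda = NULL, plda = NULL, sigmoid_scale = 1) {
  method <- match.arg(method)
  x <- as.numeric(x)
  ref_pd <- references$xvec_pd
  ref_hc <- references$xvec_hc
  sim <- switch(method,
    cosine = {
      cosine_similarity(x, ref_pd) - cosine_similarity(x, ref_hc)
    },
    lda_cosine = {
      if (is.null(lda)) stop_pdvoice("lda transform required for lda_cosine")
      xp <- lda_project(lda, x)
      cosine_similarity(xp, lda_project(lda, ref_pd)) -
        cosine_similarity(xp, lda_project(lda, ref_hc))
    },
    plda = {
      if (is.null(plda)) stop_pdvoice("plda model required for plda scoring")
      if (!is.null(lda)) {
        x <- lda_project(lda, x)
        ref_pd <- lda_project(lda, ref_pd)
        ref_hc <- lda_project(lda, ref_hc)
      }
      plda_llr(plda, x, ref_pd) - plda_llr(plda, x, ref_hc)
    })
  sigmoid(sigmoid_scale * sim)
}

#' Aggregate a subject's segment scores
#'
#' Arithmetic mean of the per-x-vector classification scores of one
#' subject.
#'
#' @param scores numeric vector of segment scores.
#' @return The mean score.
#' @export
score_subject <- function(scores) {
  if (length(scores) == 0) stop_pdvoice("no segment scores to aggregate")
  mean(scores)
}
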