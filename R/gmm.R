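#' Train a diagonal-covariance Gaussian mixture model by EM
#'
#' Fits a `n_components`-component GMM with diagonal covariances to pooled
#' feature frames, initialized from a seeded k-means run.  The
#' per-iteration mean log-likelihood is non-decreasing (asserted) and
#' training stops when its improvement falls below `tol` or after
#' `max_iter` iterations.  Component variances are floored at
#' `var_floor_frac` times the global per-dimension variance; a component
#' hitting the floor triggers a warning, not an error.
#'
#' @param features a `feature_matrix` or a numeric frames-by-dim matrix of
#'   pooled voiced frames.
#' @param n_components number of Gaussians (20 for the high-quality
#'   preset, 50 for telephone).
#' @param max_iter,tol EM stopping rule (tolerance on the change in mean
#'   log-likelihood per frame).
#' @param seed seed for the k-means initialization.
#' @param var_floor_frac variance floor as a fraction of global variance.
#' @return An object of class `gmm_model`: `weights`, `means`
#'   (components x dim), `variances` (components x dim), `n_components`,
#'   and the training `loglik` trace.
#' @export
train_gmm <- function(features, n_components, max_iter = 50, tol = 1e-4,
                      seed = 1, var_floor_frac = 1e-3) {
  x <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  n <- nrow(x); d <- ncol(x)
  if (n < 10 * n_components)
    stop_pdvoice("need at least 10 frames per component (", n, " frames, ",
                 n_components, " components)")
  var_floor <- pmax(apply(x, 2, stats::var), .Machine$double.eps) *
    var_floor_frac
  init <- with_seed(child_seed(seed, "gmm_init"), {
    if (n_components == 1L) {
      list(centers = matrix(colMeans(x), 1), cluster = rep(1L, n))
    } else {
      ## initializer only -- k-means convergence warnings are irrelevant
      km <- suppressWarnings(stats::kmeans(x, centers = n_components,
                                           iter.max = 20, nstart = 1))
      list(centers = km$centers, cluster = km$cluster)
    }
  })
  means <- unname(as.matrix(init$centers))
  variances <- matrix(0, n_components, d)
  weights <- numeric(n_components)
  for (k in seq_len(n_components)) {
    idx <- init$cluster == k
    weights[k] <- max(sum(idx), 1) / n
    v <- if (sum(idx) > 1) apply(x[idx, , drop = FALSE], 2, stats::var) else
      var_floor / var_floor_frac
    variances[k, ] <- pmax(v, var_floor)
  }
  weights <- weights / sum(weights)
  loglik <- numeric(0)
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    lp <- gmm_log_resp(x, weights, means, variances)
    ll <- mean(lp$norm)
    if (length(loglik) && ll < loglik[length(loglik)] - 1e-8)
      stop_pdvoice("EM log-likelihood decreased; numerical failure")
    converged <- length(loglik) && ll - loglik[length(loglik)] < tol
    loglik <- c(loglik, ll)
    if (converged) break
    resp <- exp(lp$logresp)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- crossprod(resp, x) / nk
    ex2 <- crossprod(resp, x^2) / nk
    v <- ex2 - means^2
    if (any(v < rep(var_floor, each = n_components))) floored <- TRUE
    variances <- pmax(v, rep(var_floor, each = n_components))
  }
  if (floored) warning("variance floor applied to collapsing component(s)")
  structure(list(weights = weights, means = means, variances = variances,
                 n_components = n_components, loglik = loglik),
            class = "gmm_model")
}

## Per-frame log densities: returns the log-responsibility matrix and the
## per-frame log-likelihood (log-sum-exp over components).
gmm_log_resp <- function(x, weights, means, variances) {
  n <- nrow(x); k <- nrow(means)
  const <- -0.5 * (ncol(x) * log(2 * pi) + rowSums(log(variances)))
  quad <- matrix(0, n, k)
  inv_v <- 1 / variances
  quad <- x^2 %*% t(0.5 * inv_v) - x %*% t(means * inv_v) +
    matrix(rowSums(0.5 * means^2 * inv_v), n, k, byrow = TRUE)
  lp <- matrix(log(weights) + const, n, k, byrow = TRUE) - quad
  norm <- logsumexp_rows(lp)
  list(logresp = lp - norm, norm = norm)
}

#' Frame-averaged log-likelihood under a GMM
#'
#' One log-likelihood per frame, averaged over frames, so the value is
#' independent of the number of frames.
#'
#' @param model a [train_gmm()] model.
#' @param features a `feature_matrix` or frames-by-dim matrix.
#' @return The mean per-frame log-likelihood.
#' @export
mean_loglik <- function(model, features) {
  x <- if (inherits(features, "feature_matrix")) features$values else
    as.matrix(features)
  if (ncol(x) != ncol(model$means))
    stop_pdvoice("feature dim ", ncol(x), " != model dim ",
                 ncol(model$means))
  mean(gmm_log_resp(x, model$weights, model$means, model$variances)$norm)
}

#' Pair of class-conditional GMMs
#'
#' @param pd_model,hc_model [train_gmm()] models of the PD and HC training
#'   groups, sharing dimension and component count.
#' @param gender the gender the pair was trained on.
#' @return An object of class `gmm_pair`.
#' @export
gmm_pair <- function(pd_model, hc_model, gender = NA_character_) {
  stopifnot(inherits(pd_model, "gmm_model"), inherits(hc_model, "gmm_model"))
  if (ncol(pd_model$means) != ncol(hc_model$means) ||
      pd_model$n_components != hc_model$n_components)
    stop_pdvoice("pd and hc models must share dim and n_components")
  structure(list(pd_model = pd_model, hc_model = hc_model, gender = gender),
            class = "gmm_pair")
}

#' Score a test subject against a PD/HC GMM pair
#'
#' Computes the sigmoid of the log-likelihood ratio
#' `mean_loglik(PD) - mean_loglik(HC)` of the subject's pooled voiced
#' frames.  Scores close to 1 point to PD, close to 0 to HC.
#'
#' @param pair a [gmm_pair()].
#' @param features the subject's concatenated kept frames.
#' @param sigmoid_scale slope of the sigmoid (equal error rate is
#'   invariant to this monotone rescaling; it only calibrates scores).
#' @return A score in (0, 1).
#' @export
score_subject_gmm <- function(pair, features, sigmoid_scale = 1) {
  llr <- mean_loglik(pair$pd_model, features) -
    mean_loglik(pair$hc_model, features)
  sigmoid(sigmoid_scale * llr)
}

#' Serialize a GMM model or pair to JSON-compatible lists
#'
#' @param model a `gmm_model` or `gmm_pair`.
#' @param path file to write (RDS-free plain text, `dput` format).
#' @return `path`, invisibly.
#' @export
write_gmm <- function(model, path) {
  dput(unclass_recursive(model), file = path)
  invisible(path)
}

#' @rdname write_gmm
#' @param what `"gmm_model"` or `"gmm_pair"`.
#' @export
read_gmm <- function(path, what = c("gmm_model", "gmm_pair")) {
  what <- match.arg(what)
  obj <- dget(path)
  if (what == "gmm_pair") {
    obj$pd_model <- structure(obj$pd_model, class = "gmm_model")
    obj$hc_model <- structure(obj$hc_model, class = "gmm_model")
  }
  structure(obj, class = what)
}

unclass_recursive <- function(x) {
  x <- unclass(x)
  if (is.list(x)) x <- lapply(x, unclass_recursive)
  x
}
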