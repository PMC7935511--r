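## Frame-level splicing contexts of the x-vector architecture.  Layers 2
## and 3 use dilated splicing; the input width of each layer is
## length(offsets) * previous output dim, giving the published dimension
## chain (5K -> 512, 1536 -> 512, 1536 -> 512, 512 -> 512, 512 -> 1500).
tdnn_offsets <- list(-2:2, c(-2L, 0L, 2L), c(-3L, 0L, 3L), 0L, 0L)

#' TDNN x-vector network configuration
#'
#' The time-delay architecture used for x-vector extraction: five
#' frame-level layers with temporal splicing (total receptive field 15
#' frames), a statistics-pooling layer producing per-dimension mean and
#' SD (population convention), two segment-level layers, and a softmax
#' output over `n_targets` training labels.  The x-vector is the
#' pre-activation of the first segment-level layer.
#'
#' @param input_dim number of input features per frame (K).
#' @param n_targets softmax width: number of training speakers, or 2 for
#'   the PD/HC class-trained variant.
#' @param frame_dims output dims of the five frame-level layers.
#' @param embedding_dim x-vector dimension (first segment-level layer).
#' @param segment_dim second segment-level layer width.
#' @return An object of class `tdnn_config`.
#' @export
tdnn_config <- function(input_dim, n_targets,
                        frame_dims = c(512, 512, 512, 512, 1500),
                        embedding_dim = 512, segment_dim = 512) {
  stopifnot(length(frame_dims) == 5, all(frame_dims > 0), input_dim > 0,
            n_targets >= 2)
  structure(list(input_dim = as.integer(input_dim),
                 n_targets = as.integer(n_targets),
                 frame_dims = as.integer(frame_dims),
                 embedding_dim = as.integer(embedding_dim),
                 segment_dim = as.integer(segment_dim),
                 offsets = tdnn_offsets,
                 receptive_field = 1L + sum(vapply(tdnn_offsets,
                                                   function(o) max(o) - min(o),
                                                   integer(1)))),
            class = "tdnn_config")
}

#' Desk-scale TDNN configuration
#'
#' Width-divided variant for fast CPU training in tests and small
#' experiments; the full 512-wide [tdnn_config()] remains the reference
#' for the dimension contract.
#'
#' @inheritParams tdnn_config
#' @param scale integer width divisor.
#' @export
tdnn_config_small <- function(input_dim, n_targets, scale = 8) {
  tdnn_config(input_dim, n_targets,
              frame_dims = pmax(8L, c(512, 512, 512, 512, 1500) %/% scale),
              embedding_dim = max(8L, 512L %/% scale),
              segment_dim = max(8L, 512L %/% scale))
}

layer_dims <- function(config) {
  in_dims <- integer(7)
  out_dims <- integer(7)
  prev <- config$input_dim
  for (l in 1:5) {
    in_dims[l] <- prev * length(config$offsets[[l]])
    out_dims[l] <- config$frame_dims[l]
    prev <- config$frame_dims[l]
  }
  in_dims[6] <- 2L * config$frame_dims[5]   # mean (+) SD pooling
  out_dims[6] <- config$embedding_dim
  in_dims[7] <- config$embedding_dim
  out_dims[7] <- config$segment_dim
  list(input = in_dims, output = out_dims)
}

#' Build a TDNN model with seeded random initialization
#'
#' He-scaled Gaussian weight initialization, deterministic in `seed`.
#'
#' @param config a [tdnn_config()].
#' @param seed integer seed.
#' @return An object of class `tdnn_model` holding the weight matrices.
#' @export
build_tdnn <- function(config, seed = 1) {
  stopifnot(inherits(config, "tdnn_config"))
  dims <- layer_dims(config)
  with_seed(child_seed(seed, "tdnn_init"), {
    weights <- list()
    for (l in 1:7) {
      weights[[paste0("W", l)]] <- matrix(
        stats::rnorm(dims$input[l] * dims$output[l],
                     sd = sqrt(2 / dims$input[l])),
        dims$input[l], dims$output[l])
      weights[[paste0("b", l)]] <- numeric(dims$output[l])
    }
    weights$W8 <- matrix(stats::rnorm(config$segment_dim * config$n_targets,
                                      sd = sqrt(2 / config$segment_dim)),
                         config$segment_dim, config$n_targets)
    weights$b8 <- numeric(config$n_targets)
    structure(list(config = config, weights = weights,
                   training_log = data.frame()),
              class = "tdnn_model")
  })
}

#' @export
print.tdnn_model <- function(x, ...) {
  cat(sprintf(paste0("<tdnn_model: K=%d, frame dims [%s], embedding %d, ",
                     "%d targets>\n"),
              x$config$input_dim,
              paste(x$config$frame_dims, collapse = ","),
              x$config$embedding_dim, x$config$n_targets))
  invisible(x)
}

#' Statistics pooling: per-dimension mean and SD over frames
#'
#' Aggregates a frames-by-dim matrix into a fixed-length vector of
#' per-dimension means and standard deviations (population convention).
#' Order-free: any permutation of the frames yields the same result.
#'
#' @param h frames-by-dim numeric matrix.
#' @return A list with `mean`, `sd`, and their concatenation `pooled`.
#' @export
statistics_pooling <- function(h) {
  m <- colMeans(h)
  centered <- sweep(h, 2, m)
  s <- sqrt(colMeans(centered^2))   # two-pass: exact 0 for constant input
  list(mean = m, sd = s, pooled = c(m, s))
}

splice <- function(A, offsets) {
  if (identical(offsets, 0L) || identical(offsets, 0)) return(A)
  t_out <- nrow(A) - (max(offsets) - min(offsets))
  do.call(cbind, lapply(offsets, function(o) {
    A[seq_len(t_out) + (o - min(offsets)), , drop = FALSE]
  }))
}

## Forward pass over one segment (frames x input_dim).  Returns the
## softmax probabilities, the x-vector (pre-ReLU segment-layer-6
## activation), pooled statistics, and (optionally) all intermediates
## needed for backprop.
tdnn_forward <- function(model, x, keep = FALSE) {
  cfg <- model$config
  w <- model$weights
  if (ncol(x) != cfg$input_dim)
    stop_pdvoice("input dim ", ncol(x), " != network K ", cfg$input_dim)
  if (nrow(x) < cfg$receptive_field)
    stop_pdvoice("segment has ", nrow(x), " frames; receptive field is ",
                 cfg$receptive_field)
  acts <- list()
  h <- x
  for (l in 1:5) {
    sp <- splice(h, cfg$offsets[[l]])
    z <- sweep(sp %*% w[[paste0("W", l)]], 2, w[[paste0("b", l)]], `+`)
    if (keep) acts[[l]] <- list(input = h, spliced = sp, z = z)
    h <- z * (z > 0)
  }
  t_frames <- nrow(h)
  st <- statistics_pooling(h)
  m <- st$mean
  s <- st$sd
  pooled <- st$pooled
  z6 <- as.numeric(crossprod(w$W6, pooled)) + w$b6   # the x-vector
  h6 <- z6 * (z6 > 0)
  z7 <- as.numeric(crossprod(w$W7, h6)) + w$b7
  h7 <- z7 * (z7 > 0)
  logits <- as.numeric(crossprod(w$W8, h7)) + w$b8
  logits <- logits - max(logits)
  probs <- exp(logits) / sum(exp(logits))
  out <- list(probs = probs, xvector = z6, pooled = pooled,
              mean = m, sd = s)
  if (keep) {
    out$acts <- acts
    out$frame_out <- h
    out$t_frames <- t_frames
    out$h6 <- h6; out$z6 <- z6; out$h7 <- h7; out$z7 <- z7
  }
  out
}

## Backprop of the cross-entropy loss for one segment; returns gradients
## keyed like the weight list.
tdnn_backward <- function(model, x, target, fwd) {
  cfg <- model$config
  w <- model$weights
  g <- list()
  dlogits <- fwd$probs
  dlogits[target] <- dlogits[target] - 1
  g$W8 <- outer(fwd$h7, dlogits)
  g$b8 <- dlogits
  dh7 <- as.numeric(w$W8 %*% dlogits) * (fwd$z7 > 0)
  g$W7 <- outer(fwd$h6, dh7)
  g$b7 <- dh7
  dh6 <- as.numeric(w$W7 %*% dh7) * (fwd$z6 > 0)
  g$W6 <- outer(fwd$pooled, dh6)
  g$b6 <- dh6
  dpooled <- as.numeric(w$W6 %*% dh6)
  d <- cfg$frame_dims[5]
  dm <- dpooled[seq_len(d)]
  ds <- dpooled[d + seq_len(d)]
  h <- fwd$frame_out
  t_frames <- fwd$t_frames
  s_safe <- pmax(fwd$sd, 1e-6)
  dh <- matrix(dm / t_frames, t_frames, d, byrow = TRUE) +
    sweep(sweep(h, 2, fwd$mean, `-`), 2, ds / (t_frames * s_safe), `*`)
  for (l in 5:1) {
    a <- fwd$acts[[l]]
    dz <- dh * (a$z > 0)
    g[[paste0("W", l)]] <- crossprod(a$spliced, dz)
    g[[paste0("b", l)]] <- colSums(dz)
    if (l > 1) {
      offsets <- cfg$offsets[[l]]
      d_in <- ncol(a$input)
      dinput <- matrix(0, nrow(a$input), d_in)
      dsp <- dz %*% t(w[[paste0("W", l)]])
      t_out <- nrow(dz)
      for (j in seq_along(offsets)) {
        rows <- seq_len(t_out) + (offsets[j] - min(offsets))
        cols <- (j - 1L) * d_in + seq_len(d_in)
        dinput[rows, ] <- dinput[rows, ] + dsp[, cols, drop = FALSE]
      }
      dh <- dinput * (fwd$acts[[l - 1]]$z > 0)
      ## fwd$acts[[l-1]]$z has the same shape as the ReLU input of layer
      ## l-1's output, which is a$input
    }
  }
  g
}

#' Sample fixed-length training chunks from feature segments
#'
#' Crops each feature matrix into random chunks of 2--4 s (200--400
#' frames at a 10 ms step), the durations used for network training.
#'
#' @param features_list list of `feature_matrix` or plain matrices.
#' @param labels label per list element.
#' @param chunks_per_segment chunks drawn from each segment.
#' @param min_frames,max_frames chunk length bounds in frames.
#' @param seed integer seed.
#' @return A list with `chunks` (list of matrices) and `labels`.
#' @export
sample_training_chunks <- function(features_list, labels,
                                   chunks_per_segment = 2,
                                   min_frames = 200, max_frames = 400,
                                   seed = 1) {
  stopifnot(length(features_list) == length(labels))
  with_seed(child_seed(seed, "chunks"), {
    chunks <- list(); out_labels <- c()
    for (i in seq_along(features_list)) {
      x <- features_list[[i]]
      if (inherits(x, "feature_matrix")) x <- x$values
      n <- nrow(x)
      if (n < 15) next
      for (j in seq_len(chunks_per_segment)) {
        len <- min(n, round(stats::runif(1, min_frames, max_frames)))
        start <- sample.int(n - len + 1L, 1)
        chunks[[length(chunks) + 1L]] <- x[start + seq_len(len) - 1L, ,
                                           drop = FALSE]
        out_labels <- c(out_labels, labels[i])
      }
    }
    list(chunks = chunks, labels = out_labels)
  })
}

#' Train a TDNN by stochastic gradient descent (Adam)
#'
#' Minimizes softmax cross-entropy over the chunk labels: speaker
#' identities (`label_mode = "speaker"`) or the two-class PD/HC variant
#' (`label_mode = "pd_class"`, softmax width 2).  Deterministic given
#' `seed` on a single thread; per-epoch training accuracy is recorded in
#' `model$training_log`.
#'
#' @param model a [build_tdnn()] model.
#' @param chunks list of frames-by-K matrices (2--4 s training chunks, see
#'   [sample_training_chunks()]).
#' @param labels chunk labels (coerced to factor).
#' @param label_mode `"speaker"` or `"pd_class"`.
#' @param epochs,lr,batch_size optimizer settings.
#' @param seed shuffling seed.
#' @return The trained `tdnn_model`.
#' @export
train_tdnn <- function(model, chunks, labels,
                       label_mode = c("speaker", "pd_class"),
                       epochs = 10, lr = 1e-3, batch_size = 8, seed = 1) {
  label_mode <- match.arg(label_mode)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop_pdvoice("need at least 2 distinct labels")
  if (label_mode == "pd_class" && nlevels(labels) != 2)
    stop_pdvoice("pd_class mode requires exactly 2 labels")
  if (nlevels(labels) != model$config$n_targets)
    stop_pdvoice("model has ", model$config$n_targets, " targets but data ",
                 "has ", nlevels(labels), " labels")
  targets <- as.integer(labels)
  w <- model$weights
  adam_m <- lapply(w, function(p) p * 0)
  adam_v <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  log_rows <- list()
  with_seed(child_seed(seed, "tdnn_train"), {
    for (epoch in seq_len(epochs)) {
      ord <- sample(seq_along(chunks))
      correct <- 0; total_loss <- 0
      batch_starts <- seq(1, length(ord), by = batch_size)
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + batch_size - 1L, length(ord))]
        grad <- NULL
        for (i in idx) {
          model$weights <- w
          fwd <- tdnn_forward(model, chunks[[i]], keep = TRUE)
          g <- tdnn_backward(model, chunks[[i]], targets[i], fwd)
          total_loss <- total_loss - log(max(fwd$probs[targets[i]], 1e-12))
          if (which.max(fwd$probs) == targets[i]) correct <- correct + 1
          grad <- if (is.null(grad)) g else
            mapply(`+`, grad, g, SIMPLIFY = FALSE)
        }
        grad <- lapply(grad, function(g) g / length(idx))
        step <- step + 1
        for (nm in names(w)) {
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grad[[nm]]
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grad[[nm]]^2
          mhat <- adam_m[[nm]] / (1 - beta1^step)
          vhat <- adam_v[[nm]] / (1 - beta2^step)
          w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, loss = total_loss / length(chunks),
        accuracy = correct / length(chunks))
    }
  })
  model$weights <- w
  model$training_log <- do.call(rbind, log_rows)
  model$label_levels <- levels(labels)
  model
}

#' Extract an x-vector from a feature segment
#'
#' The x-vector is the pre-activation (before ReLU) of the first
#' segment-level layer, a fixed-length embedding of the variable-length
#' segment.
#'
#' @param model a trained `tdnn_model`.
#' @param features a `feature_matrix` (kept frames) or plain matrix with
#'   at least `receptive_field` (15) frames; segment duration must lie in
#'   the 25 ms -- 100 s extraction limits.
#' @return Numeric vector of length `embedding_dim`, with attributes
#'   `provenance` and `parent_id` when available.
#' @export
extract_xvector <- function(model, features) {
  prov <- NULL; parent <- NULL
  if (inherits(features, "feature_matrix")) {
    prov <- features$provenance
    parent <- features$provenance$parent_id
    step_s <- features$config$step_ms / 1000
    dur <- nrow(features$values) * step_s
    if (dur > 100)
      stop_pdvoice("segment longer than 100 s; fragment it first")
    features <- features$values
  }
  if (nrow(features) < model$config$receptive_field)
    stop_pdvoice("segment shorter than the receptive field (",
                 model$config$receptive_field, " frames)")
  xv <- tdnn_forward(model, features)$xvector
  attr(xv, "provenance") <- prov
  attr(xv, "parent_id") <- parent
  xv
}

#' Extract x-vectors for a file's pieces, averaging sibling fragments
#'
#' Pieces flagged with a common `parent_id` (fragments of an over-long
#' file) are averaged into a single x-vector; independent pieces are
#' returned individually.
#'
#' @param model a trained `tdnn_model`.
#' @param features_list list of `feature_matrix` pieces from
#'   [split_segments()] + [extract_features()].
#' @return A list of x-vectors.
#' @export
extract_for_file <- function(model, features_list) {
  xvs <- lapply(features_list, function(f) extract_xvector(model, f))
  parents <- vapply(xvs, function(v) {
    p <- attr(v, "parent_id"); if (is.null(p)) NA_character_ else p
  }, character(1))
  out <- list()
  done <- logical(length(xvs))
  for (i in seq_along(xvs)) {
    if (done[i]) next
    if (is.na(parents[i])) {
      out[[length(out) + 1L]] <- xvs[[i]]
      done[i] <- TRUE
    } else {
      sib <- which(parents == parents[i])
      avg <- Reduce(`+`, lapply(xvs[sib], as.numeric)) / length(sib)
      if (sqrt(sum(avg^2)) < 1e-12)
        attr(avg, "degenerate") <- TRUE
      attr(avg, "provenance") <- attr(xvs[[sib[1]]], "provenance")
      attr(avg, "parent_id") <- parents[i]
      out[[length(out) + 1L]] <- avg
      done[sib] <- TRUE
    }
  }
  out
}
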