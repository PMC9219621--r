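# Model-II: the finetuning protocol of the transfer-learning branch,
# backbone-agnostic.  Preprocessing (bilinear resize, 3-channel
# replication, [0,1] scaling), light augmentation (random centred crop +
# flips), Adam with per-epoch exponential learning-rate decay, 10-fold
# scored output.  A small 2-conv-layer + FC surrogate backbone (pure R,
# trained from scratch) exercises the protocol at desk scale; an external
# pretrained backbone can be plugged in through the same contract.

#' Configuration of the finetuning protocol
#'
#' Defaults follow the reference protocol for a pretrained backbone:
#' 224x224 3-channel input, batch size 4, Adam at 1e-4 with per-epoch
#' exponential decay gamma 0.4, 10 epochs, flips at p = 0.5.  When
#' training the from-scratch surrogate backbone, a smaller `input_size`
#' and a larger `initial_learning_rate` are appropriate (see the methods
#' vignette).
#'
#' @param input_size network input side, pixels
#' @param channels input channels (grayscale is replicated)
#' @param batch_size minibatch size
#' @param initial_learning_rate Adam learning rate at the start of each
#'   fold
#' @param lr_decay_gamma multiplicative learning-rate decay applied after
#'   each epoch
#' @param epochs training epochs per fold
#' @param augmentation_flip_prob probability of each of the horizontal
#'   and vertical flips
#' @param crop_scale_range random centred-crop scale range (fraction of
#'   side length)
#' @param backbone `"surrogate_cnn"` or `"external"`
#' @param rng_seed integer seed governing initialisation, shuffling and
#'   augmentation
#' @return an object of class `dl_config`
#' @export
dl_config <- function(input_size = 224L, channels = 3L, batch_size = 4L,
                      initial_learning_rate = 1e-4, lr_decay_gamma = 0.4,
                      epochs = 10L, augmentation_flip_prob = 0.5,
                      crop_scale_range = c(0.9, 1.0),
                      backbone = c("surrogate_cnn", "external"),
                      rng_seed = 1L) {
  if (input_size <= 0) stop_field("input_size", "must be > 0")
  if (input_size %% 4 != 0)
    stop_field("input_size", "must be divisible by 4 (two pooling stages)")
  if (batch_size <= 0) stop_field("batch_size", "must be > 0")
  if (initial_learning_rate <= 0)
    stop_field("initial_learning_rate", "must be > 0")
  if (lr_decay_gamma <= 0) stop_field("lr_decay_gamma", "must be > 0")
  if (epochs < 1) stop_field("epochs", "must be >= 1")
  if (augmentation_flip_prob < 0 || augmentation_flip_prob > 1)
    stop_field("augmentation_flip_prob", "must be in [0, 1]")
  structure(list(input_size = as.integer(input_size),
                 channels = as.integer(channels),
                 batch_size = as.integer(batch_size),
                 initial_learning_rate = initial_learning_rate,
                 lr_decay_gamma = lr_decay_gamma,
                 epochs = as.integer(epochs),
                 augmentation_flip_prob = augmentation_flip_prob,
                 crop_scale_range = as.numeric(crop_scale_range),
                 backbone = match.arg(backbone),
                 rng_seed = as.integer(rng_seed)),
            class = "dl_config")
}

#' Learning rate in effect during a given epoch
#'
#' `lr(e) = initial_learning_rate * gamma^(e-1)`; after epoch `e` the
#' rate has been multiplied `e` times.
#'
#' @param config a [dl_config()]
#' @param epoch epoch number (1-based)
#' @return learning rate
#' @export
epoch_learning_rate <- function(config, epoch) {
  config$initial_learning_rate * config$lr_decay_gamma^(epoch - 1)
}

#' Preprocess an ROI for the network
#'
#' Bilinear resize to the network input size, intensity scaling to [0, 1]
#' by the patch maximum, and replication of the grayscale patch into all
#' channels.
#'
#' @param roi a `lesion_roi` (or any list with an `image` matrix)
#' @param config a [dl_config()]
#' @return numeric array `input_size x input_size x channels`
#' @export
preprocess_patch <- function(roi, config = dl_config()) {
  img <- roi$image
  if (nrow(img) != ncol(img)) stop("ROI patch must be square")
  mx <- max(img)
  scaled <- if (mx > 0) img / mx else img
  resized <- bilinear_resize(scaled, config$input_size, config$input_size)
  array(rep(resized, config$channels),
        dim = c(config$input_size, config$input_size, config$channels))
}

#' Training-time augmentation
#'
#' Random centred crop (scale drawn from `crop_scale_range`, resized
#' back), then horizontal and vertical flips each with the configured
#' probability.  Consumes the current RNG stream, so it is deterministic
#' under a fixed seed.
#'
#' @param x 3-D array (side x side x channels)
#' @param config a [dl_config()]
#' @return augmented array of the same shape
#' @export
augment_patch <- function(x, config = dl_config()) {
  n <- dim(x)[1]
  scale <- stats::runif(1, config$crop_scale_range[1], config$crop_scale_range[2])
  side <- max(2L, round(scale * n))
  if (side < n) {
    off <- floor((n - side) / 2)
    idx <- (off + 1):(off + side)
    x <- apply(x[idx, idx, , drop = FALSE], 3, bilinear_resize,
               out_rows = n, out_cols = n)
    x <- array(x, dim = c(n, n, dim(x)[2]))
  }
  if (stats::runif(1) < config$augmentation_flip_prob) x <- x[, n:1, , drop = FALSE]
  if (stats::runif(1) < config$augmentation_flip_prob) x <- x[n:1, , , drop = FALSE]
  x
}

## ---- surrogate convolutional backbone ------------------------------------

# cached im2col index map for 3x3 same-padding convolution
im2col_index <- function(H, W, C) {
  # linear indices into a (H+2) x (W+2) x C zero-padded array
  base_r <- rep(seq_len(H), W)
  base_c <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L * C)
  k <- 0L
  for (ch in seq_len(C)) {
    for (kc in 0:2) {
      for (kr in 0:2) {
        k <- k + 1L
        idx[, k] <- (base_r + kr) + (base_c + kc - 1L) * (H + 2L) +
          (ch - 1L) * (H + 2L) * (W + 2L)
      }
    }
  }
  idx
}

pad_array <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L, d[2] + 2L, d[3]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), ] <- x
  out
}

im2col <- function(x, idx) {
  p <- pad_array(x)
  matrix(p[as.vector(idx)], nrow(idx), ncol(idx))
}

col2im_grad <- function(dcols, idx, H, W, C) {
  g <- numeric((H + 2L) * (W + 2L) * C)
  for (k in seq_len(ncol(idx))) {
    g[idx[, k]] <- g[idx[, k]] + dcols[, k]
  }
  ga <- array(g, dim = c(H + 2L, W + 2L, C))
  ga[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

avgpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, W, 2); ce <- seq(2, W, 2)
  (x[ro, co, , drop = FALSE] + x[re, co, , drop = FALSE] +
     x[ro, ce, , drop = FALSE] + x[re, ce, , drop = FALSE]) / 4
}

unpool2_grad <- function(d, H, W) {
  F <- dim(d)[3]
  out <- array(0, dim = c(H, W, F))
  ro <- seq(1, H, 2); re <- seq(2, H, 2)
  co <- seq(1, W, 2); ce <- seq(2, W, 2)
  q <- d / 4
  out[ro, co, ] <- q; out[re, co, ] <- q
  out[ro, ce, ] <- q; out[re, ce, ] <- q
  out
}

leaky_relu <- function(z, slope = 0.1) pmax(z, slope * z)
leaky_relu_grad <- function(z, slope = 0.1) slope + (1 - slope) * (z > 0)

softmax2 <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Built-in surrogate convolutional backbone
#'
#' A small trainable network: 3x3 conv (8 filters) + leaky ReLU + 2x2
#' average pool + 3x3 conv (16 filters) + leaky ReLU + global average
#' pool + fully connected 2-class softmax.  Leaky activations (slope
#' 0.1) keep every unit trainable at the aggressive learning rates a
#' from-scratch network needs.  All layers are trainable; the object
#' fulfils the backbone contract used by [finetune_cv()] (`init`,
#' `forward`, `backward`).
#'
#' @param n_filters1,n_filters2 filters in the two convolution stages
#' @return a backbone object (list of functions)
#' @export
surrogate_cnn <- function(n_filters1 = 8L, n_filters2 = 16L) {
  cache_env <- new.env(parent = emptyenv())
  get_idx <- function(H, W, C) {
    key <- paste(H, W, C, sep = "x")
    if (is.null(cache_env[[key]])) cache_env[[key]] <- im2col_index(H, W, C)
    cache_env[[key]]
  }
  init <- function(input_size, channels, seed) {
    with_seed(seed, {
      f1 <- n_filters1; f2 <- n_filters2
      w1 <- matrix(stats::rnorm(9 * channels * f1, sd = sqrt(2 / (9 * channels))),
                   9 * channels, f1)
      w2 <- matrix(stats::rnorm(9 * f1 * f2, sd = sqrt(2 / (9 * f1))),
                   9 * f1, f2)
      # zero-initialised head: no random initial miscalibration to unlearn
      list(w1 = w1, b1 = numeric(f1), w2 = w2, b2 = numeric(f2),
           wf = matrix(0, f2, 2), bf = numeric(2),
           fixed_norm = NULL)
    })
  }
  forward <- function(params, x) {
    H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
    idx1 <- get_idx(H, W, C)
    X1 <- im2col(x, idx1)
    Z1 <- sweep(X1 %*% params$w1, 2, params$b1, "+")
    A1 <- array(leaky_relu(Z1), dim = c(H, W, ncol(Z1)))
    P1 <- avgpool2(A1)
    h <- H / 2; w <- W / 2
    idx2 <- get_idx(h, w, dim(P1)[3])
    X2 <- im2col(P1, idx2)
    Z2 <- sweep(X2 %*% params$w2, 2, params$b2, "+")
    A2 <- leaky_relu(Z2)
    g_raw <- colMeans(A2)
    g <- if (!is.null(params$fixed_norm)) {
      (g_raw - params$fixed_norm$mu) / params$fixed_norm$sd
    } else g_raw
    logits <- as.vector(g %*% params$wf + params$bf)
    p <- softmax2(logits)
    list(probs = p,
         cache = list(x = x, X1 = X1, Z1 = Z1, X2 = X2, Z2 = Z2, g = g,
                      H = H, W = W, C = C, idx1 = idx1, idx2 = idx2))
  }
  backward <- function(params, fwd, y_onehot) {
    cc <- fwd$cache
    dlogits <- fwd$probs - y_onehot
    dwf <- outer(cc$g, dlogits)
    dbf <- dlogits
    dg <- as.vector(params$wf %*% dlogits)
    if (!is.null(params$fixed_norm)) dg <- dg / params$fixed_norm$sd
    npix2 <- nrow(cc$Z2)
    dA2 <- matrix(dg / npix2, npix2, length(dg), byrow = TRUE)
    dZ2 <- dA2 * leaky_relu_grad(cc$Z2)
    dw2 <- crossprod(cc$X2, dZ2)
    db2 <- colSums(dZ2)
    dX2 <- dZ2 %*% t(params$w2)
    h <- cc$H / 2; w <- cc$W / 2
    f1 <- ncol(params$w1)
    dP1 <- col2im_grad(dX2, cc$idx2, h, w, f1)
    dA1 <- unpool2_grad(dP1, cc$H, cc$W)
    dZ1 <- matrix(dA1, ncol = f1) * leaky_relu_grad(cc$Z1)
    dw1 <- crossprod(cc$X1, dZ1)
    db1 <- colSums(dZ1)
    list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2, wf = dwf, bf = dbf)
  }
  # data-dependent normalisation of the pooled features: one forward pass
  # over a few training samples fixes a per-filter affine transform so the
  # classifier head sees unit-scale inputs (the transform is frozen, not
  # trained)
  calibrate <- function(params, sample_inputs) {
    G <- t(vapply(sample_inputs,
                  function(x) forward(params, x)$cache$g,
                  numeric(n_filters2)))
    params$fixed_norm <- list(mu = colMeans(G),
                              sd = pmax(apply(G, 2, stats::sd), 1e-3))
    params
  }
  structure(list(init = init, forward = forward, backward = backward,
                 calibrate = calibrate, name = "surrogate_cnn"),
            class = "cad_backbone")
}

# global gradient-norm clipping
clip_grads <- function(grads, max_norm = 5) {
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(nrm) && nrm > max_norm) grads <- lapply(grads, `*`, max_norm / nrm)
  grads
}

adam_trainable <- function(params) setdiff(names(params), "fixed_norm")

adam_init <- function(params) {
  nms <- adam_trainable(params)
  list(m = lapply(params[nms], function(p) p * 0),
       v = lapply(params[nms], function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in adam_trainable(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Cross-validated finetuning of a backbone (Model-II)
#'
#' Per fold: a fresh backbone is initialised, trained on the nine
#' training folds for `config$epochs` epochs with Adam at the initial
#' learning rate, multiplying the learning rate by `lr_decay_gamma`
#' after each epoch, with per-sample augmentation; the held-out fold is
#' then scored with the softmax malignancy probability.
#'
#' @param rois a `lesion_roi_set`
#' @param folds a [make_folds()] assignment aligned with `rois`
#' @param config a [dl_config()]
#' @param backbone a backbone object (default [surrogate_cnn()])
#' @param model_id model identifier for the score table
#' @return a [score_table()]; per-fold, per-epoch mean training losses in
#'   attribute `"training_loss"`
#' @export
finetune_cv <- function(rois, folds, config = dl_config(),
                        backbone = surrogate_cnn(), model_id = "Model-II") {
  stopifnot(length(rois) == length(folds$fold))
  labels <- roi_labels(rois)
  ids <- roi_ids(rois)
  inputs <- lapply(rois, preprocess_patch, config = config)
  out <- vector("list", folds$k)
  loss_log <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    tr <- which(folds$fold != f)
    te <- which(folds$fold == f)
    if (!length(te) || !length(tr)) stop(sprintf("fold %d is empty", f))
    params <- backbone$init(config$input_size, config$channels,
                            derive_seed(config$rng_seed, f))
    if (!is.null(backbone$calibrate)) {
      params <- backbone$calibrate(params,
                                   inputs[tr[seq_len(min(16, length(tr)))]])
    }
    state <- adam_init(params)
    epoch_losses <- numeric(config$epochs)
    with_seed(derive_seed(config$rng_seed, 1000L + f), {
      for (epoch in seq_len(config$epochs)) {
        lr <- epoch_learning_rate(config, epoch)
        order_idx <- tr[sample.int(length(tr))]
        losses <- numeric(0)
        batches <- split(order_idx,
                         ceiling(seq_along(order_idx) / config$batch_size))
        for (batch in batches) {
          grads <- NULL
          bl <- 0
          for (i in batch) {
            xa <- augment_patch(inputs[[i]], config)
            y <- if (labels[i] == "malignant") c(0, 1) else c(1, 0)
            fwd <- backbone$forward(params, xa)
            bl <- bl - log(max(sum(fwd$probs * y), 1e-12))
            g <- backbone$backward(params, fwd, y)
            grads <- if (is.null(grads)) g else
              Map(`+`, grads, g)
          }
          grads <- lapply(grads, `/`, length(batch))
          grads <- clip_grads(grads, max_norm = 5)
          upd <- adam_step(params, grads, state, lr)
          params <- upd$params; state <- upd$state
          losses <- c(losses, bl / length(batch))
        }
        epoch_losses[epoch] <- mean(losses)
      }
    })
    loss_log[[f]] <- epoch_losses
    sc <- vapply(te, function(i)
      backbone$forward(params, inputs[[i]])$probs[2], 0)
    out[[f]] <- score_table(ids[te], model_id, f, labels[te],
                            pmin(pmax(sc, 0), 1))
  }
  res <- do.call(rbind, out)
  class(res) <- c("score_table", "data.frame")
  attr(res, "training_loss") <- loss_log
  res
}
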