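# --- patch pipeline and training protocol ----------------------------------

#' Training configuration
#'
#' Defaults follow the transfer-learning protocol: 50x50 patches, 15 per
#' image, Adam at learning rate 1e-3, 150 epochs, 5% of the images held
#' out for validation, augmentation by a random choice of {0, 90} degree
#' rotation plus an independent random horizontal flip.
#'
#' @param patch_size square patch width in pixels.
#' @param patches_per_image patches drawn per image.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param val_fraction fraction of *images* (not patches) held out for
#'   validation, in (0, 1); splitting by image avoids leakage between
#'   train and validation patches.
#' @param augment apply rotation/flip augmentation.
#' @param seed integer seed controlling patch positions, augmentation
#'   draws and batch shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(patch_size = 50, patches_per_image = 15,
                         learning_rate = 1e-3, epochs = 150, batch_size = 16,
                         val_fraction = 0.05, augment = TRUE, seed = 1) {
  patch_size <- as.integer(patch_size)
  if (patch_size < 1) stop("`patch_size` must be positive", call. = FALSE)
  if (patches_per_image < 1) stop("`patches_per_image` must be positive", call. = FALSE)
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("`val_fraction` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(patch_size = patch_size,
         patches_per_image = as.integer(patches_per_image),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), optimizer = "adam",
         val_fraction = val_fraction, augment = isTRUE(augment),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Transfer-learning configuration
#'
#' `final_layer_only` updates only the last convolution (the network's
#' output head — the all-convolutional architecture has no fully
#' connected layers); every other parameter tensor, batch-norm running
#' statistics included, is bit-identical before and after training.
#' `all_layers` fine-tunes the whole network.
#'
#' @param mode `"final_layer_only"` or `"all_layers"`.
#' @return An object of class `transfer_config`.
#' @export
transfer_config <- function(mode = c("final_layer_only", "all_layers")) {
  structure(list(mode = match.arg(mode)), class = "transfer_config")
}

rot90cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]

apply_augmentation <- function(patch, rotate90, hflip) {
  if (rotate90) patch <- rot90cw(patch)
  if (hflip) patch <- patch[, ncol(patch):1, drop = FALSE]
  patch
}

#' Extract residual training patches from one image pair
#'
#' Draws `patches_per_image` square patches at positions uniform over the
#' valid top-left corners, deterministic per `config$seed`. The training
#' target of each patch is the noise residual `noisy - clean`.
#' Augmentation (random {0, 90} degree rotation, independent random
#' horizontal flip) is applied identically to both members of a pair, so
#' the residual pairing is preserved.
#'
#' @param image the noisy [ct_image] (or matrix).
#' @param config a [train_config].
#' @param clean_ref the clean reference, same shape.
#' @return List of `list(noisy, residual)` pairs (HU-scale matrices of
#'   `patch_size` x `patch_size`).
#' @export
extract_patches <- function(image, config, clean_ref) {
  noisy <- if (is.ct_image(image)) image$pixels else image
  clean <- if (is.ct_image(clean_ref)) clean_ref$pixels else clean_ref
  check_same_shape(noisy, clean)
  ps <- config$patch_size
  d <- dim(noisy)
  if (ps > d[1] || ps > d[2]) {
    stop(sprintf("patch size %d exceeds image size %dx%d", ps, d[1], d[2]),
         call. = FALSE)
  }
  with_seed(config$seed, {
    lapply(seq_len(config$patches_per_image), function(i) {
      r0 <- sample.int(d[1] - ps + 1L, 1L)
      c0 <- sample.int(d[2] - ps + 1L, 1L)
      np <- noisy[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
      cp <- clean[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
      if (config$augment) {
        rot <- stats::runif(1) < 0.5
        flip <- stats::runif(1) < 0.5
        np <- apply_augmentation(np, rot, flip)
        cp <- apply_augmentation(cp, rot, flip)
      }
      list(noisy = np, residual = np - cp)
    })
  })
}

# stack a list of (noisy, residual) HU pairs into normalized 4-D tensors
stack_patches <- function(pairs, norm_window) {
  ps <- nrow(pairs[[1]]$noisy)
  n <- length(pairs)
  x <- array(0, c(ps, ps, 1L, n))
  r <- array(0, c(ps, ps, 1L, n))
  scale <- norm_window[2] - norm_window[1]
  for (i in seq_len(n)) {
    x[, , 1L, i] <- normalize_hu(pairs[[i]]$noisy, norm_window)
    r[, , 1L, i] <- pairs[[i]]$residual / scale
  }
  list(x = x, r = r)
}

# --- Adam ------------------------------------------------------------------

adam_state_init <- function(model, trainable) {
  lapply(seq_along(model$layers), function(l) {
    if (!trainable[l]) return(NULL)
    layer <- model$layers[[l]]
    st <- list(mW = layer$W * 0, vW = layer$W * 0,
               mb = layer$b * 0, vb = layer$b * 0)
    if (layer$has_bn) {
      st$mg <- layer$gamma * 0
      st$vg <- layer$gamma * 0
      st$mB <- layer$beta * 0
      st$vB <- layer$beta * 0
    }
    st
  })
}

adam_update <- function(theta, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train a residual denoising network on patch pairs
#'
#' Mini-batch Adam on the mean-squared error between the predicted and
#' true noise residual. Batch order is reshuffled every epoch
#' (deterministically from `config$seed`). With `trainable`, parameters
#' of frozen layers — batch-norm running statistics included — are left
#' bit-identical; frozen batch-norm layers run with their stored running
#' statistics.
#'
#' @param model a `dncnn_model`.
#' @param pairs list of `list(noisy, residual)` HU-scale patch pairs.
#' @param config a [train_config].
#' @param val_pairs optional held-out pairs; validation loss is logged
#'   per epoch.
#' @param trainable logical vector, one entry per layer.
#' @return `list(model, history)`; `history` is a data.frame with one
#'   row per epoch (`epoch`, `train_loss`, `val_loss`).
#' @export
train_dncnn <- function(model, pairs, config, val_pairs = NULL,
                        trainable = rep(TRUE, length(model$layers))) {
  stopifnot(is.dncnn_model(model), length(pairs) >= 1)
  if (length(trainable) != length(model$layers)) {
    stop("`trainable` must have one entry per layer", call. = FALSE)
  }
  if (!any(trainable)) stop("at least one layer must be trainable", call. = FALSE)
  dat <- stack_patches(pairs, model$norm_window)
  val <- if (!is.null(val_pairs) && length(val_pairs) > 0) {
    stack_patches(val_pairs, model$norm_window)
  } else {
    NULL
  }
  n <- dim(dat$x)[4]
  state <- adam_state_init(model, trainable)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  t_step <- 0L
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        sel <- ord[s:min(s + config$batch_size - 1L, n)]
        xb <- dat$x[, , , sel, drop = FALSE]
        rb <- dat$r[, , , sel, drop = FALSE]
        lg <- dncnn_loss_grad(model, xb, rb, trainable = trainable)
        epoch_loss <- epoch_loss + lg$loss * length(sel)
        t_step <- t_step + 1L
        for (l in which(trainable)) {
          g <- lg$grads[[l]]
          layer <- model$layers[[l]]
          up <- adam_update(layer$W, g$dW, state[[l]]$mW, state[[l]]$vW,
                            config$learning_rate, t_step)
          layer$W <- up$theta
          state[[l]]$mW <- up$m
          state[[l]]$vW <- up$v
          up <- adam_update(layer$b, g$db, state[[l]]$mb, state[[l]]$vb,
                            config$learning_rate, t_step)
          layer$b <- up$theta
          state[[l]]$mb <- up$m
          state[[l]]$vb <- up$v
          if (layer$has_bn) {
            up <- adam_update(layer$gamma, g$dgamma, state[[l]]$mg, state[[l]]$vg,
                              config$learning_rate, t_step)
            layer$gamma <- up$theta
            state[[l]]$mg <- up$m
            state[[l]]$vg <- up$v
            up <- adam_update(layer$beta, g$dbeta, state[[l]]$mB, state[[l]]$vB,
                              config$learning_rate, t_step)
            layer$beta <- up$theta
            state[[l]]$mB <- up$m
            state[[l]]$vB <- up$v
            layer$run_mean <- g$run_update$run_mean
            layer$run_var <- g$run_update$run_var
          }
          model$layers[[l]] <- layer
        }
      }
      vl <- if (is.null(val)) NA_real_ else dncnn_loss(model, val$x, val$r)
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = epoch_loss / n, val_loss = vl
      ))
    }
  })
  list(model = model, history = history)
}

# --- synthetic grayscale textures (pretraining corpus stand-in) -------------

#' Random grayscale texture image
#'
#' Piecewise-smooth synthetic texture on the 0-255 gray scale: a random
#' linear ramp, a few random soft (Gaussian-blob) structures and random
#' constant-intensity rectangles, lightly smoothed. These emulate the
#' mixture of flat regions, edges and gradients a natural-image
#' pretraining corpus provides for learning generic noise removal.
#'
#' @param size square image width in pixels.
#' @param seed integer seed.
#' @return `size` x `size` matrix with values in `[0, 255]`.
#' @export
random_texture_image <- function(size = 80, seed = 1) {
  with_seed(seed, {
    rows <- matrix(seq_len(size), size, size)
    cols <- matrix(seq_len(size), size, size, byrow = TRUE)
    g <- matrix(stats::runif(1, 40, 216), size, size)
    ang <- stats::runif(1, 0, 2 * pi)
    g <- g + (cos(ang) * rows + sin(ang) * cols) * stats::runif(1, -1, 1)
    for (b in seq_len(4)) { # soft blobs
      cy <- stats::runif(1, 1, size)
      cx <- stats::runif(1, 1, size)
      s <- stats::runif(1, size / 16, size / 4)
      g <- g + stats::runif(1, -80, 80) * exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * s^2))
    }
    for (b in seq_len(3)) { # hard-edged rectangles
      r0 <- sample.int(size, 1)
      c0 <- sample.int(size, 1)
      r1 <- min(size, r0 + sample.int(size %/% 2, 1))
      c1 <- min(size, c0 + sample.int(size %/% 2, 1))
      g[r0:r1, c0:c1] <- g[r0:r1, c0:c1] + stats::runif(1, -60, 60)
    }
    pmin(pmax(g, 0), 255)
  })
}

#' Pretrain on synthetic textures with white Gaussian noise
#'
#' Desk-scale surrogate for pretraining a residual denoiser on a natural
#' grayscale image corpus: `n_images` synthetic textures are corrupted
#' with additive white Gaussian noise of SD `sigma` (0-255 scale, default
#' 25) and the network is trained to predict the residual under MSE loss.
#' The gray scale `[0, 255]` is mapped to the network's `[0, 1]` input
#' range.
#'
#' @param spec a [dncnn_spec].
#' @param config a [train_config].
#' @param n_images number of texture images.
#' @param sigma noise SD on the 0-255 scale.
#' @param image_size texture image width (>= `config$patch_size`).
#' @param seed integer seed (weights, textures, noise).
#' @return `list(model, history)` as for [train_dncnn()].
#' @export
pretrain_stand_in <- function(spec, config, n_images = 40, sigma = 25,
                              image_size = 80, seed = 1) {
  stopifnot(inherits(spec, "dncnn_spec"), n_images >= 1)
  model <- build_dncnn(spec, seed = seed, norm_window = c(0, 255))
  n_val <- max(1L, ceiling(config$val_fraction * n_images))
  pairs <- list()
  val_pairs <- list()
  for (i in seq_len(n_images)) {
    clean <- random_texture_image(image_size, seed = seed + 1000L + i)
    noisy <- clean + with_seed(seed + 2000L + i, matrix(
      stats::rnorm(length(clean), sd = sigma), nrow(clean), ncol(clean)
    ))
    cfg_i <- config
    cfg_i$seed <- config$seed + 3000L + i
    pp <- extract_patches(noisy, cfg_i, clean)
    if (i <= n_val) val_pairs <- c(val_pairs, pp) else pairs <- c(pairs, pp)
  }
  train_dncnn(model, pairs, config, val_pairs = val_pairs)
}

# --- transfer learning ------------------------------------------------------

#' Build a dose-reduction transfer corpus
#'
#' Simulates every clean base image at every dose level of the schedule:
#' `length(base_images) * length(schedule)` training pairs. With the
#' standard protocol — 100 base images and the 10-step schedule — this
#' yields 1000 training images.
#'
#' @param base_images list of clean [ct_image]s.
#' @param schedule dose fractions (see [dose_schedule()]).
#' @param baseline_noise_sd,mtf simulation settings.
#' @param seed integer; per-pair seeds are derived deterministically.
#' @return List of `list(noisy, clean)` pairs of [ct_image]s.
#' @export
build_transfer_corpus <- function(base_images, schedule = dose_schedule(),
                                  baseline_noise_sd = 10, mtf = default_mtf(),
                                  seed = 1) {
  stopifnot(length(base_images) >= 1, length(schedule) >= 1)
  out <- vector("list", length(base_images) * length(schedule))
  k <- 0L
  for (i in seq_along(base_images)) {
    for (j in seq_along(schedule)) {
      k <- k + 1L
      cfg <- dose_sim_config(schedule[j], baseline_noise_sd = baseline_noise_sd,
                             mtf = mtf,
                             seed = derive_seed(seed, sprintf("corpus-%d-%d", i, j)))
      out[[k]] <- list(noisy = simulate_low_dose(base_images[[i]], cfg),
                       clean = base_images[[i]])
    }
  }
  out
}

#' Adapt a pretrained model to dose-reduction noise
#'
#' Splits the corpus into train/validation by image (`val_fraction`),
#' builds the patch stream with [extract_patches()], and continues
#' training. In `final_layer_only` mode every parameter tensor except the
#' last convolution's is bit-identical before and after. Per-epoch train
#' and validation losses are logged.
#'
#' @param model a pretrained `dncnn_model`.
#' @param corpus list of `list(noisy, clean)` image pairs (from
#'   [build_transfer_corpus()] or equivalent).
#' @param tconfig a [transfer_config].
#' @param config a [train_config].
#' @return `list(model, history)` as for [train_dncnn()].
#' @export
transfer_learn <- function(model, corpus, tconfig = transfer_config(),
                           config = train_config()) {
  stopifnot(is.dncnn_model(model), inherits(tconfig, "transfer_config"))
  if (length(corpus) == 0) stop("`corpus` must be nonempty", call. = FALSE)
  depth <- length(model$layers)
  trainable <- if (tconfig$mode == "final_layer_only") {
    c(rep(FALSE, depth - 1L), TRUE)
  } else {
    rep(TRUE, depth)
  }
  # adapt the intensity mapping to the CT window without touching weights
  model$norm_window <- c(-1024, 1024)
  n <- length(corpus)
  n_val <- min(n - 1L, max(1L, ceiling(config$val_fraction * n)))
  val_idx <- with_seed(config$seed + 7L, sample.int(n, n_val))
  pairs <- list()
  val_pairs <- list()
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, sprintf("patches-%d", i))
    pp <- extract_patches(corpus[[i]]$noisy, cfg_i, corpus[[i]]$clean)
    if (i %in% val_idx) val_pairs <- c(val_pairs, pp) else pairs <- c(pairs, pp)
  }
  train_dncnn(model, pairs, config, val_pairs = val_pairs,
              trainable = trainable)
}
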