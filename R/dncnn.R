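# --- residual-learning denoising CNN ---------------------------------------
#
# The network maps a noisy image to its *noise residual*; the denoised
# image is input minus prediction. Layer stack:
#   [conv 3x3 + ReLU] + (depth-2) x [conv 3x3 + BN + ReLU] + [conv 3x3 -> 1]
# Convolutions use zero ("same") padding; batch normalization sits between
# the convolution and the ReLU of every middle layer. Implemented with
# im2col + GEMM so all heavy arithmetic runs in BLAS.
#
# Tensors are numeric arrays with dims (H, W, C, N). Weights of a layer
# are stored as a (k*k*Cin) x Cout matrix whose row order matches the
# col-major flattening of a (k, k, Cin) block, i.e. row = (c-1)*k^2 + kk
# with kk = (dj-1)*k + di.

#' Network architecture specification
#'
#' Defaults follow the reference residual denoiser: 20 convolution layers
#' of 64 filters, 3x3 kernels, batch normalization in the middle layers.
#' The receptive field of the stack is `2 * depth + 1` pixels.
#'
#' @param depth total number of convolution layers (>= 3).
#' @param filters feature channels per middle layer.
#' @param kernel odd kernel width.
#' @param uses_batch_norm batch normalization in middle layers.
#' @return An object of class `dncnn_spec`.
#' @export
dncnn_spec <- function(depth = 20, filters = 64, kernel = 3,
                       uses_batch_norm = TRUE) {
  depth <- as.integer(depth)
  filters <- as.integer(filters)
  kernel <- as.integer(kernel)
  if (depth < 3) stop("`depth` must be at least 3", call. = FALSE)
  if (kernel %% 2L == 0L) stop("`kernel` must be odd", call. = FALSE)
  if (filters < 1) stop("`filters` must be positive", call. = FALSE)
  structure(
    list(depth = depth, filters = filters, kernel = kernel,
         uses_batch_norm = isTRUE(uses_batch_norm), residual_output = TRUE),
    class = "dncnn_spec"
  )
}

#' @rdname dncnn_spec
#' @param spec a `dncnn_spec`.
#' @return `receptive_field`: the receptive field width in pixels.
#' @export
receptive_field <- function(spec) {
  stopifnot(inherits(spec, "dncnn_spec"))
  spec$depth * (spec$kernel - 1L) + 1L
}

#' Build a residual denoising network
#'
#' Weights use He (fan-in) initialization, biases zero, BN scale 1 /
#' shift 0; initialization is deterministic given `seed`. The model
#' predicts the noise residual of its input in normalized intensity
#' units; see [denoise_with_model()].
#'
#' @param spec a [dncnn_spec].
#' @param seed integer seed for the weight draw.
#' @param norm_window length-2 HU window mapped to `[0, 1]` at the
#'   network boundary (see [normalize_hu()]).
#' @return An object of class `dncnn_model`.
#' @export
build_dncnn <- function(spec, seed = 1, norm_window = c(-1024, 1024)) {
  stopifnot(inherits(spec, "dncnn_spec"))
  k2 <- spec$kernel^2
  layers <- with_seed(seed, lapply(seq_len(spec$depth), function(l) {
    cin <- if (l == 1) 1L else spec$filters
    cout <- if (l == spec$depth) 1L else spec$filters
    layer <- list(
      W = matrix(stats::rnorm(k2 * cin * cout, sd = sqrt(2 / (k2 * cin))),
                 k2 * cin, cout),
      b = numeric(cout),
      cin = cin, cout = cout,
      has_bn = spec$uses_batch_norm && l > 1 && l < spec$depth,
      has_relu = l < spec$depth
    )
    if (layer$has_bn) {
      layer$gamma <- rep(1, cout)
      layer$beta <- numeric(cout)
      layer$run_mean <- numeric(cout)
      layer$run_var <- rep(1, cout)
    }
    layer
  }))
  structure(
    list(spec = spec, layers = layers, norm_window = as.numeric(norm_window),
         bn_momentum = 0.9, bn_eps = 1e-5),
    class = "dncnn_model"
  )
}

#' @rdname build_dncnn
#' @param x object to test.
#' @export
is.dncnn_model <- function(x) inherits(x, "dncnn_model")

#' HU <-> normalized intensity
#'
#' The network operates on intensities in `[0, 1]`; CT images are mapped
#' linearly from the model's HU window (default `[-1024, 1024]`, width
#' 2048 HU). Residuals are differences, so they scale by the window width
#' with no offset.
#'
#' @param hu,z values to convert.
#' @param window length-2 HU window.
#' @return Converted values.
#' @export
normalize_hu <- function(hu, window = c(-1024, 1024)) {
  (hu - window[1]) / (window[2] - window[1])
}

#' @rdname normalize_hu
#' @export
denormalize_hu <- function(z, window = c(-1024, 1024)) {
  z * (window[2] - window[1]) + window[1]
}

# --- conv layer forward/backward -------------------------------------------
#
# Activations travel between layers as (npix * N) x C matrices, rows
# ordered pixel-within-sample fastest, then sample — the natural
# flattening of an (H, W, C = 1, N) array and the layout both the GEMMs
# and batch norm want, so no transposes occur on the hot path. The
# spatial structure enters only through precomputed gather indices into
# a zero-padded per-channel stack.

# spatial geometry of one (H, W, N, k) configuration
conv_geometry <- function(h, w, n, k) {
  list(h = as.integer(h), w = as.integer(w), n = as.integer(n),
       k = as.integer(k), k2 = as.integer(k * k), npix = as.integer(h * w))
}

conv_forward <- function(a, layer, geom) {
  list(out = conv_fwd_cpp(a, layer$W, layer$b, geom$h, geom$w, geom$n, geom$k),
       input = a)
}

# weights rearranged for the input-gradient convolution: spatially
# flipped taps, in/out channels swapped
flip_weights <- function(layer, k2) {
  arr <- array(layer$W, c(k2, layer$cin, layer$cout))
  matrix(aperm(arr[k2:1, , , drop = FALSE], c(1, 3, 2)),
         k2 * layer$cout, layer$cin)
}

# input gradient: correlation of dY with the flipped kernels
conv_backward_input <- function(dy, layer, geom) {
  conv_bwd_cpp(dy, dy, flip_weights(layer, geom$k2), geom$h, geom$w, geom$n,
               geom$k, need_dw = FALSE, need_dx = TRUE)$dx
}

# full gradient; cache$input is the layer's forward input
conv_backward <- function(dy, layer, cache, geom, need_dx = TRUE) {
  res <- conv_bwd_cpp(cache$input, dy, flip_weights(layer, geom$k2),
                      geom$h, geom$w, geom$n, geom$k,
                      need_dw = TRUE, need_dx = need_dx)
  list(dx = res$dx, dW = res$dW, db = colSums(dy))
}

# --- batch norm forward/backward -------------------------------------------
# x: (npix*N) x C; normalization is per channel over all rows.

bn_forward <- function(m, layer, eps, momentum, training) {
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m^2) - mu^2 # population variance over (H, W, N)
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  inv <- 1 / sqrt(va + eps)
  nrm <- nrow(m)
  xhat <- (m - rep(mu, each = nrm)) * rep(inv, each = nrm)
  y <- xhat * rep(layer$gamma, each = nrm) + rep(layer$beta, each = nrm)
  upd <- NULL
  if (training) {
    upd <- list(run_mean = momentum * layer$run_mean + (1 - momentum) * mu,
                run_var = momentum * layer$run_var + (1 - momentum) * va)
  }
  list(out = y, xhat = xhat, inv = inv, run_update = upd, training = training)
}

bn_backward <- function(dy, layer, cache) {
  nrm <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  g_inv <- layer$gamma * cache$inv
  dx <- if (cache$training) {
    # batch-statistics path:
    # dx = g*inv * (dy - mean(dy) - xhat * mean(dy * xhat)) per channel
    (dy -
       rep(dbeta / nrm, each = nrm) -
       cache$xhat * rep(dgamma / nrm, each = nrm)) *
      rep(g_inv, each = nrm)
  } else {
    # frozen layer: running statistics are constants
    dy * rep(g_inv, each = nrm)
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- full network forward/backward -----------------------------------------

# x: (H, W, 1, N) normalized intensities -> predicted residual (H, W, 1, N)
# training: TRUE uses batch statistics for trainable BN layers.
# trainable: logical vector per layer; frozen BN layers always run in
# inference mode so their state stays bit-identical.
dncnn_forward <- function(model, x, training = FALSE,
                          trainable = rep(TRUE, length(model$layers)),
                          keep_cache = FALSE, cache_from = 1L) {
  d <- dim(x)
  geom <- conv_geometry(d[1], d[2], d[4], model$spec$kernel)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  a <- matrix(as.vector(x), geom$npix * geom$n, 1L)
  for (l in seq_along(model$layers)) {
    layer <- model$layers[[l]]
    keep_l <- keep_cache && l >= cache_from
    input_l <- a
    cv <- conv_forward(a, layer, geom)
    a <- cv$out
    bn <- NULL
    if (layer$has_bn) {
      bn <- bn_forward(a, layer, model$bn_eps, model$bn_momentum,
                       training = training && trainable[l])
      a <- bn$out
    }
    pre_relu <- NULL
    if (layer$has_relu) {
      if (keep_l) pre_relu <- a
      a <- pmax(a, 0)
    }
    if (keep_l) {
      caches[[l]] <- list(
        input = if (trainable[l]) input_l else NULL,
        bn = if (is.null(bn)) NULL else bn[c("xhat", "inv", "run_update", "training")],
        pre_relu = pre_relu
      )
    }
  }
  list(out = array(a, c(d[1], d[2], 1L, d[4])), caches = caches, geom = geom)
}

# Mean-squared-error loss on the residual and full backward pass.
# Returns loss, per-layer gradients (NULL entries for frozen layers) and
# BN running-stat updates for trainable BN layers.
dncnn_loss_grad <- function(model, x, target,
                            trainable = rep(TRUE, length(model$layers))) {
  cache_from <- min(which(trainable)) # nothing below the first trainable layer moves
  fw <- dncnn_forward(model, x, training = TRUE, trainable = trainable,
                      keep_cache = TRUE, cache_from = cache_from)
  pred <- fw$out
  diff <- pred - target
  loss <- mean(diff^2)
  geom <- fw$geom
  dy <- matrix(as.vector(2 * diff / length(diff)), geom$npix * geom$n, 1L)
  grads <- vector("list", length(model$layers))
  for (l in rev(seq_along(model$layers))) {
    if (l < cache_from) break
    layer <- model$layers[[l]]
    cache <- fw$caches[[l]]
    if (layer$has_relu) {
      dy <- dy * (cache$pre_relu > 0)
    }
    g <- list()
    if (layer$has_bn) {
      bb <- bn_backward(dy, layer, cache$bn)
      dy <- bb$dx
      if (trainable[l]) {
        g$dgamma <- bb$dgamma
        g$dbeta <- bb$dbeta
        g$run_update <- cache$bn$run_update
      }
    }
    if (trainable[l]) {
      cb <- conv_backward(dy, layer, cache, geom, need_dx = l > cache_from)
      g$dW <- cb$dW
      g$db <- cb$db
      dy <- cb$dx
    } else if (l > cache_from) {
      dy <- conv_backward_input(dy, layer, geom)
    }
    grads[[l]] <- if (trainable[l]) g else NULL
    fw$caches[[l]] <- NULL # release memory as we go
  }
  list(loss = loss, grads = grads)
}

# forward-only loss (validation)
dncnn_loss <- function(model, x, target) {
  pred <- dncnn_forward(model, x, training = FALSE)$out
  mean((pred - target)^2)
}

#' Predict the noise residual of a CT image
#'
#' Runs the network on the full image (no tiling) and returns the
#' predicted noise residual on the HU scale.
#'
#' @param model a `dncnn_model`.
#' @param image a [ct_image] or numeric matrix.
#' @return Numeric matrix of residual HU values, same shape as the input.
#' @export
predict_residual <- function(model, image) {
  stopifnot(is.dncnn_model(model))
  px <- if (is.ct_image(image)) image$pixels else image
  z <- normalize_hu(px, model$norm_window)
  x <- array(z, c(dim(px), 1L, 1L))
  r <- dncnn_forward(model, x, training = FALSE)$out
  matrix(r, dim(px)[1], dim(px)[2]) * (model$norm_window[2] - model$norm_window[1])
}

#' Denoise a CT image with a residual model
#'
#' `output = input - predicted residual`. Intensities are normalized to
#' `[0, 1]` over the model's HU window before the network and
#' de-normalized after; since the residual is a difference, the identity
#' `denoised + residual = input` holds to floating-point precision.
#'
#' @param model a `dncnn_model`.
#' @param image a [ct_image] or numeric matrix.
#' @return Same type as the input.
#' @export
denoise_with_model <- function(model, image) {
  px <- if (is.ct_image(image)) image$pixels else image
  out <- px - predict_residual(model, image)
  if (is.ct_image(image)) {
    set_pixels(image, out, image_id = paste0(image$image_id, "-dncnn"))
  } else {
    out
  }
}

#' Save / load a model checkpoint
#'
#' Standard R serialization (RDS) of the full model object.
#'
#' @param model a `dncnn_model`.
#' @param path checkpoint file.
#' @return `load_dncnn`: the restored model.
#' @export
save_dncnn <- function(model, path) {
  stopifnot(is.dncnn_model(model))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dncnn
#' @export
load_dncnn <- function(path) {
  model <- readRDS(path)
  if (!is.dncnn_model(model)) stop("not a dncnn_model checkpoint", call. = FALSE)
  model
}
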