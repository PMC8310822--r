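# tiny configurations keep these tests fast; the network code is size-blind

tiny_spec <- function() dncnn_spec(depth = 3, filters = 6)

tiny_train_cfg <- function(epochs = 4, seed = 1) {
  train_config(patch_size = 16, patches_per_image = 10, epochs = epochs,
               batch_size = 8, val_fraction = 0.2, seed = seed)
}

# ~200 HU of structure + known noise, as 16x16-croppable toy images
toy_pair <- function(seed, size = 40, noise_sd = 60) {
  clean <- matrix(0, size, size)
  clean[10:25, 12:30] <- 200
  noisy <- clean + with(list(), {
    set.seed(seed)
    matrix(rnorm(size * size, sd = noise_sd), size, size)
  })
  list(noisy = noisy, clean = clean)
}

test_that("network spec validates and exposes the receptive field", {
  spec <- dncnn_spec()
  expect_equal(spec$depth, 20)
  expect_equal(spec$filters, 64)
  expect_equal(receptive_field(spec), 41) # 2 * depth + 1 for 3x3 kernels
  expect_equal(receptive_field(dncnn_spec(depth = 5)), 11)
  expect_error(dncnn_spec(depth = 2), "at least 3")
  expect_error(dncnn_spec(kernel = 4), "odd")
})

test_that("the default architecture has 20 conv layers, 18 with batch norm", {
  model <- build_dncnn(dncnn_spec(), seed = 1)
  expect_length(model$layers, 20)
  expect_equal(sum(vapply(model$layers, function(l) l$has_bn, logical(1))), 18)
  expect_false(model$layers[[1]]$has_bn)
  expect_false(model$layers[[20]]$has_bn)
  expect_false(model$layers[[20]]$has_relu)
  expect_equal(model$layers[[1]]$cin, 1)
  expect_equal(model$layers[[20]]$cout, 1)
})

test_that("weight initialization is deterministic given the seed", {
  m1 <- build_dncnn(tiny_spec(), seed = 7)
  m2 <- build_dncnn(tiny_spec(), seed = 7)
  m3 <- build_dncnn(tiny_spec(), seed = 8)
  expect_identical(m1$layers, m2$layers)
  expect_false(identical(m1$layers[[1]]$W, m3$layers[[1]]$W))
})

test_that("the convolution kernel matches a naive same-padded convolution", {
  ns <- asNamespace("ldctbench")
  set.seed(5)
  h <- 7; w <- 6; n <- 2; cin <- 3; cout <- 2; k <- 3
  a <- matrix(rnorm(h * w * n * cin), h * w * n, cin)
  W <- matrix(rnorm(k * k * cin * cout), k * k * cin, cout)
  b <- rnorm(cout)
  got <- ns$conv_fwd_cpp(a, W, b, h, w, n, k)
  # naive reference: zero-padded correlation, weights as (k, k, cin, cout)
  Warr <- array(W, c(k, k, cin, cout))
  for (s in 1:n) {
    for (c in 1:cin) {
      x <- matrix(a[(s - 1) * h * w + 1:(h * w), c], h, w)
      xp <- matrix(0, h + 2, w + 2)
      xp[2:(h + 1), 2:(w + 1)] <- x
      for (co in 1:cout) {
        ref <- matrix(0, h, w)
        for (i in 1:h) for (j in 1:w) {
          ref[i, j] <- sum(xp[i:(i + 2), j:(j + 2)] * Warr[, , c, co])
        }
        contrib <- matrix(got[(s - 1) * h * w + 1:(h * w), co], h, w)
        # accumulate references over channels; compare at the end of c loop
        if (c == 1) assign(paste0("acc", s, co), ref) else
          assign(paste0("acc", s, co), get(paste0("acc", s, co)) + ref)
        if (c == cin) expect_equal(contrib, get(paste0("acc", s, co)) + b[co],
                                   tolerance = 1e-12)
      }
    }
  }
})

test_that("analytic gradients agree with numeric differentiation", {
  ns <- asNamespace("ldctbench")
  model <- build_dncnn(dncnn_spec(depth = 3, filters = 4), seed = 42)
  set.seed(7)
  x <- array(runif(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  r <- array(rnorm(6 * 6 * 1 * 2, sd = 0.1), c(6, 6, 1, 2))
  lg <- ns$dncnn_loss_grad(model, x, r)
  eps <- 1e-6
  for (l in 1:3) {
    for (i in sample(length(model$layers[[l]]$W), 4)) {
      m1 <- model; m1$layers[[l]]$W[i] <- m1$layers[[l]]$W[i] + eps
      m2 <- model; m2$layers[[l]]$W[i] <- m2$layers[[l]]$W[i] - eps
      gn <- (ns$dncnn_loss_grad(m1, x, r)$loss -
               ns$dncnn_loss_grad(m2, x, r)$loss) / (2 * eps)
      expect_equal(lg$grads[[l]]$dW[i], gn, tolerance = 1e-5)
    }
  }
  # batch-norm scale/shift of the middle layer
  for (i in 1:2) {
    m1 <- model; m1$layers[[2]]$gamma[i] <- m1$layers[[2]]$gamma[i] + eps
    m2 <- model; m2$layers[[2]]$gamma[i] <- m2$layers[[2]]$gamma[i] - eps
    gn <- (ns$dncnn_loss_grad(m1, x, r)$loss -
             ns$dncnn_loss_grad(m2, x, r)$loss) / (2 * eps)
    expect_equal(lg$grads[[2]]$dgamma[i], gn, tolerance = 1e-5)
  }
})

test_that("residual identity: denoised plus predicted residual reconstructs the input", {
  model <- build_dncnn(tiny_spec(), seed = 3)
  img <- test_abdomen(48, seed = 2)
  res <- predict_residual(model, img)
  den <- denoise_with_model(model, img)
  expect_lt(max(abs(den$pixels + res - img$pixels)), 1e-4)
})

test_that("a zero-output-head model denoises to the identity", {
  model <- build_dncnn(tiny_spec(), seed = 3)
  last <- length(model$layers)
  model$layers[[last]]$W[] <- 0
  model$layers[[last]]$b[] <- 0
  img <- test_abdomen(32, seed = 9)
  expect_equal(denoise_with_model(model, img)$pixels, img$pixels,
               tolerance = 1e-10)
  expect_true(all(predict_residual(model, img) == 0))
})

test_that("patch extraction honours count, bounds, determinism and pairing", {
  img <- test_abdomen(96, seed = 1)
  clean <- test_abdomen(96, seed = 1, noise_sd = 0)
  cfg <- train_config(patch_size = 50, patches_per_image = 15, seed = 5)
  pairs <- extract_patches(img, cfg, clean)
  expect_length(pairs, 15)
  for (p in pairs) {
    expect_equal(dim(p$noisy), c(50, 50))
    expect_equal(dim(p$residual), c(50, 50))
    expect_true(all(is.finite(p$noisy)))
  }
  expect_identical(extract_patches(img, cfg, clean), pairs)
  cfg2 <- cfg; cfg2$seed <- 6
  expect_false(identical(extract_patches(img, cfg2, clean), pairs))
  # clean reference equal to the image -> all-zero residuals, augmented or not
  same <- extract_patches(img, cfg, img)
  expect_true(all(vapply(same, function(p) all(p$residual == 0), logical(1))))
  # the paper-sized protocol: 350x250 crop accepts 50x50 patches
  big <- ct_image(matrix(rnorm(350 * 250), 350, 250))
  expect_length(extract_patches(big, cfg, big), 15)
  expect_error(extract_patches(ct_image(matrix(0, 20, 20)), cfg,
                               ct_image(matrix(0, 20, 20))), "exceeds")
})

test_that("augmentation transforms noisy and clean members identically", {
  img <- test_abdomen(64, seed = 4)
  clean <- test_abdomen(64, seed = 4, noise_sd = 0)
  cfg <- train_config(patch_size = 20, patches_per_image = 20, seed = 11)
  pairs <- extract_patches(img, cfg, clean)
  full_res <- img$pixels - clean$pixels
  for (p in pairs) {
    # the residual of an augmented pair is an augmented sub-block of the
    # full residual field: its values must occur in the full field
    expect_true(all(round(p$residual, 9) %in% round(full_res, 9)))
  }
})

test_that("training reduces the residual loss and is seed-reproducible", {
  pairs <- lapply(1:3, function(s) {
    tp <- toy_pair(s)
    extract_patches(tp$noisy, tiny_train_cfg(seed = s), tp$clean)
  })
  pairs <- do.call(c, pairs)
  model <- build_dncnn(tiny_spec(), seed = 2)
  out1 <- train_dncnn(model, pairs, tiny_train_cfg(epochs = 5, seed = 3))
  expect_lt(tail(out1$history$train_loss, 1), out1$history$train_loss[1])
  out2 <- train_dncnn(model, pairs, tiny_train_cfg(epochs = 5, seed = 3))
  expect_identical(out1$model$layers, out2$model$layers)
  expect_identical(out1$history, out2$history)
})

test_that("final_layer_only freezing is bit-exact outside the output head", {
  tp <- lapply(1:4, function(s) {
    pair <- toy_pair(s)
    list(noisy = ct_image(pair$noisy), clean = ct_image(pair$clean))
  })
  model <- build_dncnn(dncnn_spec(depth = 4, filters = 6), seed = 5)
  out <- transfer_learn(model, tp, transfer_config("final_layer_only"),
                        tiny_train_cfg(epochs = 3, seed = 7))
  n <- length(model$layers)
  for (l in seq_len(n - 1)) {
    expect_identical(out$model$layers[[l]], model$layers[[l]])
  }
  expect_false(identical(out$model$layers[[n]]$W, model$layers[[n]]$W))
})

test_that("fine-tuning all layers fits at least as well as the frozen head", {
  tp <- lapply(1:6, function(s) {
    pair <- toy_pair(s)
    list(noisy = ct_image(pair$noisy), clean = ct_image(pair$clean))
  })
  model <- build_dncnn(dncnn_spec(depth = 4, filters = 6), seed = 5)
  frozen <- transfer_learn(model, tp, transfer_config("final_layer_only"),
                           tiny_train_cfg(epochs = 6, seed = 7))
  full <- transfer_learn(model, tp, transfer_config("all_layers"),
                         tiny_train_cfg(epochs = 6, seed = 7))
  expect_lte(tail(full$history$val_loss, 1), tail(frozen$history$val_loss, 1))
})

test_that("pretraining on clean targets drives residual predictions toward zero", {
  cfg <- train_config(patch_size = 16, patches_per_image = 12, epochs = 15,
                      batch_size = 8, val_fraction = 0.15, seed = 2)
  out <- pretrain_stand_in(tiny_spec(), cfg, n_images = 10, sigma = 0,
                           image_size = 24, seed = 4)
  untrained <- build_dncnn(tiny_spec(), seed = 4, norm_window = c(0, 255))
  probe <- random_texture_image(24, seed = 99)
  expect_lt(mean(abs(predict_residual(out$model, probe))),
            mean(abs(predict_residual(untrained, probe))))
})

test_that("pretraining reduces loss over epochs and denoises unseen textures", {
  cfg <- train_config(patch_size = 16, patches_per_image = 12, epochs = 40,
                      batch_size = 8, val_fraction = 0.15, seed = 2)
  out <- pretrain_stand_in(dncnn_spec(depth = 4, filters = 8), cfg,
                           n_images = 12, sigma = 25, image_size = 24, seed = 6)
  h <- out$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_true(all(is.finite(h$val_loss)))
  # held-out sigma = 25 evaluation against the identity baseline
  clean <- random_texture_image(48, seed = 1234)
  set.seed(77)
  noisy <- clean + matrix(rnorm(length(clean), sd = 25), nrow(clean))
  den <- noisy - predict_residual(out$model, noisy)
  expect_lt(mse(den, clean), mse(noisy, clean))
})

test_that("the transfer corpus has one entry per image-dose combination", {
  base <- lapply(1:3, function(i) test_abdomen(40, seed = i))
  sched <- c(0.75, 0.5, 0.1, 0.05)
  corpus <- build_transfer_corpus(base, sched, seed = 2)
  expect_length(corpus, 12)
  expect_true(all(vapply(corpus, function(p)
    identical(dim(p$noisy$pixels), dim(p$clean$pixels)), logical(1))))
  # clean member is the unmodified base image
  expect_identical(corpus[[1]]$clean$pixels, base[[1]]$pixels)
  expect_error(transfer_learn(build_dncnn(tiny_spec(), 1), list(),
                              transfer_config()), "nonempty")
})

test_that("model checkpoints round-trip through save/load", {
  model <- build_dncnn(tiny_spec(), seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  save_dncnn(model, path)
  back <- load_dncnn(path)
  expect_identical(back$layers, model$layers)
  img <- test_abdomen(32, seed = 2)
  expect_identical(predict_residual(back, img), predict_residual(model, img))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_dncnn(bad), "not a dncnn_model")
})
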