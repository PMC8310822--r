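# --- benchmark orchestration ------------------------------------------------

#' Derive a per-stage seed from the global seed
#'
#' One global seed is fanned out to every stochastic stage through a
#' documented rule: the stage name is hashed (31-adic over its bytes,
#' modulo a prime below 2^31) and combined with the global seed, so any
#' stage can be rerun in isolation reproducibly.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return A deterministic integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 31 + b) %% 2147480009
  as.integer((h + as.numeric(seed) * 69069) %% 2147483647)
}

#' Benchmark configuration
#'
#' Describes one end-to-end run: phantom corpus (or an input directory of
#' images), dose schedule, the set of denoising methods, network and
#' training settings, and the output directory. Everything stochastic is
#' derived from the single `seed` via [derive_seed()].
#'
#' @param input `"phantom"` or a directory of readable images.
#' @param n_images number of evaluation images (phantom source).
#' @param image_size phantom grid width in pixels.
#' @param dose_levels dose fractions to simulate.
#' @param methods character subset of `c("noisy", "median", "gaussian",
#'   "wiener", "dncnn", "dncnn_tra")`.
#' @param baseline_noise_sd normal-dose noise SD in HU.
#' @param dncnn list of network/training settings: `depth`, `filters`,
#'   `epochs`, `pretrain_images`, `train_images`, `transfer_mode`,
#'   `patches_per_image`, `patch_size`, `learning_rate`, `batch_size`.
#' @param reference_method method against which the paired tests run.
#' @param out_dir artifact directory.
#' @param image_format `"tiff16"` or `"png16"` for written images.
#' @param write_images write simulated/denoised images to `out_dir`.
#' @param seed global seed.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(input = "phantom", n_images = 2,
                             image_size = 128,
                             dose_levels = c(0.75, 0.5, 0.1, 0.05),
                             methods = c("noisy", "median", "gaussian", "wiener"),
                             baseline_noise_sd = 10,
                             dncnn = list(),
                             reference_method = methods[1],
                             out_dir = "ldct-benchmark",
                             image_format = c("tiff16", "png16"),
                             write_images = TRUE, seed = 1) {
  known <- c("noisy", "median", "gaussian", "wiener", "dncnn", "dncnn_tra")
  if (!all(methods %in% known)) {
    stop(sprintf("unknown method(s): %s",
                 paste(setdiff(methods, known), collapse = ", ")), call. = FALSE)
  }
  dn_defaults <- list(depth = 5, filters = 16, epochs = 30,
                      pretrain_images = 30, train_images = 10,
                      transfer_mode = "all_layers", patches_per_image = 15,
                      patch_size = 50, learning_rate = 1e-3, batch_size = 16)
  dn <- utils::modifyList(dn_defaults, dncnn)
  structure(
    list(input = input, n_images = as.integer(n_images),
         image_size = as.integer(image_size), dose_levels = dose_levels,
         methods = methods, baseline_noise_sd = baseline_noise_sd,
         dncnn = dn, reference_method = reference_method,
         out_dir = out_dir, image_format = match.arg(image_format),
         write_images = isTRUE(write_images), seed = as.integer(seed)),
    class = "benchmark_config"
  )
}

#' Load a benchmark configuration from YAML/JSON
#'
#' Keys mirror the arguments of [benchmark_config()].
#'
#' @param path YAML (or JSON) config file.
#' @param overrides named list applied on top of the file.
#' @return A [benchmark_config].
#' @export
read_benchmark_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals <- utils::modifyList(vals, overrides)
  do.call(benchmark_config, vals)
}

benchmark_eval_images <- function(config) {
  if (identical(config$input, "phantom")) {
    lapply(seq_len(config$n_images), function(i) {
      make_phantom(abdominal_phantom_spec(
        shape = c(config$image_size, config$image_size),
        baseline_noise_sd = config$baseline_noise_sd,
        seed = derive_seed(config$seed, sprintf("phantom-%d", i)),
        jitter_seed = derive_seed(config$seed, sprintf("anatomy-%d", i)),
        image_id = sprintf("phantom-%03d", i)
      ))
    })
  } else {
    files <- sort(list.files(config$input, full.names = TRUE,
                             pattern = "\\.(png|tif|tiff|dcm|dicom)$",
                             ignore.case = TRUE))
    if (length(files) == 0) {
      stop(sprintf("no readable images in %s", config$input), call. = FALSE)
    }
    lapply(files, read_image)
  }
}

# train the dncnn models a benchmark run needs; clean phantoms for the
# training corpus are disjoint from the evaluation set by construction
benchmark_train_models <- function(config, log) {
  dn <- config$dncnn
  spec <- dncnn_spec(depth = dn$depth, filters = dn$filters)
  tc_pre <- train_config(
    patch_size = dn$patch_size, patches_per_image = dn$patches_per_image,
    learning_rate = dn$learning_rate, epochs = dn$epochs,
    batch_size = dn$batch_size,
    seed = derive_seed(config$seed, "pretrain")
  )
  log("pretraining: %d texture images, sigma 25, %d epochs",
      dn$pretrain_images, dn$epochs)
  pre <- pretrain_stand_in(spec, tc_pre, n_images = dn$pretrain_images,
                           sigma = 25, image_size = max(64, dn$patch_size + 14),
                           seed = derive_seed(config$seed, "pretrain-weights"))
  models <- list(dncnn = pre$model)
  if ("dncnn_tra" %in% config$methods) {
    base <- lapply(seq_len(dn$train_images), function(i) {
      make_phantom(abdominal_phantom_spec(
        shape = c(config$image_size, config$image_size),
        baseline_noise_sd = config$baseline_noise_sd,
        seed = derive_seed(config$seed, sprintf("train-phantom-%d", i)),
        jitter_seed = derive_seed(config$seed, sprintf("train-anatomy-%d", i)),
        image_id = sprintf("train-%03d", i)
      ))
    })
    corpus <- build_transfer_corpus(
      base, schedule = config$dose_levels,
      baseline_noise_sd = config$baseline_noise_sd,
      seed = derive_seed(config$seed, "transfer-corpus")
    )
    tc_tra <- tc_pre
    tc_tra$seed <- derive_seed(config$seed, "transfer")
    log("transfer learning (%s): %d corpus images, %d epochs",
        dn$transfer_mode, length(corpus), dn$epochs)
    tra <- transfer_learn(pre$model, corpus,
                          transfer_config(dn$transfer_mode), tc_tra)
    models$dncnn_tra <- tra$model
    models$history_tra <- tra$history
  }
  models$history_pre <- pre$history
  models
}

#' Run the full denoising benchmark
#'
#' Phantom generation (or image loading), dose simulation, denoising with
#' every configured method, and metric report construction, with all
#' artifacts written under `config$out_dir`: simulated and denoised
#' images, the metric CSV/JSON, training-loss curves, and a log of every
#' stage with its parameters. Fully reproducible from (config, seed).
#'
#' @param config a [benchmark_config].
#' @return The `metric_report`, invisibly also written to disk.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "benchmark.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  log <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, log_con)
    message("[ldctbench] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("benchmark stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log("seed %d; %d image(s); doses: %s; methods: %s", config$seed,
      config$n_images, paste(config$dose_levels, collapse = ", "),
      paste(config$methods, collapse = ", "))

  images <- stage("inputs", benchmark_eval_images(config))

  models <- NULL
  if (any(c("dncnn", "dncnn_tra") %in% config$methods)) {
    models <- stage("training", benchmark_train_models(config, log))
    utils::write.csv(models$history_pre,
                     file.path(config$out_dir, "pretrain_history.csv"),
                     row.names = FALSE)
    if (!is.null(models$history_tra)) {
      utils::write.csv(models$history_tra,
                       file.path(config$out_dir, "transfer_history.csv"),
                       row.names = FALSE)
    }
  }

  method_funs <- list(
    noisy = identity,
    median = median_filter3,
    gaussian = gaussian_filter_s1,
    wiener = wiener_filter5,
    dncnn = function(img) denoise_with_model(models$dncnn, img),
    dncnn_tra = function(img) denoise_with_model(models$dncnn_tra, img)
  )[config$methods]

  ext <- if (config$image_format == "png16") ".png" else ".tif"
  img_dir <- file.path(config$out_dir, "images")
  if (config$write_images) dir.create(img_dir, showWarnings = FALSE)

  wrapped <- method_funs
  if (config$write_images) {
    wrapped <- lapply(names(method_funs), function(mm) {
      f <- method_funs[[mm]]
      function(img) {
        out <- f(img)
        suppressWarnings(write_image(out, file.path(
          img_dir, paste0(img$image_id, "-", mm, ext)
        )))
        out
      }
    })
    names(wrapped) <- names(method_funs)
  }

  report <- stage("evaluation", build_report(
    images, config$dose_levels, wrapped,
    reference_method = config$reference_method,
    baseline_noise_sd = config$baseline_noise_sd,
    seed = derive_seed(config$seed, "simulate")
  ))
  stage("report", write_report(report, file.path(config$out_dir, "report")))
  log("wrote %d metric rows", nrow(report$metrics))
  invisible(report)
}
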