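# --- image-quality metrics and method comparison ---------------------------

metric_pixels <- function(x) if (is.ct_image(x)) x$pixels else x

check_same_shape <- function(x, y) {
  if (!identical(dim(x), dim(y))) {
    stop("images must have identical dimensions", call. = FALSE)
  }
}

#' Mean squared error
#'
#' `MSE = (1 / (M N)) * sum((x - y)^2)` over the pixel grid.
#'
#' @param x,y same-shape images ([ct_image] or numeric matrix).
#' @return Nonnegative scalar.
#' @export
mse <- function(x, y) {
  x <- metric_pixels(x)
  y <- metric_pixels(y)
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' Peak signal-to-noise ratio (dB)
#'
#' `PSNR = 10 log10(peak^2 / MSE(x, y))` where the peak is, by default,
#' the maximum absolute value of the reference image `x` (the original
#' full-dose image). For HU images, whose large-magnitude value is often
#' the -1024 air floor, a fixed data range can be supplied instead via
#' `peak`. Identical images have infinite PSNR: the function returns
#' `NA_real_` with a warning (`"identical images"`) rather than a number.
#'
#' @param x reference image.
#' @param y test image, same shape.
#' @param peak optional explicit peak value; default `max(abs(x))`.
#' @return PSNR in dB, or `NA_real_` for identical images.
#' @export
psnr <- function(x, y, peak = NULL) {
  xp <- metric_pixels(x)
  yp <- metric_pixels(y)
  check_same_shape(xp, yp)
  m <- mean((xp - yp)^2)
  if (m == 0) {
    warning("identical images: PSNR is undefined (infinite)", call. = FALSE)
    return(NA_real_)
  }
  if (is.null(peak)) peak <- max(abs(xp))
  10 * log10(peak^2 / m)
}

#' Metric configuration for SSIM
#'
#' Regularization constants default to `C1 = (K1 L)^2`, `C2 = (K2 L)^2`
#' with `K1 = 0.01`, `K2 = 0.03` and `L` the data range. When `C1`/`C2`
#' are left `NULL`, [ssim()] derives `L` from the reference image's range
#' (`max(x) - min(x)`); supplying a `data_range` (or explicit constants)
#' makes the measure exactly symmetric in its two arguments.
#'
#' @param C1,C2 positive regularization constants, or `NULL` to derive.
#' @param data_range optional data range `L` used to derive the constants.
#' @param mode `"global"` (single evaluation with whole-image moments,
#'   the default) or `"windowed"` (mean of the local SSIM map over
#'   Gaussian-weighted windows).
#' @param window odd window width for `"windowed"` mode.
#' @param window_sigma Gaussian weight SD (pixels) for `"windowed"` mode.
#' @return An object of class `metric_config`.
#' @export
metric_config <- function(C1 = NULL, C2 = NULL, data_range = NULL,
                          mode = c("global", "windowed"), window = 11,
                          window_sigma = 1.5) {
  if (!is.null(C1) && C1 <= 0) stop("C1 must be positive", call. = FALSE)
  if (!is.null(C2) && C2 <= 0) stop("C2 must be positive", call. = FALSE)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  structure(
    list(C1 = C1, C2 = C2, data_range = data_range, mode = match.arg(mode),
         window = window, window_sigma = window_sigma),
    class = "metric_config"
  )
}

ssim_constants <- function(x, config) {
  L <- config$data_range
  if (is.null(L)) L <- max(x) - min(x)
  if (L <= 0) L <- 1
  C1 <- if (is.null(config$C1)) (0.01 * L)^2 else config$C1
  C2 <- if (is.null(config$C2)) (0.03 * L)^2 else config$C2
  c(C1 = C1, C2 = C2)
}

#' Structural similarity index
#'
#' `SSIM(x, y) = ((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`.
#'
#' In `"global"` mode (the default) the formula is evaluated once with
#' whole-image means, sample variances (n-1 denominator) and covariance.
#' In `"windowed"` mode the per-pixel SSIM map is computed from local
#' Gaussian-weighted moments and averaged. The value lies in `[-1, 1]`
#' and equals 1 iff the images are identical.
#'
#' @param x reference image.
#' @param y test image, same shape.
#' @param config a [metric_config]; defaults derive the constants from
#'   the reference image's data range.
#' @return SSIM value.
#' @export
ssim <- function(x, y, config = metric_config()) {
  xp <- metric_pixels(x)
  yp <- metric_pixels(y)
  check_same_shape(xp, yp)
  cc <- ssim_constants(xp, config)
  if (config$mode == "global") {
    mx <- mean(xp)
    my <- mean(yp)
    vx <- stats::var(as.vector(xp))
    vy <- stats::var(as.vector(yp))
    cxy <- stats::cov(as.vector(xp), as.vector(yp))
    (2 * mx * my + cc[["C1"]]) * (2 * cxy + cc[["C2"]]) /
      ((mx^2 + my^2 + cc[["C1"]]) * (vx + vy + cc[["C2"]]))
  } else {
    w1 <- local({
      r <- (config$window - 1L) %/% 2L
      w <- exp(-((-r:r)^2) / (2 * config$window_sigma^2))
      w / sum(w)
    })
    smooth <- function(m) convolve_separable(m, w1)
    mx <- smooth(xp)
    my <- smooth(yp)
    vx <- smooth(xp^2) - mx^2
    vy <- smooth(yp^2) - my^2
    cxy <- smooth(xp * yp) - mx * my
    map <- (2 * mx * my + cc[["C1"]]) * (2 * cxy + cc[["C2"]]) /
      ((mx^2 + my^2 + cc[["C1"]]) * (vx + vy + cc[["C2"]]))
    mean(map)
  }
}

#' Vertical CT-value line profile
#'
#' HU values down one column of the image, the numeric twin of a profile
#' plot along a vertical arrow.
#'
#' @param image a [ct_image] or matrix.
#' @param column 1-based column index.
#' @return `data.frame(row, hu)` with one row per image row.
#' @export
line_profile <- function(image, column) {
  px <- metric_pixels(image)
  column <- as.integer(column)
  if (column < 1 || column > ncol(px)) {
    stop(sprintf("column %d out of range [1, %d]", column, ncol(px)), call. = FALSE)
  }
  data.frame(row = seq_len(nrow(px)), hu = px[, column])
}

#' Paired two-tailed t-test between two methods
#'
#' Tests the per-image score differences of two denoising methods with a
#' paired two-tailed t-test (n - 1 degrees of freedom). Degenerate cases
#' are handled explicitly: all-zero differences give `p = 1`; constant
#' nonzero differences (infinite t) give the underflow-safe minimum
#' p-value.
#'
#' @param scores_a,scores_b equal-length numeric vectors of per-image
#'   scores (e.g., SSIM), paired by image, `n >= 2`.
#' @return `list(t, df, p)`.
#' @export
compare_methods <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must be paired (equal length)", call. = FALSE)
  }
  n <- length(scores_a)
  if (n < 2) stop("need at least 2 paired scores", call. = FALSE)
  d <- scores_a - scores_b
  # degenerate to float precision: constant differences
  if (stats::sd(d) <= 1e-12 * max(abs(mean(d)), max(abs(d)), .Machine$double.xmin)) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = .Machine$double.xmin))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = max(tt$p.value, .Machine$double.xmin))
}

#' Full factorial metric report
#'
#' Evaluates every (image, dose level, method) cell: each clean image is
#' dose-simulated, each method denoises the simulated image, and
#' SSIM/PSNR/MSE against the clean image are recorded. Methods are then
#' compared pairwise against `reference_method` at each dose level with a
#' paired two-tailed t-test on the per-image SSIM and PSNR scores.
#'
#' @param images named list of clean [ct_image]s.
#' @param dose_levels dose fractions in (0, 1].
#' @param methods named list of denoisers, each `function(ct_image) ->
#'   ct_image`. The name `"noisy"` (identity) is always available via
#'   `identity`.
#' @param reference_method name of the comparison reference (must be in
#'   `methods`).
#' @param baseline_noise_sd,mtf,seed simulation settings (see
#'   [dose_sim_config()]); per-cell seeds are derived deterministically.
#' @param metric_cfg a [metric_config].
#' @return An object of class `metric_report`: list with `metrics`
#'   (data.frame: image_id, dose_fraction, method, ssim, psnr_db, mse)
#'   and `tests` (data.frame: method, reference, dose_fraction, metric,
#'   t, df, p).
#' @export
build_report <- function(images, dose_levels, methods,
                         reference_method = names(methods)[1],
                         baseline_noise_sd = 10, mtf = default_mtf(),
                         seed = 1, metric_cfg = metric_config()) {
  stopifnot(length(images) >= 1, length(methods) >= 1)
  if (is.null(names(methods)) || any(names(methods) == "")) {
    stop("`methods` must be a named list", call. = FALSE)
  }
  if (!reference_method %in% names(methods)) {
    stop("`reference_method` must be one of the methods", call. = FALSE)
  }
  rows <- list()
  ridx <- 0L
  for (ii in seq_along(images)) {
    clean <- images[[ii]]
    for (dd in seq_along(dose_levels)) {
      dose <- dose_levels[dd]
      sim <- simulate_low_dose(clean, dose_sim_config(
        dose, baseline_noise_sd = baseline_noise_sd, mtf = mtf,
        seed = derive_seed(seed, sprintf("sim-%d-%d", ii, dd))
      ))
      for (mm in names(methods)) {
        den <- methods[[mm]](sim)
        ridx <- ridx + 1L
        rows[[ridx]] <- data.frame(
          image_id = clean$image_id, dose_fraction = dose, method = mm,
          ssim = ssim(clean, den, metric_cfg),
          psnr_db = suppressWarnings(psnr(clean, den)),
          mse = mse(clean, den),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  metrics <- do.call(rbind, rows)
  tests <- list()
  tidx <- 0L
  for (dose in dose_levels) {
    for (mm in setdiff(names(methods), reference_method)) {
      for (metric in c("ssim", "psnr_db")) {
        a <- metrics[metrics$dose_fraction == dose & metrics$method == mm, metric]
        b <- metrics[metrics$dose_fraction == dose & metrics$method == reference_method, metric]
        if (length(a) >= 2 && all(is.finite(a)) && all(is.finite(b))) {
          ct <- compare_methods(a, b)
          tidx <- tidx + 1L
          tests[[tidx]] <- data.frame(
            method = mm, reference = reference_method, dose_fraction = dose,
            metric = metric, t = ct$t, df = ct$df, p = ct$p,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  structure(
    list(
      metrics = metrics,
      tests = if (tidx > 0) do.call(rbind, tests) else NULL,
      config = list(dose_levels = dose_levels, methods = names(methods),
                    reference_method = reference_method,
                    baseline_noise_sd = baseline_noise_sd, seed = seed,
                    schema_version = 1L)
    ),
    class = "metric_report"
  )
}

#' Write a metric report to CSV and JSON
#'
#' `<stem>_metrics.csv`, `<stem>_tests.csv` and `<stem>.json` (the JSON
#' carries the config snapshot for provenance).
#'
#' @param report a `metric_report`.
#' @param stem output path stem.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "metric_report"))
  paths <- character()
  p <- paste0(stem, "_metrics.csv")
  utils::write.csv(format_metrics_csv(report$metrics), p, row.names = FALSE,
                   quote = FALSE)
  paths <- c(paths, p)
  if (!is.null(report$tests)) {
    p <- paste0(stem, "_tests.csv")
    utils::write.csv(report$tests, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  p <- paste0(stem, ".json")
  jsonlite::write_json(
    list(config = report$config, metrics = report$metrics,
         tests = report$tests),
    p, auto_unbox = TRUE, digits = NA, null = "null"
  )
  paths <- c(paths, p)
  invisible(paths)
}

# fixed-precision formatting so reruns are byte-identical
format_metrics_csv <- function(metrics) {
  out <- metrics
  for (col in c("ssim", "psnr_db", "mse")) {
    out[[col]] <- sprintf("%.10g", metrics[[col]])
  }
  out
}
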