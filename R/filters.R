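# --- classical image-space denoisers ---------------------------------------
#
# All three baselines share one border policy: edge replication. Filters
# operate on the HU grid directly and are implemented with vectorized
# shifted-copy / separable-convolution arithmetic.

pad_replicate <- function(m, k) {
  d <- dim(m)
  ri <- c(rep(1L, k), seq_len(d[1]), rep(d[1], k))
  ci <- c(rep(1L, k), seq_len(d[2]), rep(d[2], k))
  m[ri, ci, drop = FALSE]
}

# matrix of all k x k neighborhoods: rows = pixels (col-major), cols = offsets
neighborhood_matrix <- function(m, k) {
  d <- dim(m)
  p <- pad_replicate(m, (k - 1L) %/% 2L)
  out <- matrix(0, prod(d), k * k)
  col <- 0L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      col <- col + 1L
      out[, col] <- as.vector(p[di + seq_len(d[1]), dj + seq_len(d[2])])
    }
  }
  out
}

filter_input_pixels <- function(image, min_size, what) {
  px <- if (is.ct_image(image)) image$pixels else image
  if (any(dim(px) < min_size)) {
    stop(sprintf("%s needs an image of at least %dx%d", what, min_size, min_size),
         call. = FALSE)
  }
  px
}

filter_output <- function(image, px, suffix) {
  if (is.ct_image(image)) {
    set_pixels(image, px, image_id = paste0(image$image_id, suffix))
  } else {
    px
  }
}

#' 3x3 median filter
#'
#' Each output pixel is the median of its 3x3 neighborhood; borders are
#' edge-replicated.
#'
#' @param image a [ct_image] or numeric matrix, at least 3x3.
#' @return Same type as the input.
#' @export
median_filter3 <- function(image) {
  px <- filter_input_pixels(image, 3L, "median_filter3")
  nb <- neighborhood_matrix(px, 3L)
  # median of 9 = 5th order statistic, per row
  med <- apply(nb, 1L, function(v) sort.int(v, partial = 5L)[5L])
  filter_output(image, matrix(med, nrow(px), ncol(px)), "-median")
}

gaussian_kernel_1d <- function(sigma = 1, truncate = 4) {
  r <- ceiling(truncate * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w / sum(w)
}

# separable convolution with edge replication
convolve_separable <- function(px, w) {
  r <- (length(w) - 1L) %/% 2L
  d <- dim(px)
  p <- pad_replicate(px, r)
  rows_out <- matrix(0, d[1], ncol(p))
  for (t in seq_along(w)) { # vertical pass
    rows_out <- rows_out + w[t] * p[(t - 1L) + seq_len(d[1]), ]
  }
  out <- matrix(0, d[1], d[2])
  for (t in seq_along(w)) { # horizontal pass
    out <- out + w[t] * rows_out[, (t - 1L) + seq_len(d[2])]
  }
  out
}

#' Isotropic Gaussian smoothing, sigma = 1 pixel
#'
#' Convolution with a normalized isotropic Gaussian kernel of standard
#' deviation 1.0 pixel, truncated at 4 sigma; borders edge-replicated.
#'
#' @param image a [ct_image] or numeric matrix.
#' @param sigma kernel SD in pixels.
#' @return Same type as the input.
#' @export
gaussian_filter_s1 <- function(image, sigma = 1) {
  px <- filter_input_pixels(image, 1L, "gaussian_filter_s1")
  out <- convolve_separable(px, gaussian_kernel_1d(sigma))
  filter_output(image, out, "-gaussian")
}

#' 5x5 adaptive Wiener filter
#'
#' Local adaptive (Lee-type) Wiener filter: with local mean `m` and local
#' variance `v` over the 5x5 neighborhood of each pixel,
#' `output = m + max(0, v - nv) / max(v, nv) * (pixel - m)` where `nv` is
#' the noise variance — supplied, or estimated as the mean of all local
#' variances. Borders edge-replicated.
#'
#' @param image a [ct_image] or numeric matrix, at least 5x5.
#' @param noise_variance optional nonnegative noise variance (HU^2).
#' @return Same type as the input.
#' @export
wiener_filter5 <- function(image, noise_variance = NULL) {
  px <- filter_input_pixels(image, 5L, "wiener_filter5")
  if (!is.null(noise_variance) && noise_variance < 0) {
    stop("`noise_variance` must be nonnegative", call. = FALSE)
  }
  box <- rep(1 / 5, 5)
  m <- convolve_separable(px, box)
  v <- pmax(convolve_separable(px^2, box) - m^2, 0)
  nv <- if (is.null(noise_variance)) mean(v) else noise_variance
  gain <- pmax(v - nv, 0) / pmax(v, nv)
  gain[v == 0 & nv == 0] <- 0 # constant image, no noise estimate
  out <- m + gain * (px - m)
  filter_output(image, out, "-wiener")
}
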