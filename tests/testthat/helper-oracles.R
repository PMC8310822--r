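# Independent brute-force oracles: deliberately naive loop/scalar
# implementations, kept free of any code path they are used to check.

oracle_mse <- function(x, y) {
  s <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) s <- s + (x[i, j] - y[i, j])^2
  }
  s / (nrow(x) * ncol(x))
}

oracle_psnr <- function(x, y) {
  10 * log10(max(abs(x))^2 / oracle_mse(x, y))
}

# scalar SSIM from whole-image moments, written straight from the formula
oracle_ssim_global <- function(x, y, C1, C2) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  vx <- sum((x - mx)^2) / (n - 1)
  vy <- sum((y - my)^2) / (n - 1)
  cxy <- sum((x - mx) * (y - my)) / (n - 1)
  ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

oracle_pad_replicate <- function(m, k) {
  ri <- pmin(pmax(seq_len(nrow(m) + 2 * k) - k, 1), nrow(m))
  ci <- pmin(pmax(seq_len(ncol(m) + 2 * k) - k, 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

oracle_median3 <- function(m) {
  p <- oracle_pad_replicate(m, 1)
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[i, j] <- median(p[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

oracle_gaussian <- function(m, sigma = 1, truncate = 4) {
  r <- ceiling(truncate * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  p <- oracle_pad_replicate(m, r)
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      out[i, j] <- sum(p[i:(i + 2 * r), j:(j + 2 * r)] * kern)
    }
  }
  out
}

oracle_wiener5 <- function(m, noise_variance = NULL) {
  p <- oracle_pad_replicate(m, 2)
  lm <- m
  lv <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      win <- p[i:(i + 4), j:(j + 4)]
      lm[i, j] <- mean(win)
      lv[i, j] <- mean(win^2) - mean(win)^2
    }
  }
  nv <- if (is.null(noise_variance)) mean(lv) else noise_variance
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      v <- lv[i, j]
      gain <- if (max(v, nv) == 0) 0 else max(v - nv, 0) / max(v, nv)
      out[i, j] <- lm[i, j] + gain * (m[i, j] - lm[i, j])
    }
  }
  out
}

# paired t-test from the textbook closed form
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1))
}

# radially averaged 2-D periodogram (direct FFT definition)
oracle_radial_periodogram <- function(field, spacing_mm, bin_width = 0.02) {
  d <- dim(field)
  pg <- Mod(stats::fft(field))^2 / length(field)
  fy <- c(0:(d[1] %/% 2), -((d[1] + 1) %/% 2 - 1):-1) / (d[1] * spacing_mm[1])
  fx <- c(0:(d[2] %/% 2), -((d[2] + 1) %/% 2 - 1):-1) / (d[2] * spacing_mm[2])
  fr <- sqrt(outer(fy^2, fx^2, `+`))
  bin <- floor(fr / bin_width)
  keep <- fr > 0
  data.frame(
    f = tapply(fr[keep], bin[keep], mean),
    power = tapply(pg[keep], bin[keep], mean)
  )
}

# small deterministic phantoms for tests
flat_phantom <- function(size = 64, hu = 0, noise_sd = 0, seed = 1) {
  make_phantom(phantom_spec(shape = c(size, size), background_hu = hu,
                            baseline_noise_sd = noise_sd, seed = seed))
}

test_abdomen <- function(size = 128, seed = 1, noise_sd = 10) {
  make_phantom(abdominal_phantom_spec(shape = c(size, size),
                                      baseline_noise_sd = noise_sd,
                                      seed = seed, jitter_seed = seed + 500L))
}
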