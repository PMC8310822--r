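test_that("dose-to-noise factors use the printed values and the 1/d rule", {
  expect_equal(noise_factor(c(0.75, 0.5, 0.1, 0.05)), c(1.3, 2, 10, 20))
  expect_equal(noise_factor(1.0), 1.0)
  expect_equal(noise_factor(0.2), 5.0) # general rule 1/dose_fraction
  expect_equal(noise_factor(0.25), 4.0)
  expect_error(noise_factor(0), "\\(0, 1\\]")
  expect_error(noise_factor(1.2), "\\(0, 1\\]")
  expect_error(noise_factor(-0.5), "\\(0, 1\\]")
})

test_that("the default dose schedule spans the full range down to 1/100", {
  s <- dose_schedule()
  expect_length(s, 10)
  expect_equal(s[1], 1)
  expect_equal(s[10], 0.01)
  expect_true(all(diff(s) < 0))
})

test_that("MTF curves validate and interpolate linearly with zero tail", {
  expect_error(mtf_curve(c(0.1, 0.5), c(1, 0.5)), "frequency 0")
  expect_error(mtf_curve(c(0, 0.5), c(0.9, 0.5)), "must be 1")
  expect_error(mtf_curve(c(0, 0.5, 0.4), c(1, 0.8, 0.5)), "increasing")
  expect_error(mtf_curve(c(0, 0.5), c(1, 1.2)), "\\[0, 1\\]")
  curve <- mtf_curve(c(0, 1), c(1, 0.5))
  expect_equal(mtf_eval(curve, 0), 1)
  expect_equal(mtf_eval(curve, 0.5), 0.75) # linear midpoint
  expect_equal(mtf_eval(curve, 2), 0) # beyond last sample
  expect_error(mtf_eval(curve, -0.1), "nonnegative")
  dflt <- default_mtf()
  expect_equal(dflt$values[1], 1)
  expect_true(all(diff(dflt$values) < 0))
})

test_that("the bundled MTF csv reproduces the default curve", {
  path <- system.file("extdata", "default_mtf.csv", package = "ldctbench")
  curve <- read_mtf_csv(path)
  dflt <- default_mtf()
  expect_equal(curve$frequencies, dflt$frequencies, tolerance = 1e-12)
  expect_equal(curve$values, dflt$values, tolerance = 1e-12)
})

test_that("shaped noise has exact target SD, exact zero mean, per-seed novelty", {
  mtf <- default_mtf()
  z <- synthesize_shaped_noise(c(64, 64), c(0.7, 0.7), mtf, 0, seed = 1)
  expect_true(all(z == 0))
  f1 <- synthesize_shaped_noise(c(256, 256), c(0.7, 0.7), mtf, 50, seed = 1)
  f2 <- synthesize_shaped_noise(c(256, 256), c(0.7, 0.7), mtf, 50, seed = 2)
  expect_equal(sd(f1), 50)
  expect_equal(sd(f2), 50)
  expect_equal(mean(f1), 0, tolerance = 1e-12)
  expect_false(identical(f1, f2))
  expect_identical(f1, synthesize_shaped_noise(c(256, 256), c(0.7, 0.7), mtf, 50, seed = 1))
  expect_error(synthesize_shaped_noise(c(64, 64), c(0.7, 0.7), mtf, -1, seed = 1),
               "nonnegative")
})

test_that("the added-noise power spectrum is proportional to MTF squared", {
  mtf <- default_mtf()
  spacing <- c(0.7, 0.7)
  acc <- NULL
  for (seed in 1:20) {
    f <- synthesize_shaped_noise(c(256, 256), spacing, mtf, 30, seed = seed)
    rp <- oracle_radial_periodogram(f, spacing)
    acc <- if (is.null(acc)) rp else within(acc, power <- power + rp$power)
  }
  acc$power <- acc$power / 20
  band <- mtf_eval(mtf, acc$f) >= 0.1 # passband
  ratio <- acc$power[band] / mtf_eval(mtf, acc$f[band])^2
  cv <- sd(ratio) / mean(ratio)
  expect_lt(cv, 0.15)
  # and the spectrum is NOT flat before normalization (shaping is real)
  expect_gt(sd(acc$power[band]) / mean(acc$power[band]), 0.5)
})

test_that("estimate_noise_sd recovers white-noise SD and ignores structure", {
  expect_equal(estimate_noise_sd(matrix(7, 16, 16)), 0)
  ests <- vapply(1:20, function(s) {
    set.seed(s)
    estimate_noise_sd(matrix(rnorm(512 * 512, sd = 10), 512, 512))
  }, numeric(1))
  expect_gt(mean(ests), 9.3)
  expect_lt(mean(ests), 10.7)
  expect_true(all(ests > 9), info = "each replicate close to truth")
  # invariance to constant offset and linear ramps (second-derivative based)
  set.seed(1)
  base <- matrix(rnorm(128 * 128, sd = 5), 128, 128)
  ramp <- outer(seq_len(128), seq_len(128), function(i, j) 3 * i - 2 * j)
  expect_equal(estimate_noise_sd(base + 100), estimate_noise_sd(base))
  expect_equal(estimate_noise_sd(base + ramp), estimate_noise_sd(base),
               tolerance = 1e-10)
  expect_error(estimate_noise_sd(matrix(0, 2, 2)), "3x3")
})

test_that("simulated dose-equivalent images reach the calibrated total noise", {
  clean <- flat_phantom(512, hu = 40)
  noisy <- flat_phantom(512, hu = 40, noise_sd = 10, seed = 77)
  for (dose in c(0.5, 0.05)) {
    sim <- simulate_low_dose(noisy, dose_sim_config(
      dose, baseline_noise_sd = 10, seed = 13
    ))
    ratio <- sd(sim$pixels - clean$pixels) / 10
    expect_equal(ratio, noise_factor(dose), tolerance = 0.02)
  }
})

test_that("dose fraction 1 returns the input unchanged", {
  img <- flat_phantom(32, noise_sd = 5, seed = 2)
  out <- simulate_low_dose(img, dose_sim_config(1, baseline_noise_sd = 5))
  expect_identical(out$pixels, img$pixels)
})

test_that("simulation preserves the image mean and is seed-deterministic", {
  img <- flat_phantom(512, hu = 40, noise_sd = 10, seed = 3)
  cfg <- dose_sim_config(0.1, baseline_noise_sd = 10, seed = 8)
  sim1 <- simulate_low_dose(img, cfg)
  sim2 <- simulate_low_dose(img, cfg)
  expect_identical(sim1$pixels, sim2$pixels)
  expect_lt(abs(mean(sim1$pixels) - mean(img$pixels)), 0.05)
  alt <- simulate_low_dose(img, dose_sim_config(0.1, baseline_noise_sd = 10, seed = 9))
  expect_false(identical(sim1$pixels, alt$pixels))
  # different seeds, same calibrated magnitude (within 1%)
  clean <- flat_phantom(512, hu = 40)
  r1 <- sd(sim1$pixels - clean$pixels)
  r2 <- sd(alt$pixels - clean$pixels)
  expect_equal(r1, r2, tolerance = 0.01)
})

test_that("lower dose always means strictly more added noise", {
  img <- flat_phantom(128, hu = 0, noise_sd = 10, seed = 4)
  clean <- flat_phantom(128, hu = 0)
  doses <- c(0.75, 0.5, 0.3, 0.1, 0.05)
  sds <- vapply(doses, function(d) {
    sim <- simulate_low_dose(img, dose_sim_config(d, baseline_noise_sd = 10, seed = 21))
    sd(sim$pixels - img$pixels) # added component only
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
})

test_that("added_equals_target mode adds the full k-times-baseline SD", {
  img <- flat_phantom(256, hu = 0, noise_sd = 10, seed = 5)
  sim <- simulate_low_dose(img, dose_sim_config(
    0.1, baseline_noise_sd = 10, seed = 6, mode = "added_equals_target"
  ))
  expect_equal(sd(sim$pixels - img$pixels) / 10, 10, tolerance = 0.02)
})

test_that("poisson noise model is calibrated like the gaussian one", {
  img <- flat_phantom(256, hu = 0, noise_sd = 10, seed = 5)
  clean <- flat_phantom(256, hu = 0)
  sim <- simulate_low_dose(img, dose_sim_config(
    0.1, baseline_noise_sd = 10, seed = 6, noise_model = "poisson"
  ))
  expect_equal(sd(sim$pixels - clean$pixels) / 10, 10, tolerance = 0.03)
})

test_that("baseline noise SD is estimated from the image when not supplied", {
  img <- flat_phantom(256, hu = 0, noise_sd = 10, seed = 31)
  clean <- flat_phantom(256, hu = 0)
  sim <- simulate_low_dose(img, dose_sim_config(0.1, seed = 7))
  # estimate is within a few percent of 10 HU, so total lands near 100 HU
  expect_equal(sd(sim$pixels - clean$pixels), 100, tolerance = 0.08)
})

test_that("dose_sim_config validates its domain", {
  expect_error(dose_sim_config(0), "\\(0, 1\\]")
  expect_error(dose_sim_config(1.5), "\\(0, 1\\]")
  expect_error(dose_sim_config(0.5, baseline_noise_sd = -1), "positive")
  expect_error(dose_sim_config(0.5, noise_factor = 0.5), ">= 1")
})
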