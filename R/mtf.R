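#' Modulation transfer function curve
#'
#' Sampled MTF of a CT unit: spatial frequency (cycles/mm) versus
#' modulation in `[0, 1]`. The curve must start at frequency 0 with
#' modulation 1 (by definition of the MTF) and frequencies must be
#' strictly increasing. Between samples the curve is evaluated by linear
#' interpolation; beyond the last sample it is 0.
#'
#' @param frequencies strictly increasing nonnegative numeric, starting at 0.
#' @param values modulation values in `[0, 1]`; `values[1]` must be 1.
#' @param name label for reports.
#' @return An object of class `mtf_curve`.
#' @export
mtf_curve <- function(frequencies, values, name = "mtf") {
  frequencies <- as.numeric(frequencies)
  values <- as.numeric(values)
  if (length(frequencies) != length(values) || length(frequencies) < 2) {
    stop("`frequencies` and `values` must be equal-length (>= 2)", call. = FALSE)
  }
  if (frequencies[1] != 0) stop("MTF must be sampled starting at frequency 0", call. = FALSE)
  if (any(diff(frequencies) <= 0)) stop("frequencies must be strictly increasing", call. = FALSE)
  if (abs(values[1] - 1) > 1e-12) stop("modulation at zero frequency must be 1", call. = FALSE)
  if (any(values < 0 | values > 1)) stop("modulation values must lie in [0, 1]", call. = FALSE)
  structure(list(frequencies = frequencies, values = values, name = name),
            class = "mtf_curve")
}

#' @rdname mtf_curve
#' @param curve an `mtf_curve`.
#' @param frequency nonnegative frequency or vector thereof (cycles/mm).
#' @return `mtf_eval`: modulation value(s) in `[0, 1]`.
#' @export
mtf_eval <- function(curve, frequency) {
  stopifnot(inherits(curve, "mtf_curve"))
  if (any(frequency < 0)) stop("frequency must be nonnegative", call. = FALSE)
  stats::approx(curve$frequencies, curve$values, xout = frequency,
                yleft = 1, yright = 0, ties = "ordered")$y
}

#' Default scanner MTF
#'
#' A smooth Gaussian-shaped stand-in for a CT unit's measured MTF:
#' modulation 1 at zero frequency, falling to 0.05 at the Nyquist
#' frequency of a 0.7 mm pixel grid (1 / (2 * 0.7) ~ 0.714 cycles/mm).
#' Bundled as `inst/extdata/default_mtf.csv`; the simulation pipeline is
#' agnostic to the particular curve, which can be replaced by a measured
#' two-column CSV via [read_mtf_csv()].
#'
#' @param n_samples number of tabulated points.
#' @return An [mtf_curve].
#' @export
default_mtf <- function(n_samples = 30) {
  f_nyq <- 1 / (2 * 0.7)
  f <- seq(0, f_nyq, length.out = n_samples)
  f0 <- f_nyq / sqrt(log(1 / 0.05))
  mtf_curve(f, exp(-(f / f0)^2), name = "default-gaussian")
}

#' Read / write an MTF curve as two-column CSV
#'
#' Columns: `frequency_cycles_per_mm`, `modulation`.
#'
#' @param path CSV file.
#' @param name label for the returned curve.
#' @return [read_mtf_csv()]: an [mtf_curve].
#' @export
read_mtf_csv <- function(path, name = basename(path)) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("MTF CSV needs two columns (frequency, modulation)", call. = FALSE)
  mtf_curve(d[[1]], d[[2]], name = name)
}

#' @rdname read_mtf_csv
#' @param curve an [mtf_curve] to write.
#' @export
write_mtf_csv <- function(curve, path) {
  stopifnot(inherits(curve, "mtf_curve"))
  utils::write.csv(
    data.frame(frequency_cycles_per_mm = curve$frequencies,
               modulation = curve$values),
    path, row.names = FALSE
  )
  invisible(path)
}
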