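#' Synthetic abdominal phantom specification
#'
#' Describes a deterministic elliptical phantom: a uniform background,
#' a list of (possibly rotated) ellipses painted in order — later
#' ellipses overwrite earlier ones — and a Gaussian texture of standard
#' deviation `baseline_noise_sd` added everywhere to emulate the quantum
#' noise of a normal-dose acquisition.
#'
#' Ellipses are rasterized with a pixel-center-inside test: a pixel
#' belongs to an ellipse iff its center satisfies the ellipse inequality.
#'
#' @param shape integer (rows, cols) of the output grid.
#' @param background_hu background value in HU.
#' @param ellipses list of ellipse descriptions, each a list with fields
#'   `center` (row, col in pixels), `semi_axes` (row, col semi-axis
#'   lengths in pixels, both positive), `rotation_deg` (counter-clockwise
#'   rotation) and `hu` (value painted inside).
#' @param baseline_noise_sd nonnegative SD (HU) of the added Gaussian texture.
#' @param seed integer; the phantom is a pure function of the spec, seed included.
#' @param pixel_spacing_mm,slice_thickness_mm geometry passed to [ct_image].
#' @param image_id label passed to [ct_image].
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(512, 512), background_hu = -1000,
                         ellipses = list(), baseline_noise_sd = 0, seed = 1,
                         pixel_spacing_mm = c(0.7, 0.7),
                         slice_thickness_mm = 3, image_id = "phantom") {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 1)) {
    stop("`shape` must be two positive integers", call. = FALSE)
  }
  if (baseline_noise_sd < 0) stop("`baseline_noise_sd` must be >= 0", call. = FALSE)
  for (e in ellipses) {
    if (is.null(e$center) || is.null(e$semi_axes) || is.null(e$hu)) {
      stop("each ellipse needs `center`, `semi_axes` and `hu`", call. = FALSE)
    }
    if (any(e$semi_axes <= 0)) stop("ellipse semi-axes must be positive", call. = FALSE)
  }
  structure(
    list(
      shape = shape, background_hu = background_hu, ellipses = ellipses,
      baseline_noise_sd = baseline_noise_sd, seed = as.integer(seed),
      pixel_spacing_mm = pixel_spacing_mm,
      slice_thickness_mm = slice_thickness_mm, image_id = image_id
    ),
    class = "phantom_spec"
  )
}

ellipse_mask <- function(shape, center, semi_axes, rotation_deg = 0) {
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  dy <- rows - center[1]
  dx <- cols - center[2]
  th <- rotation_deg * pi / 180
  u <- dy * cos(th) + dx * sin(th)
  v <- -dy * sin(th) + dx * cos(th)
  (u / semi_axes[1])^2 + (v / semi_axes[2])^2 <= 1
}

#' Render a phantom
#'
#' Deterministic given the spec (seed included): the same spec always
#' yields the identical image.
#'
#' @param spec a [phantom_spec].
#' @return A [ct_image].
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  px <- matrix(spec$background_hu, spec$shape[1], spec$shape[2])
  for (e in spec$ellipses) {
    rot <- if (is.null(e$rotation_deg)) 0 else e$rotation_deg
    px[ellipse_mask(spec$shape, e$center, e$semi_axes, rot)] <- e$hu
  }
  if (spec$baseline_noise_sd > 0) {
    px <- px + with_seed(spec$seed, matrix(
      stats::rnorm(length(px), sd = spec$baseline_noise_sd),
      spec$shape[1], spec$shape[2]
    ))
  }
  ct_image(px,
    pixel_spacing_mm = spec$pixel_spacing_mm,
    slice_thickness_mm = spec$slice_thickness_mm, image_id = spec$image_id
  )
}

#' Abdominal-like phantom specification
#'
#' Builds a phantom spec that mimics the gross composition of an axial
#' abdominal CT slice: an elliptical body of soft tissue containing a
#' liver, spleen, two kidneys, aorta, a vertebral body and bowel gas,
#' on an air background. With `jitter_seed`, organ positions, sizes and
#' HU values are perturbed slightly so that a corpus of anatomically
#' varied slices can be generated from consecutive seeds.
#'
#' Typical organ HU values are used (soft tissue ~40, liver ~60,
#' bone ~400, air -1000); `baseline_noise_sd = 10` HU approximates the
#' quantum-noise level of a routine normal-dose abdominal acquisition.
#'
#' @param shape grid size (rows, cols).
#' @param baseline_noise_sd normal-dose Gaussian texture SD in HU.
#' @param seed seed for the phantom's noise texture.
#' @param jitter_seed optional integer; when given, anatomy is randomly
#'   perturbed (deterministically for that value).
#' @param image_id label.
#' @return A [phantom_spec].
#' @export
abdominal_phantom_spec <- function(shape = c(256, 256), baseline_noise_sd = 10,
                                   seed = 1, jitter_seed = NULL,
                                   image_id = sprintf("abdomen-%03d", seed)) {
  s <- min(shape) # scale anatomy to the grid
  u <- function(frac) frac * s
  jit <- function(x, rel = 0.06) x * (1 + stats::runif(length(x), -rel, rel))
  build <- function() {
    cy <- shape[1] / 2
    cx <- shape[2] / 2
    list(
      list( # body outline, soft tissue
        center = c(cy, cx), semi_axes = jit(c(u(0.38), u(0.46))),
        rotation_deg = 0, hu = jit(40, 0.1)
      ),
      list( # liver, right side (image left)
        center = c(cy - u(0.06), cx - u(0.18)) + stats::runif(2, -u(0.01), u(0.01)),
        semi_axes = jit(c(u(0.17), u(0.15))), rotation_deg = stats::runif(1, -15, 15),
        hu = jit(60, 0.08)
      ),
      list( # stomach / bowel gas pocket
        center = c(cy - u(0.08), cx + u(0.12)) + stats::runif(2, -u(0.02), u(0.02)),
        semi_axes = jit(c(u(0.06), u(0.07))), rotation_deg = stats::runif(1, -30, 30),
        hu = -800
      ),
      list( # spleen
        center = c(cy - u(0.02), cx + u(0.28)) + stats::runif(2, -u(0.01), u(0.01)),
        semi_axes = jit(c(u(0.08), u(0.05))), rotation_deg = stats::runif(1, 20, 50),
        hu = jit(50, 0.08)
      ),
      list( # left kidney
        center = c(cy + u(0.14), cx + u(0.16)) + stats::runif(2, -u(0.01), u(0.01)),
        semi_axes = jit(c(u(0.06), u(0.04))), rotation_deg = stats::runif(1, -20, 20),
        hu = jit(35, 0.1)
      ),
      list( # right kidney
        center = c(cy + u(0.14), cx - u(0.16)) + stats::runif(2, -u(0.01), u(0.01)),
        semi_axes = jit(c(u(0.06), u(0.04))), rotation_deg = stats::runif(1, -20, 20),
        hu = jit(35, 0.1)
      ),
      list( # aorta
        center = c(cy + u(0.10), cx + u(0.02)), semi_axes = jit(c(u(0.025), u(0.025))),
        rotation_deg = 0, hu = jit(45, 0.1)
      ),
      list( # vertebral body
        center = c(cy + u(0.24), cx), semi_axes = jit(c(u(0.06), u(0.05))),
        rotation_deg = 0, hu = jit(400, 0.1)
      )
    )
  }
  ell <- if (is.null(jitter_seed)) {
    with_seed(0L, build()) # runif draws become deterministic, no jitter seed given
  } else {
    with_seed(as.integer(jitter_seed), build())
  }
  phantom_spec(
    shape = shape, background_hu = -1000, ellipses = ell,
    baseline_noise_sd = baseline_noise_sd, seed = seed, image_id = image_id
  )
}
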