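#' CT slice container
#'
#' A `ct_image` holds one 2-D CT slice as a numeric matrix of Hounsfield
#' units (HU) together with its physical geometry. Row-major orientation
#' with the origin at the top-left is used throughout the package; pixel
#' `[i, j]` is row `i` (top to bottom), column `j` (left to right),
#' 1-based as usual in R.
#'
#' Internal processing may transiently push values outside the clinical
#' HU range; values are clamped to `[-1024, 3071]` only on file write.
#'
#' @param pixels numeric matrix of HU values (rows x cols); all finite.
#' @param pixel_spacing_mm positive length-2 numeric, physical size of one
#'   pixel in mm as (row spacing, column spacing). A single number is
#'   recycled to both axes.
#' @param slice_thickness_mm positive scalar, slice thickness in mm.
#' @param image_id opaque character label carried through reports.
#'
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(pixels, pixel_spacing_mm = c(0.7, 0.7),
                     slice_thickness_mm = 3, image_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("all pixel values must be finite", call. = FALSE)
  }
  if (length(pixel_spacing_mm) == 1) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  }
  if (length(pixel_spacing_mm) != 2 || any(pixel_spacing_mm <= 0)) {
    stop("`pixel_spacing_mm` must be two positive numbers", call. = FALSE)
  }
  if (length(slice_thickness_mm) != 1 || slice_thickness_mm <= 0) {
    stop("`slice_thickness_mm` must be a positive scalar", call. = FALSE)
  }
  structure(
    list(
      pixels = unname(pixels),
      pixel_spacing_mm = as.numeric(pixel_spacing_mm),
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      image_id = as.character(image_id)
    ),
    class = "ct_image"
  )
}

#' @rdname ct_image
#' @param x object to test or print.
#' @export
is.ct_image <- function(x) inherits(x, "ct_image")

#' @rdname ct_image
#' @param ... unused.
#' @export
print.ct_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<ct_image '%s': %d x %d px, %.3g x %.3g mm/px, slice %.3g mm, HU [%.0f, %.0f]>\n",
    x$image_id, d[1], d[2], x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    x$slice_thickness_mm, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

# replace the pixel grid, keeping geometry/identity
set_pixels <- function(image, pixels, image_id = image$image_id) {
  ct_image(pixels,
    pixel_spacing_mm = image$pixel_spacing_mm,
    slice_thickness_mm = image$slice_thickness_mm,
    image_id = image_id
  )
}

#' Centered crop of a CT slice
#'
#' Extracts the centered `height` x `width` sub-grid. When the margin left
#' over on an axis is odd, the extra row/column is dropped from the
#' bottom/right: the top-left corner of the crop sits at
#' `floor((size - crop) / 2)` (0-based). Pixel spacing is preserved;
#' the crop operates purely in pixel space.
#'
#' @param image a [ct_image].
#' @param height,width requested output dimensions in pixels.
#' @return A [ct_image] of exactly the requested size.
#' @export
crop_center <- function(image, height, width) {
  stopifnot(is.ct_image(image))
  d <- dim(image$pixels)
  height <- as.integer(height)
  width <- as.integer(width)
  if (height < 1 || width < 1) stop("crop size must be positive", call. = FALSE)
  if (height > d[1] || width > d[2]) {
    stop(sprintf(
      "crop %dx%d exceeds image size %dx%d", height, width, d[1], d[2]
    ), call. = FALSE)
  }
  r0 <- (d[1] - height) %/% 2L
  c0 <- (d[2] - width) %/% 2L
  set_pixels(image, image$pixels[r0 + seq_len(height), c0 + seq_len(width), drop = FALSE])
}

# seed scoping: evaluate expr under a fixed RNG state, restoring the
# caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
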