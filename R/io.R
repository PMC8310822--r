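# --- raster I/O -------------------------------------------------------------
#
# Interchange convention for 16-bit PNG/TIFF: stored = HU + 1024 (unsigned),
# so air (-1024 HU) is stored as 0 and water (0 HU) as 1024. HU values are
# clamped to [-1024, 3071] on write (stored range [0, 4095]); a warning
# reports how many pixels were clamped.

HU_MIN <- -1024
HU_MAX <- 3071
HU_OFFSET <- 1024

clamp_hu <- function(px) {
  n_out <- sum(px < HU_MIN | px > HU_MAX)
  if (n_out > 0) {
    warning(sprintf("%d pixel(s) outside [%d, %d] HU clamped on write",
                    n_out, HU_MIN, HU_MAX), call. = FALSE)
  }
  pmin(pmax(px, HU_MIN), HU_MAX)
}

#' Read a CT slice from disk
#'
#' Supported formats: single-frame DICOM (explicit or implicit VR, little
#' endian), 16-bit grayscale PNG and 16-bit grayscale TIFF. For DICOM the
#' HU values are reconstructed as `RescaleSlope * stored + RescaleIntercept`
#' and pixel spacing/slice thickness are taken from the header; missing
#' rescale tags are an error, never a silent identity. For PNG/TIFF the
#' stored-value convention `HU = stored - 1024` applies and spacing comes
#' from the `pixel_spacing_mm` argument.
#'
#' @param path file to read.
#' @param format one of `"dicom"`, `"png16"`, `"tiff16"`; default guesses
#'   from the file extension.
#' @param pixel_spacing_mm,slice_thickness_mm geometry for formats that do
#'   not carry it (PNG/TIFF).
#' @param image_id label; defaults to the file name.
#' @return A [ct_image].
#' @export
read_image <- function(path, format = c("auto", "dicom", "png16", "tiff16"),
                       pixel_spacing_mm = c(0.7, 0.7), slice_thickness_mm = 3,
                       image_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  px <- switch(format,
    png16 = {
      arr <- png::readPNG(path)
      if (length(dim(arr)) == 3) arr <- arr[, , 1]
      round(arr * 65535) - HU_OFFSET
    },
    tiff16 = {
      arr <- tiff::readTIFF(path)
      if (length(dim(arr)) == 3) arr <- arr[, , 1]
      round(arr * 65535) - HU_OFFSET
    },
    dicom = {
      d <- read_dicom_minimal(path)
      if (!is.null(d$pixel_spacing_mm)) pixel_spacing_mm <- d$pixel_spacing_mm
      if (!is.null(d$slice_thickness_mm)) slice_thickness_mm <- d$slice_thickness_mm
      d$hu
    }
  )
  ct_image(px,
    pixel_spacing_mm = pixel_spacing_mm,
    slice_thickness_mm = slice_thickness_mm, image_id = image_id
  )
}

#' Write a CT slice to disk
#'
#' Lossless for integer HU in `[-1024, 3071]`; out-of-range values are
#' clamped with a warning. DICOM writing is not supported.
#'
#' @param image a [ct_image].
#' @param path output file.
#' @param format `"png16"` or `"tiff16"` (default guesses from extension).
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path, format = c("auto", "png16", "tiff16")) {
  stopifnot(is.ct_image(image))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  stored <- round(clamp_hu(image$pixels)) + HU_OFFSET
  switch(format,
    png16 = write_png16(stored, path),
    tiff16 = tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L,
                             compression = "none"),
    dicom = stop("DICOM writing is not supported", call. = FALSE)
  )
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = "png16",
    tif = , tiff = "tiff16",
    dcm = , dicom = "dicom",
    stop(sprintf("cannot guess image format from extension '.%s'", ext),
         call. = FALSE)
  )
}

# --- 16-bit grayscale PNG encoder ------------------------------------------
# png::writePNG emits 8-bit only, so the 16-bit encoder lives here:
# PNG signature, IHDR (bit depth 16, grayscale), one zlib IDAT (filter 0
# per scanline, big-endian samples), IEND. CRC32 is the standard
# reflected table-driven algorithm.

# R's bitwShiftR is a logical shift on the 32-bit pattern, so the classic
# reflected CRC-32 (polynomial 0xEDB88320) translates directly.
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        cc <- i
        for (k in 1:8) {
          cc <- if (bitwAnd(cc, 1L) != 0L) {
            bitwXor(-306674912L, bitwShiftR(cc, 1))
          } else {
            bitwShiftR(cc, 1)
          }
        }
        t[i + 1] <- cc
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1], bitwShiftR(crc, 8))
  }
  bitwXor(crc, -1L)
}

u32_be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(u32_be(length(data)), body, u32_be(if (crc < 0) crc + 4294967296 else crc))
}

write_png16 <- function(stored, path) {
  stored <- pmin(pmax(round(stored), 0), 65535)
  h <- nrow(stored)
  w <- ncol(stored)
  vals <- as.vector(t(stored)) # row-major scanlines
  hi <- as.raw(vals %/% 256)
  lo <- as.raw(vals %% 256)
  samples <- as.vector(rbind(hi, lo)) # big-endian 16-bit
  scan <- matrix(samples, nrow = 2L * w, ncol = h)
  raw_data <- as.vector(rbind(matrix(as.raw(0), 1, h), scan)) # filter byte 0
  ihdr <- c(u32_be(w), u32_be(h), as.raw(c(16, 0, 0, 0, 0)))
  out <- c(
    as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
    png_chunk("IHDR", ihdr),
    png_chunk("IDAT", memCompress(raw_data, "gzip")),
    png_chunk("IEND", raw())
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# --- minimal single-frame DICOM reader --------------------------------------
# Part-10 files, little endian, explicit or implicit VR, uncompressed
# 16-bit single-frame pixel data. Reads only the tags the pipeline needs.

dcm_u16 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "little",
          signed = FALSE)
}
dcm_u32 <- function(raw, off) {
  readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
}

read_dicom_minimal <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 132 || rawToChar(raw[129:132]) != "DICM") {
    stop(sprintf("not a DICOM part-10 file: %s", path), call. = FALSE)
  }
  off <- 132L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  pixel_raw <- NULL
  while (off + 8 <= length(raw)) {
    group <- dcm_u16(raw, off)
    elem <- dcm_u16(raw, off + 2)
    vr <- rawToChar(raw[(off + 5):(off + 6)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit && vr %in% long_vrs) {
      len <- dcm_u32(raw, off + 8)
      hdr <- 12L
    } else if (explicit) {
      len <- dcm_u16(raw, off + 6)
      hdr <- 8L
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, off + 4)
      hdr <- 8L
    }
    if (len < 0) stop("undefined-length DICOM elements are not supported", call. = FALSE)
    val_off <- off + hdr
    if (val_off + len > length(raw)) stop("truncated DICOM element", call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "7fe0,0010") {
      pixel_raw <- raw[(val_off + 1):(val_off + len)]
    } else if (len > 0) {
      tags[[key]] <- raw[(val_off + 1):(val_off + len)]
    }
    off <- val_off + len
  }
  need_u16 <- function(key, what) {
    if (is.null(tags[[key]])) stop(sprintf("DICOM missing %s (%s)", what, key), call. = FALSE)
    readBin(tags[[key]], "integer", size = 2, endian = "little", signed = FALSE)
  }
  str_tag <- function(key) {
    if (is.null(tags[[key]])) return(NULL)
    trimws(rawToChar(tags[[key]]))
  }
  rows <- need_u16("0028,0010", "Rows")
  cols <- need_u16("0028,0011", "Columns")
  bits <- need_u16("0028,0100", "BitsAllocated")
  if (bits != 16) stop("only 16-bit DICOM pixel data is supported", call. = FALSE)
  pixrep <- if (!is.null(tags[["0028,0103"]])) need_u16("0028,0103", "PixelRepresentation") else 0L
  slope_s <- str_tag("0028,1053")
  inter_s <- str_tag("0028,1052")
  if (is.null(slope_s) || is.null(inter_s)) {
    stop("DICOM missing RescaleSlope/RescaleIntercept; refusing to guess HU scaling",
         call. = FALSE)
  }
  if (is.null(pixel_raw)) stop("DICOM missing PixelData", call. = FALSE)
  if (length(pixel_raw) < 2 * rows * cols) stop("DICOM PixelData too short", call. = FALSE)
  stored <- readBin(pixel_raw, "integer", n = rows * cols, size = 2,
                    endian = "little", signed = (pixrep == 1L))
  hu <- as.numeric(slope_s) * stored + as.numeric(inter_s)
  spacing <- NULL
  sp <- str_tag("0028,0030")
  if (!is.null(sp)) spacing <- as.numeric(strsplit(sp, "\\\\")[[1]])[1:2]
  thick <- str_tag("0018,0050")
  list(
    hu = matrix(hu, rows, cols, byrow = TRUE), # DICOM stores row by row
    pixel_spacing_mm = spacing,
    slice_thickness_mm = if (is.null(thick)) NULL else as.numeric(thick)
  )
}
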