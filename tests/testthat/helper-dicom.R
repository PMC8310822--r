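# Byte-level writer for tiny synthetic single-frame DICOM fixtures
# (part-10, explicit VR little endian). Independent of the package's
# reader; only the tags a CT slice needs.

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  head <- c(dcm_raw_u16(group), dcm_raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_raw_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_raw_u16(length(value_raw)), value_raw)
  }
}

write_test_dicom <- function(path, stored, slope = 1, intercept = -1024,
                             spacing = c(0.7, 0.7), thickness = 3,
                             include_rescale = TRUE) {
  rows <- nrow(stored)
  cols <- ncol(stored)
  pixel_bytes <- writeBin(as.integer(t(stored)), raw(), size = 2,
                          endian = "little") # row-major
  ds <- c(
    dcm_element(0x0018, 0x0050, "DS", charToRaw(format(thickness))),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(cols)),
    dcm_element(0x0028, 0x0030, "DS",
                charToRaw(paste(spacing, collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(0))
  )
  if (include_rescale) {
    ds <- c(ds,
      dcm_element(0x0028, 0x1052, "DS", charToRaw(format(intercept))),
      dcm_element(0x0028, 0x1053, "DS", charToRaw(format(slope)))
    )
  }
  ds <- c(ds, dcm_element(0x7FE0, 0x0010, "OW", pixel_bytes))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), ds), con)
  invisible(path)
}
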