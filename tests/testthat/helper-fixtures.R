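# Fixture builders. Everything is generated in code at test time; nothing
# binary is stored in the repository.

tiny_phantom_spec <- function(seed = 7L) {
  phantom_spec(shape = c(8L, 32L, 32L), radius_range = c(0.25, 0.35),
               deform_amplitude = 1, seed = seed)
}

tiny_arch <- function(...) {
  arch_spec(stage_channels = c(2L, 2L, 4L, 4L, 4L), dropout_rate = 0, ...)
}

# ---- minimal explicit-VR little-endian DICOM writer ----------------------

dcm_raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
dcm_raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- c(dcm_raw_u16(group), dcm_raw_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0L, 0L)), dcm_raw_u32(length(value_raw)), value_raw)
  } else {
    c(head, dcm_raw_u16(length(value_raw)), value_raw)
  }
}

dcm_str_el <- function(group, element, vr, s) dcm_element(group, element, vr, charToRaw(s))

# Write one single-frame slice. `pixels` is a rows x cols integer matrix of
# raw (pre-rescale) values, stored row-major as signed 16-bit.
write_test_dicom <- function(path, pixels, series_uid, instance,
                             position = NULL, orientation = c(1, 0, 0, 0, 1, 0),
                             slope = 1, intercept = 0, pixel_spacing = c(1, 1),
                             omit_position = FALSE) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  body <- c(
    dcm_str_el(0x0008, 0x0018, "UI", sprintf("1.2.3.4.%d", instance)),
    dcm_str_el(0x0020, 0x000E, "UI", series_uid),
    dcm_str_el(0x0020, 0x0013, "IS", as.character(instance)),
    if (!omit_position) c(
      dcm_str_el(0x0020, 0x0032, "DS", paste(position, collapse = "\\")),
      dcm_str_el(0x0020, 0x0037, "DS", paste(orientation, collapse = "\\"))
    ),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_u16(rows)),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_u16(cols)),
    dcm_str_el(0x0028, 0x0030, "DS", paste(pixel_spacing, collapse = "\\")),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_u16(16L)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_u16(1L)),
    dcm_str_el(0x0028, 0x1052, "DS", as.character(intercept)),
    dcm_str_el(0x0028, 0x1053, "DS", as.character(slope)),
    dcm_element(0x7FE0, 0x0010, "OW",
                writeBin(as.integer(t(pixels)), raw(), size = 2L, endian = "little"))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0L), 128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_str_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"), con)
  writeBin(body, con)
  invisible(path)
}

# A 5-slice series with shuffled filenames; slice z has constant raw value
# 100 * z and position z * thickness along the normal.
write_test_series <- function(dir, n = 5L, shuffle = TRUE, thickness = 2.5,
                              slope = 1, intercept = 0, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file_order <- if (shuffle) c(3L, 1L, 5L, 2L, 4L)[seq_len(n)] else seq_len(n)
  for (k in seq_len(n)) {
    z <- file_order[k]
    write_test_dicom(file.path(dir, sprintf("slice_%02d.dcm", k)),
                     pixels = matrix(100L * z, 4L, 6L),
                     series_uid = "9.8.7.6", instance = z,
                     position = c(0, 0, z * thickness),
                     slope = slope, intercept = intercept, ...)
  }
  invisible(dir)
}
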