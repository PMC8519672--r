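# Minimal DICOM reader for single-frame CT/MR series stored as one .dcm per
# slice (CHAOS-style), supporting the explicit-VR little-endian transfer
# syntax. Only the tags needed to assemble a volume are parsed: series UID,
# image position/orientation, instance number, rows/columns, pixel spacing,
# bits allocated, pixel representation, rescale slope/intercept, pixel data.

dcm_tag <- function(group, element) sprintf("%04X,%04X", group, element)

dcm_u16 <- function(raw, at) {
  readBin(raw[at:(at + 1L)], "integer", size = 2L, endian = "little", signed = FALSE)
}
dcm_u32 <- function(raw, at) {
  v <- readBin(raw[at:(at + 3L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# Parse one explicit-VR little-endian file into a tag -> raw-value list.
dcm_parse_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM") {
    stop("not a DICOM part-10 file: ", path)
  }
  pos <- 133L
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- list()
  vrs <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- dcm_u16(raw, pos)
    element <- dcm_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- dcm_u32(raw, pos + 8L)
      vstart <- pos + 12L
    } else {
      len <- dcm_u16(raw, pos + 6L)
      vstart <- pos + 8L
    }
    if (len > 0 && vstart + len - 1L > n) stop("truncated DICOM element in ", path)
    key <- dcm_tag(group, element)
    tags[[key]] <- if (len > 0) raw[vstart:(vstart + len - 1L)] else raw(0)
    vrs[[key]] <- vr
    pos <- vstart + len
    if (key == dcm_tag(0x7FE0, 0x0010)) break
  }
  list(tags = tags, vrs = vrs, path = path)
}

dcm_string <- function(parsed, group, element) {
  v <- parsed$tags[[dcm_tag(group, element)]]
  if (is.null(v)) return(NULL)
  trimws(rawToChar(v[v != as.raw(0L)]))
}

dcm_numeric <- function(parsed, group, element) {
  s <- dcm_string(parsed, group, element)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1L]])
}

dcm_us <- function(parsed, group, element) {
  v <- parsed$tags[[dcm_tag(group, element)]]
  if (is.null(v)) return(NULL)
  dcm_u16(v, 1L)
}

dcm_pixel_matrix <- function(parsed) {
  rows <- dcm_us(parsed, 0x0028, 0x0010)
  cols <- dcm_us(parsed, 0x0028, 0x0011)
  bits <- dcm_us(parsed, 0x0028, 0x0100)
  signed <- identical(dcm_us(parsed, 0x0028, 0x0103), 1L)
  pd <- parsed$tags[[dcm_tag(0x7FE0, 0x0010)]]
  if (is.null(rows) || is.null(cols) || is.null(pd)) {
    stop("missing Rows/Columns/PixelData in ", parsed$path)
  }
  if (!identical(bits, 16L)) stop("only 16-bit pixel data supported; got ", bits)
  vals <- readBin(pd, "integer", n = rows * cols, size = 2L,
                  endian = "little", signed = signed)
  if (length(vals) != rows * cols) stop("pixel data size mismatch in ", parsed$path)
  matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
}

#' Read a DICOM series directory as a volume
#'
#' Reads every `.dcm` file in `dir` (one single-frame slice per file),
#' verifies they share one series UID, applies the rescale slope/intercept,
#' and stacks slices sorted by the projection of their image position onto
#' the slice normal -- never by filename. Files without position tags fall
#' back to instance-number ordering with a warning.
#'
#' @param dir Directory containing one DICOM series.
#' @return A [ct_volume()] in `(depth, height, width)` order, intensities in
#'   rescaled (HU-like) units.
#' @export
read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- list.files(dir, pattern = "\\.dcm$", ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L) stop("no .dcm files in ", dir)
  parsed <- lapply(files, dcm_parse_file)
  uids <- vapply(parsed, function(p) {
    u <- dcm_string(p, 0x0020, 0x000E)
    if (is.null(u)) "" else u
  }, character(1L))
  if (length(unique(uids)) > 1L) {
    stop("mixed series UIDs in ", dir, ": ", paste(unique(uids), collapse = ", "))
  }
  positions <- lapply(parsed, dcm_numeric, 0x0020, 0x0032)
  have_pos <- all(vapply(positions, function(p) !is.null(p) && length(p) == 3L, logical(1L)))
  if (have_pos) {
    orient <- dcm_numeric(parsed[[1L]], 0x0020, 0x0037)
    normal <- if (!is.null(orient) && length(orient) == 6L) {
      r <- orient[1:3]; c_ <- orient[4:6]
      c(r[2L] * c_[3L] - r[3L] * c_[2L],
        r[3L] * c_[1L] - r[1L] * c_[3L],
        r[1L] * c_[2L] - r[2L] * c_[1L])
    } else c(0, 0, 1)
    proj <- vapply(positions, function(p) sum(p * normal), numeric(1L))
    ord <- order(proj)
    dz <- if (length(proj) > 1L) stats::median(diff(sort(proj))) else 1
  } else {
    warning("image position tags missing; falling back to instance-number order")
    inst <- vapply(parsed, function(p) {
      v <- dcm_numeric(p, 0x0020, 0x0013)
      if (is.null(v)) NA_real_ else v[1L]
    }, numeric(1L))
    if (anyNA(inst)) stop("neither image position nor instance number available")
    ord <- order(inst)
    dz <- 1
  }
  slices <- lapply(parsed[ord], function(p) {
    slope <- dcm_numeric(p, 0x0028, 0x1053)
    intercept <- dcm_numeric(p, 0x0028, 0x1052)
    m <- dcm_pixel_matrix(p)
    m * (if (is.null(slope)) 1 else slope[1L]) +
      (if (is.null(intercept)) 0 else intercept[1L])
  })
  dims <- unique(lapply(slices, dim))
  if (length(dims) > 1L) stop("inconsistent slice dimensions in ", dir)
  vol <- array(0, dim = c(length(slices), dims[[1L]][1L], dims[[1L]][2L]))
  for (i in seq_along(slices)) vol[i, , ] <- slices[[i]]
  ps <- dcm_numeric(parsed[[1L]], 0x0028, 0x0030)
  if (is.null(ps) || length(ps) != 2L) ps <- c(1, 1)
  if (!is.finite(dz) || dz <= 0) dz <- 1
  ct_volume(vol, spacing = c(dz, ps[1L], ps[2L]))
}
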