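# Volume I/O and 2.5D input construction. Internal axis convention:
# (depth, height, width), 1-based indices, axial slices along the first
# axis. NIfTI files store (width, height, depth) per the usual x/y/z order;
# readers and writers permute accordingly so round trips are exact.

#' CT volume container
#'
#' @param voxels 3D numeric array `(depth, height, width)` of finite values.
#' @param spacing Positive voxel spacing in mm, `(depth, height, width)` order.
#' @param reference Optional `niftiImage` carrying the original header, kept
#'   for round-trip writing.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), reference = NULL) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!all(is.finite(voxels))) stop("voxels must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  structure(list(voxels = voxels, spacing = spacing, reference = reference),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("ct_volume: %d slices of %d x %d, spacing %.3g x %.3g x %.3g mm\n",
              d[1L], d[2L], d[3L], x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

# (depth, height, width) -> NIfTI's (width, height, depth) on-disk order
dhw_to_xyz <- function(arr) aperm(arr, c(3L, 2L, 1L))
xyz_to_dhw <- function(arr) aperm(arr, c(3L, 2L, 1L))

#' Read a NIfTI volume
#'
#' Axis order is canonicalized to `(depth, height, width)` with axial slices
#' along the first axis; the original header is preserved for round-trip
#' writing.
#'
#' @param path Path to a 3D NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [ct_volume()].
#' @export
read_nifti_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D image, got ", length(d), " dimensions")
  arr <- xyz_to_dhw(as.array(img))
  sp <- RNifti::pixdim(img)
  ct_volume(arr, spacing = rev(sp[seq_len(3L)]), reference = img)
}

#' Write a CT volume to NIfTI
#'
#' @param vol A [ct_volume()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  arr <- dhw_to_xyz(vol$voxels)
  img <- if (!is.null(vol$reference)) {
    RNifti::asNifti(arr, reference = vol$reference)
  } else {
    img0 <- RNifti::asNifti(arr)
    RNifti::pixdim(img0) <- rev(vol$spacing)
    img0
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a binary mask aligned to a reference volume
#'
#' The mask inherits the reference's NIfTI header (affine included) and is
#' stored as unsigned 8-bit integers. Non-binary input is thresholded at 0.5
#' with a warning.
#'
#' @param mask 3D array; values in `{0, 1}` expected.
#' @param reference The [ct_volume()] the mask is aligned to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, reference, path) {
  stopifnot(inherits(reference, "ct_volume"))
  if (!identical(dim(mask), dim(reference$voxels))) {
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match reference shape ",
         paste(dim(reference$voxels), collapse = "x"))
  }
  if (!all(mask %in% c(0, 1))) {
    warning("non-binary mask: thresholding at 0.5")
    mask <- (mask >= 0.5) * 1L
  }
  arr <- dhw_to_xyz(array(as.integer(mask), dim = dim(mask)))
  img <- if (!is.null(reference$reference)) {
    RNifti::asNifti(arr, reference = reference$reference, datatype = "uint8")
  } else {
    RNifti::asNifti(arr, pixdim = rev(reference$spacing), datatype = "uint8")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask volume
#'
#' @param path Path to a NIfTI mask.
#' @return Integer array `(depth, height, width)` with values in `{0, 1}`.
#' @export
read_mask <- function(path) {
  vol <- read_nifti_volume(path)
  m <- vol$voxels
  if (!all(m %in% c(0, 1))) stop("mask file contains non-binary values: ", path)
  array(as.integer(m), dim = dim(m))
}

#' Intensity window
#'
#' @param hu_min,hu_max Window bounds in HU; `hu_min < hu_max`. The default
#'   `[-200, 250]` is a typical liver window.
#' @return A `window_spec` list.
#' @export
window_spec <- function(hu_min = -200, hu_max = 250) {
  if (!(hu_min < hu_max)) stop("hu_min must be strictly less than hu_max")
  structure(list(hu_min = hu_min, hu_max = hu_max), class = "window_spec")
}

#' Window and normalize intensities
#'
#' Clips voxel values to `[hu_min, hu_max]` and maps the window linearly to
#' `[0, 1]`. Monotone non-decreasing, and idempotent on already-normalized
#' input with the `[0, 1]` window.
#'
#' @param vol A [ct_volume()].
#' @param w A [window_spec()].
#' @return A [ct_volume()] with values in `[0, 1]`.
#' @export
window_normalize <- function(vol, w = window_spec()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(w, "window_spec"))
  v <- pmin(pmax(vol$voxels, w$hu_min), w$hu_max)
  v <- (v - w$hu_min) / (w$hu_max - w$hu_min)
  ct_volume(v, spacing = vol$spacing, reference = vol$reference)
}

#' Build 2.5D slice triplets
#'
#' One triplet per axial slice: the slice plus its upper and lower
#' neighbours stacked as channels. Boundary slices use edge replication
#' (slice 0 stands in for the missing slice below slice 1, and likewise at
#' the top), so predictions cover every slice.
#'
#' @param vol A [ct_volume()] (or bare 3D array).
#' @return List of length `depth`; element `z` has `stack`, a
#'   `3 x height x width` array with channels `(z-1, z, z+1)`, and
#'   `center_index = z` (1-based).
#' @export
make_triplets <- function(vol) {
  vox <- if (inherits(vol, "ct_volume")) vol$voxels else vol
  d <- dim(vox)
  stopifnot(length(d) == 3L, d[1L] >= 1L)
  lapply(seq_len(d[1L]), function(z) {
    lo <- max(z - 1L, 1L)
    hi <- min(z + 1L, d[1L])
    stack <- array(0, dim = c(3L, d[2L], d[3L]))
    stack[1L, , ] <- vox[lo, , ]
    stack[2L, , ] <- vox[z, , ]
    stack[3L, , ] <- vox[hi, , ]
    list(stack = stack, center_index = z)
  })
}

#' Pair LiTS-style volumes and segmentations in a directory
#'
#' @param dir Directory containing `volume-*.nii` and `segmentation-*.nii`.
#' @return Data frame with columns `case`, `volume`, `segmentation` (full
#'   paths), sorted by case index.
#' @export
list_volume_pairs <- function(dir) {
  vols <- list.files(dir, pattern = "^volume-[0-9]+\\.nii(\\.gz)?$", full.names = TRUE)
  if (length(vols) == 0L) stop("no volume-*.nii files in ", dir)
  idx <- as.integer(sub("^volume-([0-9]+)\\..*$", "\\1", basename(vols)))
  segs <- file.path(dir, sub("^volume-", "segmentation-", basename(vols)))
  missing <- !file.exists(segs)
  if (any(missing)) {
    stop("unpaired volumes (no segmentation): ",
         paste(basename(vols[missing]), collapse = ", "))
  }
  o <- order(idx)
  data.frame(case = idx[o], volume = vols[o], segmentation = segs[o],
             stringsAsFactors = FALSE)
}

#' Build a 2.5D training set from volume/mask pairs
#'
#' Windows each volume, forms slice triplets and pairs each with its
#' centre-slice ground truth.
#'
#' @param pairs Data frame from [list_volume_pairs()], or a directory path.
#' @param window A [window_spec()].
#' @return List of samples, each with `stack` (`3 x H x W`, in `[0, 1]`) and
#'   `mask` (`H x W` binary matrix).
#' @export
load_triplet_dataset <- function(pairs, window = window_spec()) {
  if (is.character(pairs)) pairs <- list_volume_pairs(pairs)
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    vol <- window_normalize(read_nifti_volume(pairs$volume[i]), window)
    mask <- read_mask(pairs$segmentation[i])
    trips <- make_triplets(vol)
    for (t in trips) {
      out[[length(out) + 1L]] <- list(stack = t$stack,
                                      mask = mask[t$center_index, , ])
    }
  }
  out
}
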