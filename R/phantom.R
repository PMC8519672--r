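# Deterministic synthetic CT-like phantoms: a single connected, smoothly
# deformed ellipsoid ("liver") embedded in a noisy background, with a paired
# binary mask, written in the same NIfTI layout the readers consume. These
# stand in for clinical volumes so that every other module is testable
# without external data.

#' Phantom specification
#'
#' Defaults mimic liver-vs-background contrast after CT windowing:
#' foreground around 100 HU, background around -50 HU, noise SD 15 HU --
#' values inside the default `[-200, 250]` display window used by
#' [window_normalize()].
#'
#' @param shape Integer `(depth, height, width)` voxel counts; depth >= 3.
#' @param fg_mean,bg_mean Foreground/background intensity (HU-like).
#' @param noise_sd Gaussian intensity noise standard deviation; >= 0.
#' @param radius_range Length-2 range of ellipsoid semi-axes as a fraction of
#'   each volume extent, within `(0, 0.5]`.
#' @param deform_amplitude Amplitude (voxels) of the low-frequency sinusoidal
#'   radial boundary deformation; >= 0.
#' @param seed Integer seed; identical specs produce bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(16L, 64L, 64L), fg_mean = 100, bg_mean = -50,
                         noise_sd = 15, radius_range = c(0.2, 0.35),
                         deform_amplitude = 1.5, seed = 42L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop("invalid field 'shape': need 3 positive extents")
  if (shape[1L] < 3L) stop("invalid field 'shape': depth must be >= 3")
  if (length(radius_range) != 2L || any(radius_range <= 0) || any(radius_range > 0.5) ||
      radius_range[1L] > radius_range[2L]) {
    stop("invalid field 'radius_range': need an increasing range within (0, 0.5]")
  }
  if (length(noise_sd) != 1L || noise_sd < 0) stop("invalid field 'noise_sd': must be >= 0")
  if (length(deform_amplitude) != 1L || deform_amplitude < 0) {
    stop("invalid field 'deform_amplitude': must be >= 0")
  }
  structure(list(shape = shape, fg_mean = fg_mean, bg_mean = bg_mean,
                 noise_sd = noise_sd, radius_range = as.numeric(radius_range),
                 deform_amplitude = deform_amplitude, seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Lehmer-style mixing of (seed, i) into an independent 31-bit per-case seed;
# all intermediates stay below 2^53 so the arithmetic is exact in doubles.
derive_seed <- function(seed, i) {
  m <- 2147483647
  x <- (abs(as.double(seed)) + 1) %% m
  x <- (x * 48271) %% m
  x <- (x + (as.double(i) * 69621) %% m) %% m
  x <- (x * 48271) %% m
  x <- (x * 16807) %% m
  as.integer(x)
}

#' Generate one synthetic phantom
#'
#' A randomly oriented ellipsoid with a smooth low-frequency radial boundary
#' deformation; the deformation is radial about the centre, so the region is
#' star-shaped and therefore a single connected component. The volume is
#' `bg_mean + (fg_mean - bg_mean) * mask + N(0, noise_sd)`.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (a [ct_volume()]) and `mask` (integer array of
#'   the same shape with values in `{0, 1}`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$shape
  with_seed(spec$seed, {
    centre <- (sh + 1) / 2 + stats::runif(3, -0.05, 0.05) * sh
    radii <- stats::runif(3, spec$radius_range[1L], spec$radius_range[2L]) * sh
    rot <- random_rotation()
    freq <- sample(1:3, 2L, replace = TRUE)
    phase <- stats::runif(2, 0, 2 * pi)
    co <- expand_grid_coords(sh)            # 3 x nvox, (d, h, w) order
    q <- rot %*% (co - centre)
    e <- sqrt(colSums((q / radii)^2))
    theta <- atan2(q[2L, ], q[1L, ])
    phi_ang <- atan2(q[3L, ], sqrt(q[1L, ]^2 + q[2L, ]^2))
    wobble <- sin(freq[1L] * theta + phase[1L]) * cos(freq[2L] * phi_ang + phase[2L])
    rel_amp <- spec$deform_amplitude / mean(radii)
    rel_amp <- min(rel_amp, 0.45)           # keep the region star-shaped
    mask_v <- as.integer(e + rel_amp * wobble <= 1)
    mask <- array(mask_v, dim = sh)
    vox <- spec$bg_mean + (spec$fg_mean - spec$bg_mean) * mask
    if (spec$noise_sd > 0) {
      vox <- vox + array(stats::rnorm(prod(sh), sd = spec$noise_sd), dim = sh)
    }
    list(volume = ct_volume(vox, spacing = c(1, 1, 1)), mask = mask)
  })
}

expand_grid_coords <- function(sh) {
  d <- rep(seq_len(sh[1L]), times = sh[2L] * sh[3L])
  h <- rep(rep(seq_len(sh[2L]), each = sh[1L]), times = sh[3L])
  w <- rep(seq_len(sh[3L]), each = sh[1L] * sh[2L])
  rbind(d, h, w)
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` NIfTI pairs following the LiTS naming convention
#' (`volume-i.nii`, `segmentation-i.nii`, `i` starting at 0) plus a
#' `manifest.csv`. Per-case seeds are derived deterministically from
#' `spec$seed`, so repeated runs are byte-identical.
#'
#' @param n Number of cases; >= 1.
#' @param spec A [phantom_spec()] template.
#' @param out_dir Output directory (created if missing).
#' @return Data frame manifest with columns `case`, `volume`, `segmentation`,
#'   `seed`.
#' @export
generate_phantom_dataset <- function(n, spec, out_dir) {
  stopifnot(n >= 1, inherits(spec, "phantom_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L) stop("output directory not writable: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    case_spec <- spec
    case_spec$seed <- derive_seed(spec$seed, i)
    ph <- generate_phantom(case_spec)
    vpath <- file.path(out_dir, sprintf("volume-%d.nii", i - 1L))
    spath <- file.path(out_dir, sprintf("segmentation-%d.nii", i - 1L))
    write_volume(ph$volume, vpath)
    write_mask(ph$mask, ph$volume, spath)
    rows[[i]] <- data.frame(case = i - 1L, volume = basename(vpath),
                            segmentation = basename(spath), seed = case_spec$seed)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}
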