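# Training objectives: soft Dice loss, boundary loss driven by the signed
# Euclidean distance map of the ground-truth region, their weighted
# composite, and the Wasserstein critic/generator losses.

#' Loss configuration
#'
#' @param alpha Weight of the Dice term in the composite loss
#'   `alpha * L_Dice + (1 - alpha) * L_BD`; in `[0, 1]`. Default 0.1, so the
#'   boundary term dominates.
#' @param reduction How the boundary integrand is reduced over the image
#'   domain: `"mean"` (default; keeps `alpha`'s balance independent of image
#'   size) or `"sum"`.
#' @param adv_weight Non-negative weight `lambda` of the adversarial term in
#'   the generator's total training loss.
#' @param type Segmentation objective: `"composite"` (default; the Dice +
#'   boundary fusion), or one of the ablation baselines `"dice"`,
#'   `"boundary"`, `"iou"`, `"bce"`.
#' @return A `loss_config` list.
#' @export
loss_config <- function(alpha = 0.1, reduction = c("mean", "sum"), adv_weight = 0.01,
                        type = c("composite", "dice", "boundary", "iou", "bce")) {
  reduction <- match.arg(reduction)
  type <- match.arg(type)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  if (!is.numeric(adv_weight) || length(adv_weight) != 1L || adv_weight < 0) {
    stop("adv_weight must be a single non-negative value")
  }
  structure(list(alpha = alpha, reduction = reduction, adv_weight = adv_weight,
                 type = type),
            class = "loss_config")
}

check_binary <- function(m, what = "mask") {
  if (!all(m %in% c(0, 1))) stop(what, " must contain only 0 and 1")
  invisible(m)
}

#' Dice loss
#'
#' `1 - 2|A n B| / (|A| + |B|)` where `A` is the predicted foreground and `B`
#' the ground-truth foreground. Soft predictions are handled by the standard
#' continuous relaxation: `|A n B| = sum(p * t)`, `|A| + |B| = sum(p) + sum(t)`.
#' A smoothing constant (1e-6) enters numerator and denominator only when both
#' regions are empty, so the printed identities hold exactly otherwise.
#'
#' @param pred Probability map in `[0, 1]` or binary mask, same shape as `target`.
#' @param target Binary ground-truth mask.
#' @return Scalar in `[0, 1]`; 0 for perfect overlap.
#' @export
dice_loss <- function(pred, target) {
  if (!identical(dim2(pred), dim2(target))) stop("pred and target shapes differ")
  check_binary(target, "target")
  if (anyNA(pred) || !all(is.finite(pred))) stop("pred contains non-finite values")
  if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]")
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target)
  if (denom == 0) {
    eps <- 1e-6
    return(1 - (2 * inter + eps) / (denom + eps))
  }
  1 - 2 * inter / denom
}

# dim() that treats a bare vector as 1 x n.
dim2 <- function(x) if (is.null(dim(x))) c(1L, length(x)) else dim(x)

as_grid <- function(x) {
  if (is.null(dim(x))) matrix(x, nrow = 1L) else x
}

#' Signed Euclidean distance map of a binary region
#'
#' The boundary level set of region `G`: for every pixel, the Euclidean
#' distance to the nearest boundary pixel of `G` (foreground pixels with a
#' 4-adjacent background neighbour), negated strictly inside `G`, zero on the
#' boundary itself, positive outside.
#'
#' @param target Binary mask (matrix or vector) with at least one foreground
#'   and one background pixel.
#' @return Numeric array of the same shape.
#' @export
signed_distance_map <- function(target) {
  g <- as_grid(target)
  check_binary(g, "target")
  if (all(g == 1) || all(g == 0)) {
    stop("boundary undefined: mask is all-", if (all(g == 1)) "foreground" else "background")
  }
  boundary <- boundary_pixels(g)
  if (!any(boundary)) stop("boundary undefined: no foreground pixel touches background")
  # exact EDT: distance of every pixel to the nearest boundary pixel
  dist <- EBImage::distmap(1 - boundary, metric = "euclidean")
  dist <- as.numeric(dist)
  dim(dist) <- dim(g)
  phi <- dist
  inside <- g == 1 & !boundary
  phi[inside] <- -dist[inside]
  if (is.null(dim(target))) phi <- as.numeric(phi)
  phi
}

# Foreground pixels with a 4-adjacent background neighbour (in-image
# neighbours only; the image border is not treated as background).
boundary_pixels <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  bg <- g == 0
  nb <- matrix(FALSE, nr, nc)
  if (nr > 1L) {
    nb[-1L, ] <- nb[-1L, ] | bg[-nr, ]
    nb[-nr, ] <- nb[-nr, ] | bg[-1L, ]
  }
  if (nc > 1L) {
    nb[, -1L] <- nb[, -1L] | bg[, -nc]
    nb[, -nc] <- nb[, -nc] | bg[, -1L]
  }
  (g == 1) & nb
}

#' Boundary loss
#'
#' Reduction over the image domain of `phi_G(p) * s(p)`: the ground-truth
#' signed distance map weighted by the predicted foreground probability.
#' Negative values reward probability mass strictly inside the true region;
#' the minimum over all probability maps is attained by the ground-truth
#' region itself.
#'
#' @param pred Probability map, same shape as `phi`.
#' @param phi Signed distance map from [signed_distance_map()].
#' @param reduction `"mean"` (default) or `"sum"`.
#' @return Scalar; may be negative.
#' @export
boundary_loss <- function(pred, phi, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  if (!identical(dim2(pred), dim2(phi))) stop("pred and phi shapes differ")
  v <- sum(phi * pred)
  if (reduction == "mean") v / length(phi) else v
}

#' Composite segmentation loss
#'
#' `alpha * L_Dice + (1 - alpha) * L_BD`, the weighted fusion of region
#' overlap and boundary agreement. The signed distance map is computed from
#' `target` unless supplied.
#'
#' @param pred Probability map or binary mask.
#' @param target Binary ground-truth mask.
#' @param cfg A [loss_config()].
#' @param phi Optional precomputed signed distance map of `target`.
#' @return Scalar loss.
#' @export
composite_loss <- function(pred, target, cfg = loss_config(), phi = NULL) {
  stopifnot(inherits(cfg, "loss_config"))
  ld <- dice_loss(pred, target)
  if (is.null(phi)) phi <- signed_distance_map(target)
  lb <- boundary_loss(pred, phi, reduction = cfg$reduction)
  cfg$alpha * ld + (1 - cfg$alpha) * lb
}

#' Wasserstein critic loss
#'
#' The quantity the critic minimizes: `mean(fake) - mean(real)`. Its negation
#' estimates the Wasserstein distance between annotation and prediction score
#' distributions.
#'
#' @param real_scores,fake_scores Non-empty numeric vectors of critic scores.
#' @return Scalar.
#' @export
critic_loss <- function(real_scores, fake_scores) {
  if (length(real_scores) == 0L || length(fake_scores) == 0L) {
    stop("score vectors must be non-empty")
  }
  mean(fake_scores) - mean(real_scores)
}

#' Generator adversarial loss
#'
#' `-mean(fake_scores)`: the generator is trained to raise the critic's
#' scores of its own outputs.
#'
#' @param fake_scores Non-empty numeric vector of critic scores on predictions.
#' @return Scalar.
#' @export
generator_adv_loss <- function(fake_scores) {
  if (length(fake_scores) == 0L) stop("fake_scores must be non-empty")
  -mean(fake_scores)
}

# Ablation baselines ---------------------------------------------------------

#' Soft IoU (Jaccard) loss
#'
#' `1 - |A n B| / |A u B|` with the continuous relaxation
#' `|A n B| = sum(p t)`, `|A u B| = sum(p) + sum(t) - sum(p t)`. An ablation
#' baseline for the composite objective.
#'
#' @inheritParams dice_loss
#' @return Scalar in `[0, 1]`.
#' @export
iou_loss <- function(pred, target) {
  if (!identical(dim2(pred), dim2(target))) stop("pred and target shapes differ")
  check_binary(target, "target")
  inter <- sum(pred * target)
  union <- sum(pred) + sum(target) - inter
  if (union == 0) return(0)
  1 - inter / union
}

#' Binary cross-entropy loss
#'
#' `-mean(t log p + (1 - t) log(1 - p))`, with probabilities clamped away
#' from 0 and 1 for numerical safety. An ablation baseline.
#'
#' @inheritParams dice_loss
#' @param eps Clamping constant.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, target, eps = 1e-7) {
  if (!identical(dim2(pred), dim2(target))) stop("pred and target shapes differ")
  check_binary(target, "target")
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(target * log(p) + (1 - target) * log(1 - p))
}

# Analytic gradients used by the training loop ------------------------------

dice_loss_grad <- function(pred, target) {
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target)
  if (denom == 0) return(array(0, dim = dim2(pred)))
  -2 * target / denom + 2 * inter / denom^2
}

boundary_loss_grad <- function(phi, reduction = "mean") {
  if (reduction == "mean") phi / length(phi) else phi
}

iou_loss_grad <- function(pred, target) {
  inter <- sum(pred * target)
  union <- sum(pred) + sum(target) - inter
  if (union == 0) return(array(0, dim = dim2(pred)))
  -(target * union - inter * (1 - target)) / union^2
}

bce_loss_grad <- function(pred, target, eps = 1e-7) {
  p <- pmin(pmax(pred, eps), 1 - eps)
  g <- (-target / p + (1 - target) / (1 - p)) / length(pred)
  g * (pred > eps & pred < 1 - eps)
}
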