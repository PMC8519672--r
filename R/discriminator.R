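# The Wasserstein critic: a small CNN that scores fused (candidate mask,
# annotation) stacks with a single unbounded linear output. Capacity is
# constrained by weight clipping, the plain-WGAN device.

#' Critic architecture specification
#'
#' @param channels Channel plan of the four convolution blocks; the
#'   published plan shrinks with depth: `(64, 64, 32, 32)`.
#' @param fc_width Width of the penultimate fully connected layer.
#' @param input_hw In-plane `(height, width)` of the fused input; needed to
#'   size the fully connected head. Must be at least 16 (four 2x pools).
#' @param in_channels Input channels; 2 for (prediction, annotation), 3 when
#'   the centre CT slice is also concatenated.
#' @return A `critic_spec` list.
#' @export
critic_spec <- function(channels = c(64, 64, 32, 32), fc_width = 32L,
                        input_hw = c(64L, 64L), in_channels = 2L) {
  channels <- as.integer(channels)
  if (length(channels) != 4L || any(channels < 1L)) {
    stop("channels must give four positive widths")
  }
  input_hw <- as.integer(rep(input_hw, length.out = 2L))
  if (any(input_hw < 16L)) {
    stop("input smaller than the receptive-field minimum (16x16): ",
         paste(input_hw, collapse = "x"))
  }
  structure(list(channels = channels, fc_width = as.integer(fc_width),
                 input_hw = input_hw, in_channels = as.integer(in_channels)),
            class = "critic_spec")
}

#' Fuse a predicted mask with an annotation
#'
#' Channel-wise concatenation: channel 1 the prediction, channel 2 the
#' annotation (order matters).
#'
#' @param pred_mask Probability map or binary mask (`H x W` matrix).
#' @param annotation Binary mask of the same shape.
#' @return Array `(2, H, W)`.
#' @export
fuse_inputs <- function(pred_mask, annotation) {
  if (!identical(dim2(pred_mask), dim2(annotation))) {
    stop("pred_mask and annotation shapes differ")
  }
  p <- as_grid(pred_mask); a <- as_grid(annotation)
  out <- array(0, c(2L, nrow(p), ncol(p)))
  out[1L, , ] <- p
  out[2L, , ] <- a
  out
}

#' Build the Wasserstein critic
#'
#' Four convolution blocks (1x3x3 kernels, stride 1, batch normalization,
#' ReLU), each followed by 1x2x2 max pooling that halves the in-plane size,
#' then two fully connected layers ending in a single linear unit. No
#' sigmoid or softmax anywhere on the output path: the score is an unbounded
#' scalar.
#'
#' @param spec A [critic_spec()].
#' @return A `wgan_critic` model; score batches with [critic_score()].
#' @export
build_discriminator <- function(spec = critic_spec()) {
  stopifnot(inherits(spec, "critic_spec"))
  ch <- spec$channels
  layers <- list()
  cin <- spec$in_channels
  hw <- spec$input_hw
  for (i in 1:4) {
    layers <- c(layers, list(
      conv3d(cin, ch[i], kernel = c(1, 3, 3)),
      batchnorm(ch[i]), relu_layer(),
      maxpool3d(c(1, 2, 2), stride = c(1, 2, 2))
    ))
    cin <- ch[i]
    hw <- hw %/% 2L
  }
  if (any(hw < 1L)) stop("input smaller than the receptive-field minimum")
  feat <- cin * hw[1L] * hw[2L]
  layers <- c(layers, list(flatten_layer(),
                           linear_layer(feat, spec$fc_width), relu_layer(),
                           linear_layer(spec$fc_width, 1L)))
  model <- nn_sequential(layers)
  class(model) <- c("wgan_critic", class(model))
  model$spec <- spec
  model
}

# (N, C, H, W) batch -> internal (C, H, W, 1, N)
stack_batch_to_tensor <- function(batch) {
  d <- dim(batch)
  stopifnot(length(d) == 4L)
  x <- aperm(batch, c(2L, 3L, 4L, 1L))
  dim(x) <- c(d[2L], d[3L], d[4L], 1L, d[1L])
  x
}

#' Score a batch of fused stacks
#'
#' @param model A `wgan_critic`.
#' @param batch Array `(N, in_channels, H, W)` of fused stacks (see
#'   [fuse_inputs()]).
#' @param training Logical; cache activations for backprop.
#' @return Numeric vector of `N` unbounded scores.
#' @export
critic_score <- function(model, batch, training = FALSE) {
  stopifnot(inherits(model, "wgan_critic"))
  d <- dim(batch)
  if (any(d[3:4] != model$spec$input_hw)) {
    stop("input size ", d[3L], "x", d[4L], " does not match the critic's ",
         paste(model$spec$input_hw, collapse = "x"))
  }
  out <- nn_forward(model, stack_batch_to_tensor(batch), training)
  as.numeric(out)
}

# Backward from per-sample score gradients; returns gradient w.r.t. the
# (N, C, H, W) input batch.
critic_backward_input <- function(model, dscores) {
  g <- matrix(dscores, nrow = 1L)
  dx <- nn_backward(model, g)
  d <- dim(dx)
  out <- aperm(dx, c(5L, 1L, 2L, 3L, 4L))
  dim(out) <- c(d[5L], d[1L], d[2L], d[3L])
  out
}

#' Clip critic weights
#'
#' Clamps every trainable scalar of the model into `[-c, c]`, the plain-WGAN
#' Lipschitz device. Idempotent.
#'
#' @param model Any model built by this package.
#' @param c Positive clipping constant; default 0.01.
#' @return The model, invisibly (modified in place).
#' @export
clip_weights <- function(model, c = 0.01) {
  stopifnot(c > 0)
  for (r in nn_param_refs(model)) {
    p <- r$env$params[[r$name]]
    p[p > c] <- c
    p[p < -c] <- -c
    r$env$params[[r$name]] <- p
  }
  invisible(model)
}

#' Largest absolute trainable weight
#'
#' @param model Any model built by this package.
#' @return Scalar `max |w|` over all trainable parameters.
#' @export
max_abs_weight <- function(model) {
  m <- 0
  for (r in nn_param_refs(model)) m <- max(m, max(abs(r$env$params[[r$name]])))
  m
}
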