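# The improved 2.5D VNet generator: five encoder stages and four decoder
# stages of series convolutions (1x3x3 intra-slice followed by 3x1x1
# inter-slice, each with batch normalization and ReLU), strided-convolution
# downsampling (in-plane only; the depth extent is the 3-slice stack),
# transposed-convolution upsampling, chained-residual-pooling skip
# connections fused by channel concatenation, and a final 1x1x1 projection
# with sigmoid read out at the centre slice.

#' Generator architecture specification
#'
#' @param stage_channels Channel widths of the five encoder stages.
#' @param kernel_mode `"series"` (default): each convolution block is a
#'   1x3x3 followed by a 3x1x1 kernel; `"full3d"`: a single 3x3x3 kernel.
#' @param crp_blocks Number of chained pool-convolve units per skip
#'   connection.
#' @param crp_kernel Pooling kernel of the CRP units, `(depth, height,
#'   width)`; odd so spatial size is preserved.
#' @param dropout_rate Dropout rate inside CRP units, in `[0, 1)`.
#' @param in_slices Number of input slices (the 2.5D stack); default 3.
#' @param out_channels Output channels of the final projection; 1 gives a
#'   sigmoid foreground probability.
#' @return An `arch_spec` list.
#' @export
arch_spec <- function(stage_channels = c(32, 64, 128, 256, 256),
                      kernel_mode = c("series", "full3d"),
                      crp_blocks = 2L, crp_kernel = c(1, 5, 5),
                      dropout_rate = 0.2, in_slices = 3L, out_channels = 1L) {
  kernel_mode <- match.arg(kernel_mode)
  stage_channels <- as.integer(stage_channels)
  if (length(stage_channels) != 5L || any(stage_channels < 1L)) {
    stop("stage_channels must give five positive encoder widths")
  }
  crp_kernel <- as.integer(rep(crp_kernel, length.out = 3L))
  if (any(crp_kernel %% 2L == 0L)) stop("crp_kernel must be odd in every axis")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (!in_slices %in% c(1L, 3L) && in_slices %% 2L == 0L) {
    stop("in_slices must be odd so a centre slice exists")
  }
  structure(list(stage_channels = stage_channels, kernel_mode = kernel_mode,
                 crp_blocks = as.integer(crp_blocks), crp_kernel = crp_kernel,
                 dropout_rate = dropout_rate, in_slices = as.integer(in_slices),
                 out_channels = as.integer(out_channels)),
            class = "arch_spec")
}

#' Series convolution block
#'
#' In `series` mode, a 1x3x3 intra-slice convolution followed by a 3x1x1
#' inter-slice convolution, each with batch normalization and ReLU -- a
#' separable alternative to a full 3D kernel. In `full3d` mode, a single
#' 3x3x3 convolution with the same trimmings. Spatial size is preserved.
#'
#' @param cin,cout Input/output channel counts.
#' @param mode `"series"` or `"full3d"`.
#' @return A block usable with [nn_forward()]/[nn_backward()].
#' @export
series_conv_block <- function(cin, cout, mode = c("series", "full3d")) {
  mode <- match.arg(mode)
  layers <- if (mode == "series") {
    list(conv3d(cin, cout, kernel = c(1, 3, 3)), batchnorm(cout), relu_layer(),
         conv3d(cout, cout, kernel = c(3, 1, 1)), batchnorm(cout), relu_layer())
  } else {
    list(conv3d(cin, cout, kernel = c(3, 3, 3)), batchnorm(cout), relu_layer())
  }
  blk <- nn_sequential(layers)
  class(blk) <- c("series_conv_block", class(blk))
  blk$mode <- mode
  blk
}

#' Downsampling block
#'
#' Strided convolution replacing pooling: 1x3x3 kernel, stride 2 in-plane
#' only (the 3-slice depth extent is preserved), then batch normalization
#' and ReLU. Halves height and width.
#'
#' @param cin,cout Input/output channel counts.
#' @return A block usable with [nn_forward()].
#' @export
downsample_block <- function(cin, cout) {
  blk <- nn_sequential(list(
    conv3d(cin, cout, kernel = c(1, 3, 3), stride = c(1, 2, 2), pad = c(0, 1, 1)),
    batchnorm(cout), relu_layer()
  ))
  class(blk) <- c("downsample_block", class(blk))
  blk
}

#' Upsampling (deconvolution) block
#'
#' Transposed convolution with stride 2 in-plane, doubling height and width,
#' followed by batch normalization and ReLU. `full3d` mode uses a 3x3x3
#' kernel (matching the published per-layer parameter counts); `series` mode
#' uses 1x3x3.
#'
#' @param cin,cout Input/output channel counts.
#' @param mode `"series"` or `"full3d"`.
#' @return A block usable with [nn_forward()].
#' @export
upsample_block <- function(cin, cout, mode = c("series", "full3d")) {
  mode <- match.arg(mode)
  k <- if (mode == "series") c(1, 3, 3) else c(3, 3, 3)
  p <- if (mode == "series") c(0, 1, 1) else c(1, 1, 1)
  blk <- nn_sequential(list(
    conv_transpose3d(cin, cout, kernel = k, stride = c(1, 2, 2), pad = p,
                     output_padding = c(0, 1, 1)),
    batchnorm(cout), relu_layer()
  ))
  class(blk) <- c("upsample_block", class(blk))
  blk
}

# ---- chained residual pooling --------------------------------------------

#' Chained residual pooling block
#'
#' A running sum starting at the input, to which each of `n_units` chained
#' pool-then-convolve branches is added: size-preserving max pooling
#' (default 1x5x5, stride 1, padding 2), a 1x3x3 convolution, batch
#' normalization, ReLU and dropout. Enlarges the receptive field of the skip
#' pathway without changing shape or channel count; with all convolution
#' weights zero it reduces to the identity.
#'
#' @param channels Channel count (unchanged).
#' @param n_units Number of chained units; default 2.
#' @param pool_kernel Pooling kernel `(depth, height, width)`.
#' @param dropout_rate Dropout rate applied on each branch during training.
#' @return A block usable with [nn_forward()].
#' @export
crp_block <- function(channels, n_units = 2L, pool_kernel = c(1, 5, 5),
                      dropout_rate = 0.2) {
  pool_kernel <- as.integer(rep(pool_kernel, length.out = 3L))
  stopifnot(all(pool_kernel %% 2L == 1L))
  units <- lapply(seq_len(n_units), function(i) {
    # separable max pooling: max over a kxk window = max over rows then
    # columns; 2k offset passes instead of k^2
    pool <- nn_sequential(list(
      maxpool3d(c(pool_kernel[1L], pool_kernel[2L], 1L), stride = c(1, 1, 1),
                pad = c((pool_kernel[1L] - 1L) %/% 2L,
                        (pool_kernel[2L] - 1L) %/% 2L, 0L)),
      maxpool3d(c(1L, 1L, pool_kernel[3L]), stride = c(1, 1, 1),
                pad = c(0L, 0L, (pool_kernel[3L] - 1L) %/% 2L))
    ))
    list(pool = pool,
         conv = conv3d(channels, channels, kernel = c(1, 3, 3)),
         bn = batchnorm(channels), relu = relu_layer(),
         drop = dropout_layer(dropout_rate))
  })
  children <- unlist(lapply(units, function(u) u[c("pool", "conv", "bn", "relu", "drop")]),
                     recursive = FALSE, use.names = FALSE)
  new_layer("crp_block", channels = channels, units = units, children = children)
}

#' @export
nn_forward.crp_block <- function(layer, x, training = FALSE) {
  s <- x
  h <- x
  for (u in layer$units) {
    h <- nn_forward(u$pool, h, training)
    h <- nn_forward(u$conv, h, training)
    h <- nn_forward(u$bn, h, training)
    h <- nn_forward(u$relu, h, training)
    h <- nn_forward(u$drop, h, training)
    s <- s + h
  }
  s
}

#' @export
nn_backward.crp_block <- function(layer, grad) {
  dh <- NULL
  for (u in rev(layer$units)) {
    g <- if (is.null(dh)) grad else grad + dh
    g <- nn_backward(u$drop, g)
    g <- nn_backward(u$relu, g)
    g <- nn_backward(u$bn, g)
    g <- nn_backward(u$conv, g)
    dh <- nn_backward(u$pool, g)
  }
  grad + dh
}

# ---- residual stage -------------------------------------------------------

# Short-range residual learning: the stage input is added to the stage body
# output (through a 1x1x1 projection when channel counts differ).
residual_stage <- function(cin, cout, n_blocks = 2L, mode = "series") {
  body <- nn_sequential(c(list(series_conv_block(cin, cout, mode)),
                          if (n_blocks > 1L) {
                            lapply(seq_len(n_blocks - 1L), function(i) {
                              series_conv_block(cout, cout, mode)
                            })
                          }))
  proj <- if (cin != cout) conv3d(cin, cout, kernel = c(1, 1, 1)) else NULL
  new_layer("residual_stage", body = body, proj = proj,
            children = c(list(body), if (!is.null(proj)) list(proj)))
}

#' @export
nn_forward.residual_stage <- function(layer, x, training = FALSE) {
  y <- nn_forward(layer$body, x, training)
  s <- if (is.null(layer$proj)) x else nn_forward(layer$proj, x, training)
  y + s
}

#' @export
nn_backward.residual_stage <- function(layer, grad) {
  gb <- nn_backward(layer$body, grad)
  gs <- if (is.null(layer$proj)) grad else nn_backward(layer$proj, grad)
  gb + gs
}

# ---- the generator --------------------------------------------------------

#' Build the 2.5D VNet generator
#'
#' Five encoder stages at the widths of `spec$stage_channels`, each two
#' series convolution blocks with a short-range residual; strided-conv
#' downsampling between stages; four decoder stages, each a stride-2
#' transposed convolution (doubling the skip's channel count), channel
#' concatenation with the CRP-filtered skip, and a residual series block;
#' then a 1x1x1 projection and sigmoid, read out at the centre slice.
#'
#' @param spec An [arch_spec()].
#' @return A `vnet_generator` model; run it with [generator_forward()].
#' @export
build_generator <- function(spec = arch_spec()) {
  stopifnot(inherits(spec, "arch_spec"))
  sc <- spec$stage_channels
  mode <- spec$kernel_mode
  enc <- list(residual_stage(1L, sc[1L], mode = mode))
  downs <- list()
  for (i in 2:5) {
    downs[[i - 1L]] <- downsample_block(sc[i - 1L], sc[i])
    enc[[i]] <- residual_stage(sc[i], sc[i], mode = mode)
  }
  crps <- list(); ups <- list(); dec <- list()
  dec_in <- sc[5L]
  for (j in 1:4) {
    skip_ch <- sc[5L - j]
    up_ch <- 2L * skip_ch
    ups[[j]] <- upsample_block(dec_in, up_ch, mode = mode)
    crps[[j]] <- crp_block(skip_ch, n_units = spec$crp_blocks,
                           pool_kernel = spec$crp_kernel,
                           dropout_rate = spec$dropout_rate)
    dec[[j]] <- residual_stage(up_ch + skip_ch, skip_ch, n_blocks = 1L, mode = mode)
    dec_in <- skip_ch
  }
  head <- conv3d(sc[1L], spec$out_channels, kernel = c(1, 1, 1))
  # sigmoid foreground probability for a single output channel, channel-wise
  # softmax for a two-channel (foreground, background) head
  out_act <- if (spec$out_channels == 1L) sigmoid_layer() else channel_softmax_layer()
  new_layer("vnet_generator", spec = spec, enc = enc, downs = downs,
            crps = crps, ups = ups, dec = dec, head = head, out_act = out_act,
            children = c(enc, downs, crps, ups, dec, list(head, out_act)))
}

#' Encoder channel plan of a built generator
#'
#' Reads the output channel width of each encoder stage back from the built
#' layers (not from the spec).
#'
#' @param model A `vnet_generator`.
#' @return Integer vector of five stage widths.
#' @export
encoder_channels <- function(model) {
  stopifnot(inherits(model, "vnet_generator"))
  vapply(model$enc, function(st) {
    convs <- Filter(function(l) inherits(l, "conv3d"), nn_collect(st$body))
    convs[[length(convs)]]$cout
  }, integer(1L))
}

# Pad H and W up to multiples of 16 (four halvings); returns padded tensor
# and the original size for cropping.
pad_to_multiple <- function(x, mult = 16L) {
  d <- dim(x)
  H2 <- as.integer(ceiling(d[2L] / mult) * mult)
  W2 <- as.integer(ceiling(d[3L] / mult) * mult)
  if (H2 == d[2L] && W2 == d[3L]) return(list(x = x, orig = d[c(2L, 3L)], padded = FALSE))
  message("in-plane size ", d[2L], "x", d[3L], " not divisible by ", mult,
          "; zero-padding to ", H2, "x", W2)
  xp <- array(0, c(d[1L], H2, W2, d[4L], d[5L]))
  xp[, seq_len(d[2L]), seq_len(d[3L]), , ] <- x
  list(x = xp, orig = d[c(2L, 3L)], padded = TRUE)
}

# Convert a batch of triplets (N, slices, H, W) to the internal layout
# (1, H, W, slices, N).
triplet_batch_to_tensor <- function(batch) {
  d <- dim(batch)
  stopifnot(length(d) == 4L)
  x <- aperm(batch, c(3L, 4L, 2L, 1L))
  dim(x) <- c(1L, d[3L], d[4L], d[2L], d[1L])
  x
}

#' Forward pass of the generator
#'
#' @param model A `vnet_generator` from [build_generator()].
#' @param x Input batch: array `(N, in_slices, H, W)` of windowed
#'   intensities in `[0, 1]` (a stacked set of slice triplets).
#' @param training Logical; enables dropout/batch statistics and caches
#'   activations for the backward pass.
#' @param zero_skips Integer vector of encoder stages (1-4) whose skip
#'   features are zeroed before the CRP block; a diagnostic for probing
#'   skip-pathway connectivity.
#' @return Array `(N, out_channels, H, W)` of centre-slice foreground
#'   probabilities in `[0, 1]`.
#' @export
generator_forward <- function(model, x, training = FALSE, zero_skips = integer(0)) {
  stopifnot(inherits(model, "vnet_generator"), length(dim(x)) == 4L)
  d <- dim(x)
  t5 <- triplet_batch_to_tensor(x)
  padded <- pad_to_multiple(t5)
  f <- padded$x
  skips <- vector("list", 4L)
  for (i in 1:5) {
    f <- nn_forward(model$enc[[i]], f, training)
    if (i < 5L) {
      skips[[i]] <- if (i %in% zero_skips) f * 0 else f
      f <- nn_forward(model$downs[[i]], f, training)
    }
  }
  split_at <- integer(4L)
  for (j in 1:4) {
    f <- nn_forward(model$ups[[j]], f, training)
    s <- nn_forward(model$crps[[j]], skips[[5L - j]], training)
    split_at[j] <- dim(f)[1L]
    f <- concat_channels(f, s)
    f <- nn_forward(model$dec[[j]], f, training)
  }
  logits <- nn_forward(model$head, f, training)
  dz <- dim(logits)[4L]
  centre <- (dz + 1L) %/% 2L
  lc <- logits[, , , centre, , drop = FALSE]
  prob <- nn_forward(model$out_act, lc, training)
  if (training) {
    model$cache <- list(split_at = split_at, centre = centre,
                        logits_dim = dim(logits), orig = padded$orig,
                        was_padded = padded$padded, in_dim = d)
  }
  # back to (N, C, H, W), cropped to the original in-plane size
  pd <- dim(prob)
  out <- aperm(prob, c(5L, 1L, 2L, 3L, 4L))
  dim(out) <- c(pd[5L], pd[1L], pd[2L], pd[3L])
  out[, , seq_len(d[3L]), seq_len(d[4L]), drop = FALSE]
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[-1L] == db[-1L]))
  out <- array(0, c(da[1L] + db[1L], da[2L], da[3L], da[4L], da[5L]))
  out[seq_len(da[1L]), , , , ] <- a
  out[da[1L] + seq_len(db[1L]), , , , ] <- b
  out
}

#' Backward pass of the generator
#'
#' @param model A `vnet_generator` run forward with `training = TRUE`.
#' @param grad Gradient of the loss w.r.t. the forward output,
#'   `(N, out_channels, H, W)`.
#' @return Gradient w.r.t. the input batch (discarded by callers; parameter
#'   gradients are accumulated in the layers), invisibly.
#' @export
generator_backward <- function(model, grad) {
  cache <- model$cache
  d <- cache$in_dim
  ld <- cache$logits_dim
  # embed into padded (C,H,W,1,N) then through sigmoid
  gfull <- array(0, c(ld[1L], ld[2L], ld[3L], 1L, ld[5L]))
  gp <- aperm(grad, c(2L, 3L, 4L, 1L))
  gfull[, seq_len(d[3L]), seq_len(d[4L]), 1L, ] <- gp
  g <- nn_backward(model$out_act, gfull)
  glog <- array(0, ld)
  glog[, , , cache$centre, ] <- g[, , , 1L, ]
  f <- nn_backward(model$head, glog)
  skip_grads <- vector("list", 4L)
  for (j in 4:1) {
    f <- nn_backward(model$dec[[j]], f)
    ns <- cache$split_at[j]
    gup <- f[seq_len(ns), , , , , drop = FALSE]
    gskip <- f[ns + seq_len(dim(f)[1L] - ns), , , , , drop = FALSE]
    skip_grads[[5L - j]] <- nn_backward(model$crps[[j]], gskip)
    f <- nn_backward(model$ups[[j]], gup)
  }
  for (i in 5:1) {
    if (i < 5L) {
      f <- nn_backward(model$downs[[i]], f)
      f <- f + skip_grads[[i]]
    }
    f <- nn_backward(model$enc[[i]], f)
  }
  invisible(f)
}
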