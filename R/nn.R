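# Minimal layer-based neural-network core with explicit reverse-mode
# differentiation. Tensors are plain numeric arrays in the fixed layout
# (channels, height, width, depth, batch); depth carries the 2.5D slice axis.
# Convolutions are evaluated as one BLAS GEMM per kernel offset, which keeps
# everything vectorised without compiled code.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$params)) e$params <- list()
  e$grads <- list()
  class(e) <- c(type, "nn_layer")
  e
}

#' Forward pass through a layer or model
#'
#' @param layer A layer or model built by this package.
#' @param x Input array in the internal `(C, H, W, D, N)` layout (or a matrix
#'   for fully connected layers).
#' @param training Logical; `TRUE` enables dropout and batch statistics and
#'   caches the activations needed by [nn_backward()].
#' @return The layer output.
#' @export
nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")

#' Backward pass through a layer or model
#'
#' Propagates the gradient of a scalar loss with respect to the layer output
#' back to its input, accumulating parameter gradients in the layer. Must
#' follow a forward pass with `training = TRUE`.
#'
#' @param layer A layer previously run forward in training mode.
#' @param grad Gradient with the same shape as the layer output.
#' @return Gradient with respect to the layer input.
#' @export
nn_backward <- function(layer, grad) UseMethod("nn_backward")

# Sub-layers reachable from a composite layer.
nn_children <- function(layer) UseMethod("nn_children")
#' @export
nn_children.default <- function(layer) if (is.null(layer$children)) list() else layer$children

nn_collect <- function(layer) {
  out <- list(layer)
  for (ch in nn_children(layer)) out <- c(out, nn_collect(ch))
  out
}

# References to every trainable parameter: list of (env, name) pairs.
nn_param_refs <- function(model) {
  refs <- list()
  for (ly in nn_collect(model)) {
    for (nm in names(ly$params)) refs[[length(refs) + 1L]] <- list(env = ly, name = nm)
  }
  refs
}

#' Count trainable parameters
#'
#' Exact number of trainable scalars reachable from a model or single layer:
#' convolution and fully connected weights and biases. Normalization layers
#' here are non-affine and contribute none.
#'
#' @param model A layer or model.
#' @return Integer count.
#' @examples
#' count_parameters(conv3d(3, 32, kernel = c(1, 3, 3)))  # 3*9*32 + 32 = 896
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "nn_layer"))
  n <- 0
  for (ly in nn_collect(model)) for (p in ly$params) n <- n + length(p)
  as.integer(n)
}

# ---- sequential container -------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) && !inherits(layers[[1L]], "nn_layer")) {
    layers <- layers[[1L]]
  }
  new_layer("nn_sequential", children = layers)
}

#' @export
nn_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (ch in layer$children) x <- nn_forward(ch, x, training)
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, grad) {
  for (ch in rev(layer$children)) grad <- nn_backward(ch, grad)
  grad
}

# ---- 3D convolution -------------------------------------------------------

# kernel/stride/pad are (depth, height, width) triples, matching the field's
# k_d x k_h x k_w notation (so 1x3x3 is an intra-slice kernel).
conv3d <- function(cin, cout, kernel, stride = c(1, 1, 1), pad = NULL, bias = TRUE,
                   init_sd = NULL) {
  kernel <- as.integer(rep(kernel, length.out = 3L))
  stride <- as.integer(rep(stride, length.out = 3L))
  if (is.null(pad)) {
    stopifnot(all(kernel %% 2L == 1L))
    pad <- (kernel - 1L) %/% 2L
  }
  pad <- as.integer(rep(pad, length.out = 3L))
  kvol <- prod(kernel)
  if (is.null(init_sd)) init_sd <- sqrt(2 / (cin * kvol))
  # weight layout (cout, cin, kh, kw, kd)
  W <- array(stats::rnorm(cout * cin * kvol, sd = init_sd),
             dim = c(cout, cin, kernel[2L], kernel[3L], kernel[1L]))
  params <- list(W = W)
  if (bias) params$b <- numeric(cout)
  new_layer("conv3d", cin = cin, cout = cout, kernel = kernel, stride = stride,
            pad = pad, bias = bias, params = params)
}

conv_pad <- function(x, pad, fill = 0) {
  if (all(pad == 0L)) return(x)
  d <- dim(x)
  xp <- array(fill, c(d[1L], d[2L] + 2L * pad[2L], d[3L] + 2L * pad[3L],
                      d[4L] + 2L * pad[1L], d[5L]))
  xp[, pad[2L] + seq_len(d[2L]), pad[3L] + seq_len(d[3L]),
     pad[1L] + seq_len(d[4L]), ] <- x
  xp
}

# Offset order must match the (cin, kh, kw, kd) flattening of the weight
# array: height offset fastest, then width, then depth.
conv_offsets <- function(k) {
  out <- vector("list", prod(k))
  i <- 0L
  for (cc in seq_len(k[1L])) for (b in seq_len(k[3L])) for (a in seq_len(k[2L])) {
    i <- i + 1L
    out[[i]] <- c(a, b, cc)
  }
  out
}

#' @export
nn_forward.conv3d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 5L, d[1L] == layer$cin)
  k <- layer$kernel; s <- layer$stride
  xp <- conv_pad(x, layer$pad)
  dp <- dim(xp)
  Ho <- (dp[2L] - k[2L]) %/% s[2L] + 1L
  Wo <- (dp[3L] - k[3L]) %/% s[3L] + 1L
  Do <- (dp[4L] - k[1L]) %/% s[1L] + 1L
  M <- Ho * Wo * Do * d[5L]
  cin <- d[1L]
  K <- prod(k)
  # im2col: one (cin * K) x M patch matrix, then a single GEMM
  Xcol <- matrix(0, cin * K, M)
  row0 <- 0L
  for (off in conv_offsets(k)) {
    slab <- xp[, off[1L] + s[2L] * (seq_len(Ho) - 1L),
               off[2L] + s[3L] * (seq_len(Wo) - 1L),
               off[3L] + s[1L] * (seq_len(Do) - 1L), , drop = FALSE]
    Xcol[row0 + seq_len(cin), ] <- slab
    row0 <- row0 + cin
  }
  Wmat <- layer$params$W
  dim(Wmat) <- c(layer$cout, cin * K)
  out <- Wmat %*% Xcol
  if (layer$bias) out <- out + layer$params$b
  dim(out) <- c(layer$cout, Ho, Wo, Do, d[5L])
  if (training) layer$cache <- list(Xcol = Xcol, xdim = d, pdim = dp, odim = dim(out))
  out
}

#' @export
nn_backward.conv3d <- function(layer, grad) {
  cache <- layer$cache
  d <- cache$xdim; od <- cache$odim
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  M <- prod(od[-1L])
  cin <- d[1L]
  gm <- grad
  dim(gm) <- c(layer$cout, M)
  Wmat <- layer$params$W
  dim(Wmat) <- c(layer$cout, cin * prod(k))
  dW <- tcrossprod(gm, cache$Xcol)
  dim(dW) <- dim(layer$params$W)
  dXcol <- crossprod(Wmat, gm)
  dxp <- array(0, cache$pdim)
  row0 <- 0L
  for (off in conv_offsets(k)) {
    dslab <- dXcol[row0 + seq_len(cin), , drop = FALSE]
    dim(dslab) <- c(cin, od[2L], od[3L], od[4L], od[5L])
    hidx <- off[1L] + s[2L] * (seq_len(od[2L]) - 1L)
    widx <- off[2L] + s[3L] * (seq_len(od[3L]) - 1L)
    didx <- off[3L] + s[1L] * (seq_len(od[4L]) - 1L)
    dxp[, hidx, widx, didx, ] <- dxp[, hidx, widx, didx, , drop = FALSE] + dslab
    row0 <- row0 + cin
  }
  layer$grads <- list(W = dW)
  if (layer$bias) layer$grads$b <- rowSums(gm)
  dxp[, p[2L] + seq_len(d[2L]), p[3L] + seq_len(d[3L]),
      p[1L] + seq_len(d[4L]), , drop = FALSE]
}

# ---- transposed 3D convolution -------------------------------------------

# Implemented as zero-dilation of the input followed by a stride-1
# convolution; the inner conv weight is the layer's parameter set, so
# parameter counts follow the usual Cin*K*Cout + Cout closed form.
conv_transpose3d <- function(cin, cout, kernel, stride = c(1, 2, 2), pad = NULL,
                             output_padding = NULL) {
  kernel <- as.integer(rep(kernel, length.out = 3L))
  stride <- as.integer(rep(stride, length.out = 3L))
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  pad <- as.integer(rep(pad, length.out = 3L))
  if (is.null(output_padding)) output_padding <- stride - 1L
  output_padding <- as.integer(rep(output_padding, length.out = 3L))
  inner <- conv3d(cin, cout, kernel, stride = c(1, 1, 1),
                  pad = kernel - 1L - pad, bias = TRUE,
                  init_sd = sqrt(2 / (cin * prod(kernel))))
  new_layer("conv_transpose3d", cin = cin, cout = cout, stride = stride,
            output_padding = output_padding, inner = inner,
            children = list(inner))
}

ct_dilate_positions <- function(n, s) 1L + s * (seq_len(n) - 1L)

#' @export
nn_forward.conv_transpose3d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  s <- layer$stride; op <- layer$output_padding
  Hd <- (d[2L] - 1L) * s[2L] + 1L + op[2L]
  Wd <- (d[3L] - 1L) * s[3L] + 1L + op[3L]
  Dd <- (d[4L] - 1L) * s[1L] + 1L + op[1L]
  z <- array(0, c(d[1L], Hd, Wd, Dd, d[5L]))
  z[, ct_dilate_positions(d[2L], s[2L]), ct_dilate_positions(d[3L], s[3L]),
    ct_dilate_positions(d[4L], s[1L]), ] <- x
  if (training) layer$cache <- list(xdim = d)
  nn_forward(layer$inner, z, training)
}

#' @export
nn_backward.conv_transpose3d <- function(layer, grad) {
  dz <- nn_backward(layer$inner, grad)
  d <- layer$cache$xdim
  s <- layer$stride
  dz[, ct_dilate_positions(d[2L], s[2L]), ct_dilate_positions(d[3L], s[3L]),
     ct_dilate_positions(d[4L], s[1L]), , drop = FALSE]
}

# ---- batch normalization --------------------------------------------------

# Non-affine: pure standardization per channel; adjacent convolutions carry
# bias/scale freedom, and parameter counts then match the conv-only closed
# forms throughout.
batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_layer("batchnorm", channels = channels, eps = eps, momentum = momentum,
            running_mean = numeric(channels), running_var = rep(1, channels),
            initialized = FALSE)
}

#' @export
nn_forward.batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  C <- layer$channels
  xm <- x
  dim(xm) <- c(C, length(x) %/% C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    istd <- 1 / sqrt(v + layer$eps)
    xhat <- (xm - mu) * istd
    m <- layer$momentum
    if (!layer$initialized) {
      layer$running_mean <- mu
      layer$running_var <- v
      layer$initialized <- TRUE
    } else {
      layer$running_mean <- (1 - m) * layer$running_mean + m * mu
      layer$running_var <- (1 - m) * layer$running_var + m * v
    }
    layer$cache <- list(xhat = xhat, istd = istd, dims = d, train = TRUE)
  } else {
    istd <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- (xm - layer$running_mean) * istd
    layer$cache <- list(istd = istd, dims = d, train = FALSE)
  }
  dim(xhat) <- d
  xhat
}

#' @export
nn_backward.batchnorm <- function(layer, grad) {
  cache <- layer$cache
  d <- cache$dims
  C <- layer$channels
  g <- grad
  dim(g) <- c(C, length(grad) %/% C)
  if (cache$train) {
    xhat <- cache$xhat
    dx <- cache$istd * (g - rowMeans(g) - xhat * rowMeans(g * xhat))
  } else {
    dx <- cache$istd * g
  }
  dim(dx) <- d
  dx
}

# ---- elementwise layers ---------------------------------------------------

relu_layer <- function() new_layer("relu_layer")
#' @export
nn_forward.relu_layer <- function(layer, x, training = FALSE) {
  y <- x * (x > 0)
  if (training) layer$cache <- list(mask = x > 0)
  y
}
#' @export
nn_backward.relu_layer <- function(layer, grad) grad * layer$cache$mask

sigmoid_layer <- function() new_layer("sigmoid_layer")
#' @export
nn_forward.sigmoid_layer <- function(layer, x, training = FALSE) {
  y <- 1 / (1 + exp(-x))
  if (training) layer$cache <- list(y = y)
  y
}
#' @export
nn_backward.sigmoid_layer <- function(layer, grad) {
  y <- layer$cache$y
  grad * y * (1 - y)
}

channel_softmax_layer <- function() new_layer("channel_softmax_layer")
#' @export
nn_forward.channel_softmax_layer <- function(layer, x, training = FALSE) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L], length(x) %/% d[1L])
  xm <- sweep(xm, 2L, do.call(pmax, asplit(xm, 1L)))
  e <- exp(xm)
  y <- sweep(e, 2L, colSums(e), "/")
  dim(y) <- d
  if (training) layer$cache <- list(y = y, dims = d)
  y
}
#' @export
nn_backward.channel_softmax_layer <- function(layer, grad) {
  d <- layer$cache$dims
  y <- layer$cache$y
  dim(y) <- c(d[1L], prod(d) %/% d[1L])
  g <- grad
  dim(g) <- dim(y)
  dx <- y * sweep(g, 2L, colSums(g * y))
  dim(dx) <- d
  dx
}

dropout_layer <- function(rate) {
  stopifnot(rate >= 0, rate < 1)
  new_layer("dropout_layer", rate = rate)
}
#' @export
nn_forward.dropout_layer <- function(layer, x, training = FALSE) {
  if (!training || layer$rate == 0) {
    layer$cache <- list(mask = NULL)
    return(x)
  }
  keep <- 1 - layer$rate
  mask <- array((stats::runif(length(x)) < keep) / keep, dim = dim(x))
  layer$cache <- list(mask = mask)
  x * mask
}
#' @export
nn_backward.dropout_layer <- function(layer, grad) {
  if (is.null(layer$cache$mask)) grad else grad * layer$cache$mask
}

# ---- max pooling ----------------------------------------------------------

maxpool3d <- function(kernel, stride = NULL, pad = c(0, 0, 0)) {
  kernel <- as.integer(rep(kernel, length.out = 3L))
  if (is.null(stride)) stride <- kernel
  stride <- as.integer(rep(stride, length.out = 3L))
  pad <- as.integer(rep(pad, length.out = 3L))
  new_layer("maxpool3d", kernel = kernel, stride = stride, pad = pad)
}

#' @export
nn_forward.maxpool3d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  k <- layer$kernel; s <- layer$stride
  xp <- conv_pad(x, layer$pad, fill = -Inf)
  dp <- dim(xp)
  Ho <- (dp[2L] - k[2L]) %/% s[2L] + 1L
  Wo <- (dp[3L] - k[3L]) %/% s[3L] + 1L
  Do <- (dp[4L] - k[1L]) %/% s[1L] + 1L
  od <- c(d[1L], Ho, Wo, Do, d[5L])
  best <- array(-Inf, od)
  arg <- array(0L, od)
  offi <- 0L
  for (a in seq_len(k[2L])) for (b in seq_len(k[3L])) for (cc in seq_len(k[1L])) {
    offi <- offi + 1L
    slab <- xp[, a + s[2L] * (seq_len(Ho) - 1L), b + s[3L] * (seq_len(Wo) - 1L),
               cc + s[1L] * (seq_len(Do) - 1L), , drop = FALSE]
    upd <- slab > best
    upd[is.na(upd)] <- TRUE   # propagate NaN inputs instead of dropping them
    best[upd] <- slab[upd]
    arg[upd] <- offi
  }
  if (training) layer$cache <- list(arg = arg, xdim = d, pdim = dp, odim = od)
  best
}

#' @export
nn_backward.maxpool3d <- function(layer, grad) {
  cache <- layer$cache
  d <- cache$xdim; od <- cache$odim
  k <- layer$kernel; s <- layer$stride; p <- layer$pad
  dxp <- array(0, cache$pdim)
  offi <- 0L
  for (a in seq_len(k[2L])) for (b in seq_len(k[3L])) for (cc in seq_len(k[1L])) {
    offi <- offi + 1L
    sel <- cache$arg == offi
    if (!any(sel)) next
    contrib <- grad * sel
    hidx <- a + s[2L] * (seq_len(od[2L]) - 1L)
    widx <- b + s[3L] * (seq_len(od[3L]) - 1L)
    didx <- cc + s[1L] * (seq_len(od[4L]) - 1L)
    dxp[, hidx, widx, didx, ] <- dxp[, hidx, widx, didx, , drop = FALSE] + contrib
  }
  dxp[, p[2L] + seq_len(d[2L]), p[3L] + seq_len(d[3L]),
      p[1L] + seq_len(d[4L]), , drop = FALSE]
}

# ---- fully connected ------------------------------------------------------

flatten_layer <- function() new_layer("flatten_layer")
#' @export
nn_forward.flatten_layer <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) layer$cache <- list(dims = d)
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}
#' @export
nn_backward.flatten_layer <- function(layer, grad) {
  dim(grad) <- layer$cache$dims
  grad
}

linear_layer <- function(fin, fout) {
  W <- matrix(stats::rnorm(fout * fin, sd = sqrt(2 / fin)), fout, fin)
  new_layer("linear_layer", fin = fin, fout = fout,
            params = list(W = W, b = numeric(fout)))
}
#' @export
nn_forward.linear_layer <- function(layer, x, training = FALSE) {
  stopifnot(is.matrix(x), nrow(x) == layer$fin)
  if (training) layer$cache <- list(x = x)
  layer$params$W %*% x + layer$params$b
}
#' @export
nn_backward.linear_layer <- function(layer, grad) {
  layer$grads <- list(W = grad %*% t(layer$cache$x), b = rowSums(grad))
  t(layer$params$W) %*% grad
}

# ---- optimizer ------------------------------------------------------------

# RMSProp, the optimizer customarily paired with weight-clipped Wasserstein
# critics (momentum-based updates interact badly with clipping).
rmsprop_init <- function(model) {
  refs <- nn_param_refs(model)
  list(refs = refs, ms = lapply(refs, function(r) r$env$params[[r$name]] * 0))
}

rmsprop_step <- function(state, lr, alpha = 0.99, eps = 1e-8) {
  for (i in seq_along(state$refs)) {
    r <- state$refs[[i]]
    g <- r$env$grads[[r$name]]
    if (is.null(g)) next
    state$ms[[i]] <- alpha * state$ms[[i]] + (1 - alpha) * g * g
    r$env$params[[r$name]] <- r$env$params[[r$name]] - lr * g / (sqrt(state$ms[[i]]) + eps)
  }
  state
}

# Finite-difference probe used by the test-suite gradient checks.
nn_numeric_grad <- function(fun, env, name, idx, h = 1e-4) {
  p <- env$params[[name]]
  p[idx] <- p[idx] + h
  env$params[[name]] <- p
  up <- fun()
  p[idx] <- p[idx] - 2 * h
  env$params[[name]] <- p
  dn <- fun()
  p[idx] <- p[idx] + h
  env$params[[name]] <- p
  (up - dn) / (2 * h)
}
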