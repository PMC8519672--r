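# Independent oracles used across tests.

# Exhaustive nearest-boundary-pixel search: the brute-force reference for
# signed_distance_map. Boundary pixels are foreground pixels with an
# in-image 4-adjacent background neighbour.
sdm_oracle <- function(mask) {
  m <- if (is.null(dim(mask))) matrix(mask, nrow = 1L) else mask
  nr <- nrow(m); nc <- ncol(m)
  is_boundary <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (m[i, j] != 1) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1L]; jj <- j + d[2L]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && m[ii, jj] == 0) {
        is_boundary[i, j] <- TRUE
      }
    }
  }
  bidx <- which(is_boundary, arr.ind = TRUE)
  if (nrow(bidx) == 0L) stop("no boundary pixels")
  phi <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d <- sqrt(min((bidx[, 1L] - i)^2 + (bidx[, 2L] - j)^2))
    phi[i, j] <- if (m[i, j] == 1 && !is_boundary[i, j]) -d else if (m[i, j] == 1) 0 else d
  }
  if (is.null(dim(mask))) as.numeric(phi) else phi
}

# Random binary mask guaranteed to contain both classes.
random_mask <- function(nr, nc, p = 0.5) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1L, p), nr, nc)
    if (any(m == 1) && any(m == 0)) return(m)
  }
}

# 6-connected component count for a 3D binary array (flood fill).
n_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ncomp <- 0L
  idx_fg <- which(mask == 1)
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      co <- arrayInd(cur, d)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- co
        nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        li <- nb[1L] + d[1L] * (nb[2L] - 1L) + d[1L] * d[2L] * (nb[3L] - 1L)
        if (mask[li] == 1 && lab[li] == 0L) {
          lab[li] <- ncomp
          queue <- c(queue, li)
        }
      }
    }
  }
  ncomp
}
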