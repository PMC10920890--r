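# 3D convolution machinery.
#
# A batch of cubic feature maps is stored as a matrix of shape
# (batch * positions, channels); positions are linearized column-major over
# (i, j, k), exactly the order obtained from `dim(grid) <- c(n^3, channels)`.
# A 3x3x3 convolution is computed as a sum over its 27 kernel offsets: each
# offset pairs a set of output positions with a set of input positions
# (precomputed index maps) and contributes one BLAS matrix product
# X[in, ] %*% W[offset, , ]. This makes forward and backward passes exact
# transposes of each other.

# index maps for a 3^3 kernel at stride s with "same/2" padding:
# output o (1..ceil(D/s)) reads input i = s*(o-1) + 1 + d, d in {-1,0,1}
conv_index_maps <- function(d_in, stride) {
  d_out <- as.integer(ceiling(d_in / stride))
  axis <- function(d) {
    o <- seq_len(d_out)
    i <- stride * (o - 1L) + 1L + d
    ok <- i >= 1L & i <= d_in
    list(o = o[ok], i = i[ok])
  }
  maps <- vector("list", 27L)
  k <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    ax <- axis(dx); ay <- axis(dy); az <- axis(dz)
    # linear indices, column-major over (x, y, z)
    lin <- function(cx, cy, cz, d) {
      gx <- rep(cx, times = length(cy) * length(cz))
      gy <- rep(rep(cy, each = length(cx)), times = length(cz))
      gz <- rep(cz, each = length(cx) * length(cy))
      gx + (gy - 1L) * d + (gz - 1L) * d * d
    }
    maps[[k]] <- list(
      out = lin(ax$o, ay$o, az$o, d_out),
      inp = lin(ax$i, ay$i, az$i, d_in)
    )
  }
  list(maps = maps, d_in = as.integer(d_in), d_out = d_out,
       p_in = as.integer(d_in)^3L, p_out = d_out^3L,
       row_cache = new.env(parent = emptyenv()))
}

# batch-replicated row indices, memoized per batch size (the cache is an
# environment, so it is shared across copies of the layer during training)
cached_rows <- function(m, batch) {
  key <- as.character(batch)
  rows <- m$row_cache[[key]]
  if (is.null(rows)) {
    rows <- lapply(m$maps, function(mk) list(
      ro = batch_rows(mk$out, batch, m$p_out),
      ri = batch_rows(mk$inp, batch, m$p_in)))
    m$row_cache[[key]] <- rows
  }
  rows
}

# replicate per-sample position indices across a batch
batch_rows <- function(idx, batch, positions) {
  as.vector(outer(idx, (seq_len(batch) - 1L) * positions, "+"))
}

conv_init <- function(c_in, c_out, d_in, stride) {
  sd <- sqrt(2 / (27 * c_in))
  list(W = array(stats::rnorm(27 * c_in * c_out, sd = sd),
                 dim = c(27L, c_in, c_out)),
       b = numeric(c_out),
       maps = conv_index_maps(d_in, stride))
}

conv_forward <- function(layer, X, batch) {
  m <- layer$maps
  rows <- cached_rows(m, batch)
  Y <- matrix(0, batch * m$p_out, dim(layer$W)[3])
  for (k in 1:27) {
    rk <- rows[[k]]
    if (!length(rk$ro)) next
    Y[rk$ro, ] <- Y[rk$ro, , drop = FALSE] +
      X[rk$ri, , drop = FALSE] %*% layer$W[k, , ]
  }
  sweep(Y, 2, layer$b, "+")
}

conv_backward <- function(layer, X, dY, batch) {
  m <- layer$maps
  rows <- cached_rows(m, batch)
  dW <- array(0, dim = dim(layer$W))
  dX <- matrix(0, nrow(X), ncol(X))
  for (k in 1:27) {
    rk <- rows[[k]]
    if (!length(rk$ro)) next
    dyk <- dY[rk$ro, , drop = FALSE]
    dW[k, , ] <- crossprod(X[rk$ri, , drop = FALSE], dyk)
    dX[rk$ri, ] <- dX[rk$ri, , drop = FALSE] + tcrossprod(dyk, layer$W[k, , ])
  }
  list(dW = dW, db = colSums(dY), dX = dX)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

global_avg_pool <- function(X, batch, positions) {
  rowsum(X, group = rep(seq_len(batch), each = positions)) / positions
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}
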