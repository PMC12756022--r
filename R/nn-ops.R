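# Neural-network primitives on dense R arrays.
#
# Volumes and activation maps are 4-D arrays with dim (nx, ny, nz, channels).
# 3-D convolution is evaluated as an im2col gather followed by one BLAS
# matrix product; all backward passes are derived by hand and verified by
# finite differences in the test suite. Large inputs are processed in
# z-chunks so reference-scale grids fit in memory.

CONV_KERNEL <- 3L          # fixed 3x3x3 kernels throughout the encoder
CONV_PAD <- 1L             # "same" padding for stride 1
CHUNK_LIMIT <- 4e7         # max elements of one im2col chunk

# Geometry (index-matrix) cache: im2col and pooling index matrices depend
# only on shapes, so they are built once per shape and reused across the
# training loop.
.geom_cache <- new.env(parent = emptyenv())

geom_cached <- function(key, builder) {
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  val <- builder()
  .geom_cache[[key]] <- val
  val
}

conv_out_dim <- function(n, stride) as.integer(floor((n - 1) / stride) + 1)

# Linear indices into the zero-padded spatial grid for every output voxel
# (rows) and kernel offset (27 columns). `rows` restricts to a contiguous
# range of output voxels (x-fastest ordering).
conv_index <- function(dims, stride, rows = NULL) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  px <- nx + 2L; py <- ny + 2L
  no <- c(conv_out_dim(nx, stride), conv_out_dim(ny, stride),
          conv_out_dim(nz, stride))
  nvox <- prod(no)
  if (is.null(rows)) rows <- seq_len(nvox)
  r0 <- rows - 1L
  ox <- r0 %% no[1]
  oy <- (r0 %/% no[1]) %% no[2]
  oz <- r0 %/% (no[1] * no[2])
  # padded (1-based) center coordinates of each output voxel
  cx <- ox * stride + 2L; cy <- oy * stride + 2L; cz <- oz * stride + 2L
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  idx <- matrix(0L, length(rows), 27L)
  for (o in seq_len(27L)) {
    idx[, o] <- (cx + off[o, 1]) + (cy + off[o, 2] - 1L) * px +
      (cz + off[o, 3] - 1L) * px * py
  }
  idx
}

pad_volume <- function(x) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2L, d[2] + 2L, d[3] + 2L, d[4]))
  out[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x
  out
}

# Full multi-channel im2col index matrix (nvox x 27*cin) into the flat
# padded array; cached per shape since it is geometry only.
conv_index_full <- function(dims, stride, cin) {
  key <- paste("conv", paste(dims, collapse = "x"), stride, cin, sep = "|")
  geom_cached(key, function() {
    npad <- prod(dims + 2L)
    S <- conv_index(dims, stride)
    idx <- matrix(0L, nrow(S), 27L * cin)
    for (c in seq_len(cin)) {
      idx[, ((c - 1L) * 27L + 1L):(c * 27L)] <- S + (c - 1L) * npad
    }
    # stored flat (dim stripped) so the gather never re-copies the index
    list(idx = as.vector(idx), dims = dim(idx))
  })
}

# im2col matrix for an input volume (small-shape fast path only).
conv_im2col <- function(x, stride) {
  d <- dim(x)
  xp <- pad_volume(x)
  ix <- conv_index_full(d[1:3], stride, d[4])
  col <- xp[ix$idx]
  dim(col) <- ix$dims
  col
}

# Forward 3-D convolution. W is a (27 * Cin) x Cout matrix whose rows are
# ordered offset-fastest within each input channel; b has length Cout.
# Returns the output array plus (for small shapes) the im2col matrix,
# reused by the backward pass.
conv3d_forward <- function(x, W, b, stride = 1L, keep_col = TRUE) {
  d <- dim(x)
  cin <- d[4]
  cout <- ncol(W)
  no <- c(conv_out_dim(d[1], stride), conv_out_dim(d[2], stride),
          conv_out_dim(d[3], stride))
  nvox <- prod(no)
  if (nvox * 27 * cin <= CHUNK_LIMIT) {
    col <- conv_im2col(x, stride)
    out <- col %*% W
    out <- sweep(out, 2L, b, "+")
    return(list(out = array(out, c(no, cout)),
                col = if (keep_col) col else NULL))
  }
  # chunked path for reference-scale grids: never materialize the full im2col
  xp <- pad_volume(x)
  npadvox <- prod(dim(xp)[1:3])
  out <- matrix(0, nvox, cout)
  chunk <- max(1L, as.integer(CHUNK_LIMIT / (27 * cin)))
  start <- 1L
  while (start <= nvox) {
    rows <- start:min(nvox, start + chunk - 1L)
    idx <- conv_index(d[1:3], stride, rows)
    col <- matrix(0, length(rows), 27L * cin)
    for (c in seq_len(cin)) {
      col[, ((c - 1L) * 27L + 1L):(c * 27L)] <-
        xp[as.vector(idx) + (c - 1L) * npadvox]
    }
    out[rows, ] <- col %*% W
    start <- start + chunk
  }
  out <- sweep(out, 2L, b, "+")
  list(out = array(out, c(no, cout)), col = NULL)
}

# Rearranged (flipped) kernel for the transposed convolution used in the
# stride-1 input-gradient pass: W2[(co-1)*27 + o, ci] = W[(ci-1)*27 +
# (28-o), co].
conv_weight_flip <- function(W, cin, cout) {
  W2 <- matrix(0, 27L * cout, cin)
  rev_o <- 28L - seq_len(27L)
  for (ci in seq_len(cin)) {
    blk <- W[((ci - 1L) * 27L + 1L):(ci * 27L), , drop = FALSE]  # 27 x cout
    W2[, ci] <- as.vector(blk[rev_o, , drop = FALSE])            # offset-fastest per co
  }
  W2
}

# Backward 3-D convolution: gradients for input, weights and bias. `col`
# is the cached im2col matrix from the forward pass (NULL to recompute).
conv3d_backward <- function(x, W, stride, dout, col = NULL,
                            need_dx = TRUE) {
  d <- dim(x)
  cin <- d[4]
  cout <- ncol(W)
  no <- dim(dout)[1:3]
  nvox <- prod(no)
  dout_m <- matrix(dout, nvox, cout)
  small <- nvox * 27 * max(cin, cout) <= CHUNK_LIMIT
  if (small) {
    if (is.null(col)) col <- conv_im2col(x, stride)
    dW <- crossprod(col, dout_m)
    db <- colSums(dout_m)
    dx <- NULL
    if (need_dx) {
      if (stride == 1L) {
        # transposed convolution: gather dout and multiply by the flipped
        # kernel (identical geometry because stride 1 keeps the grids equal)
        dcol <- conv_im2col(array(dout_m, c(no, cout)), 1L)
        dx <- array(dcol %*% conv_weight_flip(W, cin, cout), c(d[1:3], cin))
      } else {
        dx <- conv_scatter_dx(d, stride, dout_m %*% t(W))
      }
    }
    return(list(dx = dx, dW = dW, db = db))
  }
  # chunked fallback (reference-scale shapes)
  xp <- pad_volume(x)
  npadvox <- prod(dim(xp)[1:3])
  dxp <- numeric(npadvox * cin)
  dW <- matrix(0, nrow(W), cout)
  chunk <- max(1L, as.integer(CHUNK_LIMIT / (27 * max(cin, cout))))
  start <- 1L
  while (start <= nvox) {
    rows <- start:min(nvox, start + chunk - 1L)
    idx <- conv_index(d[1:3], stride, rows)
    colc <- matrix(0, length(rows), 27L * cin)
    for (c in seq_len(cin)) {
      colc[, ((c - 1L) * 27L + 1L):(c * 27L)] <-
        xp[as.vector(idx) + (c - 1L) * npadvox]
    }
    dW <- dW + crossprod(colc, dout_m[rows, , drop = FALSE])
    if (need_dx) {
      dcol <- dout_m[rows, , drop = FALSE] %*% t(W)
      for (c in seq_len(cin)) {
        base <- (c - 1L) * npadvox
        for (o in seq_len(27L)) {
          tgt <- base + idx[, o]
          # distinct targets for a fixed offset: the add is a safe scatter
          dxp[tgt] <- dxp[tgt] + dcol[, (c - 1L) * 27L + o]
        }
      }
    }
    start <- start + chunk
  }
  db <- colSums(dout_m)
  dx <- NULL
  if (need_dx) {
    dxp <- array(dxp, c(dim(xp)[1:3], cin))
    dx <- dxp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# Scatter-based input gradient for strided convolutions on small shapes.
conv_scatter_dx <- function(d, stride, dcol) {
  cin <- d[4]
  pd <- d[1:3] + 2L
  npadvox <- prod(pd)
  idx <- conv_index(d[1:3], stride)
  dxp <- numeric(npadvox * cin)
  for (c in seq_len(cin)) {
    base <- (c - 1L) * npadvox
    for (o in seq_len(27L)) {
      tgt <- base + idx[, o]
      dxp[tgt] <- dxp[tgt] + dcol[, (c - 1L) * 27L + o]
    }
  }
  dxp <- array(dxp, c(pd, cin))
  dxp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE]
}

# ---- max pooling -----------------------------------------------------------

# Non-overlapping max pooling by integer factors f = c(fx, fy, fz);
# remainder voxels are dropped (floor semantics).
maxpool3d_forward <- function(x, f) {
  d <- dim(x)
  no <- d[1:3] %/% f
  assert_that(all(no >= 1L), "pooling factor exceeds input extent")
  nvox <- prod(no)
  noff <- prod(f)
  idx <- geom_cached(
    paste("pool", paste(d[1:3], collapse = "x"),
          paste(f, collapse = "x"), sep = "|"),
    function() {
      off <- as.matrix(expand.grid(dx = 0:(f[1] - 1L), dy = 0:(f[2] - 1L),
                                   dz = 0:(f[3] - 1L)))
      r0 <- seq_len(nvox) - 1L
      ox <- (r0 %% no[1]) * f[1] + 1L
      oy <- ((r0 %/% no[1]) %% no[2]) * f[2] + 1L
      oz <- (r0 %/% (no[1] * no[2])) * f[3] + 1L
      m <- matrix(0L, nvox, noff)
      for (o in seq_len(noff)) {
        m[, o] <- (ox + off[o, 1]) + (oy + off[o, 2] - 1L) * d[1] +
          (oz + off[o, 3] - 1L) * d[1] * d[2]
      }
      m
    })
  out <- array(0, c(no, d[4]))
  amax <- matrix(0L, nvox, d[4])
  spat <- prod(d[1:3])
  sel <- cbind(seq_len(nvox), 0L)
  for (c in seq_len(d[4])) {
    m <- x[as.vector(idx) + (c - 1L) * spat]
    dim(m) <- c(nvox, noff)
    a <- max.col(m, ties.method = "first")
    sel[, 2] <- a
    amax[, c] <- idx[sel]
    out[, , , c] <- array(m[sel], no)
  }
  list(out = out, amax = amax, in_dim = d)
}

maxpool3d_backward <- function(cache, dout) {
  d <- cache$in_dim
  dx <- array(0, d)
  nvox <- nrow(cache$amax)
  spat <- prod(d[1:3])
  dout_m <- matrix(dout, nvox, d[4])
  flat <- numeric(spat * d[4])
  for (c in seq_len(d[4])) {
    tgt <- (c - 1L) * spat + cache$amax[, c]
    flat[tgt] <- flat[tgt] + dout_m[, c]
  }
  array(flat, d)
}

# Partition boundaries used by adaptive pooling, instance ground truth and
# key-patch geometry: cell i along an axis of length n covers voxels
# (floor(n*(i-1)/t) + 1) .. floor(n*i/t).
cell_bounds <- function(n, t) {
  lo <- floor(n * (seq_len(t) - 1) / t) + 1L
  hi <- floor(n * seq_len(t) / t)
  cbind(lo = as.integer(lo), hi = as.integer(hi))
}

# Adaptive max pooling to an exact target grid (possibly uneven cells).
adaptive_maxpool_forward <- function(x, target) {
  d <- dim(x)
  assert_that(all(d[1:3] >= target), "adaptive pool target exceeds input grid")
  nvox <- prod(target)
  geom <- geom_cached(
    paste("adapt", paste(d[1:3], collapse = "x"),
          paste(target, collapse = "x"), sep = "|"),
    function() {
      bx <- cell_bounds(d[1], target[1])
      by <- cell_bounds(d[2], target[2])
      bz <- cell_bounds(d[3], target[3])
      # per output cell (x-fastest, matching the flat instance ordering),
      # the flat spatial indices of its member voxels
      members <- vector("list", nvox)
      n <- 0L
      for (kz in seq_len(target[3])) for (ky in seq_len(target[2]))
        for (kx in seq_len(target[1])) {
          n <- n + 1L
          g <- expand.grid(x = bx[kx, 1]:bx[kx, 2], y = by[ky, 1]:by[ky, 2],
                           z = bz[kz, 1]:bz[kz, 2])
          members[[n]] <- g$x + (g$y - 1L) * d[1] + (g$z - 1L) * d[1] * d[2]
        }
      width <- max(lengths(members))
      idx <- matrix(1L, nvox, width)
      valid <- matrix(FALSE, nvox, width)
      for (i in seq_len(nvox)) {
        k <- length(members[[i]])
        idx[i, seq_len(k)] <- members[[i]]
        valid[i, seq_len(k)] <- TRUE
      }
      list(idx = idx, valid = valid, bounds = list(x = bx, y = by, z = bz))
    })
  idx <- geom$idx
  width <- ncol(idx)
  spat <- prod(d[1:3])
  out <- array(0, c(target, d[4]))
  amax <- matrix(0L, nvox, d[4])
  sel <- cbind(seq_len(nvox), 0L)
  for (c in seq_len(d[4])) {
    m <- x[as.vector(idx) + (c - 1L) * spat]
    dim(m) <- c(nvox, width)
    m[!geom$valid] <- -Inf
    a <- max.col(m, ties.method = "first")
    sel[, 2] <- a
    amax[, c] <- idx[sel]
    out[, , , c] <- array(m[sel], target)
  }
  list(out = out, amax = amax, in_dim = d, bounds = geom$bounds)
}

adaptive_maxpool_backward <- function(cache, dout) {
  maxpool3d_backward(cache, dout)
}

# ---- batch normalization ---------------------------------------------------

# Normalizes each channel over the spatial voxels of the current volume
# (one volume per forward pass), with running statistics used in eval mode.
batchnorm_forward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  m <- prod(d[1:3])
  xm <- matrix(x, m, d[4])
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * va
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
  }
  sd <- sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, sd, "/")
  y <- sweep(sweep(xhat, 2L, bn$gamma, "*"), 2L, bn$beta, "+")
  list(out = array(y, d), xhat = xhat, sd = sd, bn = bn, dims = d,
       training = training)
}

batchnorm_backward <- function(cache, gamma, dout) {
  d <- cache$dims
  m <- prod(d[1:3])
  dy <- matrix(dout, m, d[4])
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  if (cache$training) {
    t1 <- sweep(dy, 2L, colMeans(dy), "-")
    t2 <- sweep(cache$xhat, 2L, colMeans(dy * cache$xhat), "*")
    dx <- sweep(t1 - t2, 2L, gamma / cache$sd, "*")
  } else {
    dx <- sweep(dy, 2L, gamma / cache$sd, "*")
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- dropout ---------------------------------------------------------------

dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array(stats::rbinom(length(x), 1L, 1 - rate), dim(x)) / (1 - rate)
  list(out = x * mask, mask = mask)
}

dropout_backward <- function(cache, dout) {
  if (is.null(cache$mask)) dout else dout * cache$mask
}

# ---- parameter initialization and Adam -------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

new_bn_state <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       running_mean = rep(0, channels), running_var = rep(1, channels))
}

# Recursively walk two parallel nested lists of numeric leaves.
map_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map_params(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

param_zeros_like <- function(p) {
  if (is.list(p)) lapply(p, param_zeros_like) else p * 0
}

param_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, param_flatten), use.names = FALSE)
  else as.numeric(p)
}

param_global_norm <- function(g) sqrt(sum(param_flatten(g)^2))

param_scale <- function(p, s) {
  if (is.list(p)) lapply(p, param_scale, s = s) else p * s
}

param_add <- function(a, b) map_params(a, b, function(x, y) x + y)

#' Create an Adam optimizer state
#' @keywords internal
adam_init <- function(params, lr = 1e-4, weight_decay = 1e-5,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, wd = weight_decay, beta1 = beta1, beta2 = beta2, eps = eps,
       t = 0L, m = param_zeros_like(params), v = param_zeros_like(params))
}

# One Adam step (classic coupled L2 weight decay added to the gradient).
adam_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
  step_leaf <- function(p, g, m, v) {
    g <- g + opt$wd * p
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p_new <- p - opt$lr * (m / bc1) / (sqrt(v / bc2) + opt$eps)
    list(p = p_new, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      pn <- p; mn <- m; vn <- v
      for (i in seq_along(p)) {
        r <- walk(p[[i]], g[[i]], m[[i]], v[[i]])
        pn[[i]] <- r$p; mn[[i]] <- r$m; vn[[i]] <- r$v
      }
      list(p = pn, m = mn, v = vn)
    } else {
      step_leaf(p, g, m, v)
    }
  }
  r <- walk(params, grads, opt$m, opt$v)
  opt$m <- r$m; opt$v <- r$v
  list(opt = opt, params = r$p)
}
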