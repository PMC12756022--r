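# Positional encodings for instance coordinates.
#
# CLE (collateral location encoding) = a two-layer GELU network over the
# normalized (x, y, z) instance centers, fused with the instance features
# by per-column standardization + concatenation, then reweighted by a
# softmax importance attention over instances. The simpler comparators are
# SPE (fixed sinusoidal features, fused the same way) and NPE (the GELU
# network without the importance weighting).

#' Initialize a learnable positional network
#'
#' Two affine layers around a GELU: `a2 %*% GELU(a1 p + b1) + b2` applied
#' rowwise to coordinates p in [0,1]^3.
#'
#' @param d_pos output encoding dimension (default 16).
#' @param hidden hidden width (default 32).
#' @param seed integer seed.
#' @return parameter list (a1 3 x hidden, b1, a2 hidden x d_pos, b2).
#' @export
posnet_init <- function(d_pos = 16L, hidden = 32L, seed = 1L) {
  with_seed(seed, list(a1 = he_init(3L, hidden, 3L), b1 = rep(0, hidden),
                       a2 = he_init(hidden, d_pos, hidden),
                       b2 = rep(0, d_pos)))
}

#' Encode instance positions with the learnable GELU network
#'
#' @param coords N x 3 matrix of normalized coordinates in [0,1]^3
#'   (values outside trigger an extrapolation warning, not an error).
#' @param params parameters from [posnet_init()].
#' @return N x d_pos encoding matrix.
#' @export
encode_positions <- function(coords, params) {
  coords <- as.matrix(coords)
  assert_that(ncol(coords) == 3L, "coords must be N x 3")
  if (any(coords < 0 | coords > 1)) {
    warning("coords outside [0,1]^3: positional network extrapolates")
  }
  z1 <- sweep(coords %*% params$a1, 2L, params$b1, "+")
  sweep(gelu(z1) %*% params$a2, 2L, params$b2, "+")
}

encode_positions_cache <- function(coords, params) {
  z1 <- sweep(as.matrix(coords) %*% params$a1, 2L, params$b1, "+")
  g <- gelu(z1)
  out <- sweep(g %*% params$a2, 2L, params$b2, "+")
  list(out = out, z1 = z1, g = g, coords = as.matrix(coords))
}

encode_positions_backward <- function(cache, params, dout) {
  da2 <- crossprod(cache$g, dout)
  db2 <- colSums(dout)
  dg <- dout %*% t(params$a2)
  dz1 <- dg * gelu_grad(cache$z1)
  list(grads = list(a1 = crossprod(cache$coords, dz1), b1 = colSums(dz1),
                    a2 = da2, b2 = db2))
}

#' Fixed sinusoidal positional encoding
#'
#' For each axis and frequency k = 1..n_freq emits
#' sin(2^(k-1) * 2 * pi * c) and cos(2^(k-1) * 2 * pi * c), giving
#' d_pos = 3 * 2 * n_freq columns (sin block first, then cos, per axis
#' then frequency).
#'
#' @param coords N x 3 normalized coordinates.
#' @param n_freq number of frequencies (>= 1).
#' @return N x (6 * n_freq) matrix.
#' @export
sinusoidal_encoding <- function(coords, n_freq = 3L) {
  assert_that(is_count(n_freq) && n_freq >= 1L, "n_freq must be >= 1")
  coords <- as.matrix(coords)
  cols <- list()
  for (axis in 1:3) for (k in seq_len(n_freq)) {
    ang <- 2^(k - 1) * 2 * pi * coords[, axis]
    cols[[length(cols) + 1L]] <- sin(ang)
    cols[[length(cols) + 1L]] <- cos(ang)
  }
  do.call(cbind, cols)
}

# Per-instance (row) standardization across features (population
# variance, epsilon-guarded), with cache for backprop. Normalizing within
# each instance keeps the fused blocks scale-commensurate without coupling
# instances: a bag-wide (per-column) standardization would leak global bag
# statistics into every instance and let attention classify from an
# arbitrary cell, defeating the MIL semantics.
rowstd_forward <- function(x, eps = 1e-5) {
  mu <- rowMeans(x)
  va <- rowMeans(x^2) - mu^2
  sd <- sqrt(pmax(va, 0) + eps)
  xhat <- (x - mu) / sd
  list(out = xhat, xhat = xhat, sd = sd)
}

rowstd_backward <- function(cache, dout) {
  (dout - rowMeans(dout) - cache$xhat * rowMeans(dout * cache$xhat)) /
    cache$sd
}

#' Fuse instance features with a positional encoding
#'
#' Each block is standardized per instance across its features (so the two
#' blocks are scale-commensurate while instances stay decoupled) and the
#' results are concatenated rowwise: `H' = [std(F) || std(Fhat)]`. A
#' zero-column encoding degrades to `std(F)`.
#'
#' @param features N x D instance features.
#' @param encoding N x d_pos positional encoding (or NULL / 0 columns).
#' @return N x (D + d_pos) fused matrix.
#' @export
fuse <- function(features, encoding = NULL) {
  fuse_forward(features, encoding)$out
}

fuse_forward <- function(features, encoding = NULL) {
  f <- rowstd_forward(as.matrix(features))
  if (is.null(encoding) || ncol(encoding) == 0L) {
    return(list(out = f$out, f = f, e = NULL, d = ncol(features)))
  }
  assert_that(nrow(encoding) == nrow(features),
              "features and encoding disagree on instance count")
  e <- rowstd_forward(as.matrix(encoding))
  list(out = cbind(f$out, e$out), f = f, e = e, d = ncol(features))
}

fuse_backward <- function(cache, dout) {
  d <- cache$d
  dfeat <- rowstd_backward(cache$f, dout[, seq_len(d), drop = FALSE])
  denc <- if (is.null(cache$e)) NULL else
    rowstd_backward(cache$e, dout[, -seq_len(d), drop = FALSE])
  list(dfeatures = dfeat, dencoding = denc)
}

#' Adaptive importance weighting over instances
#'
#' Computes one scalar score per instance from the fused features, a
#' softmax over the instance axis (so the weights are in [0,1] and sum to
#' 1) and the elementwise product `O = H' * A`.
#'
#' @param H_prime N x d fused features.
#' @param w length-d weight vector.
#' @param b scalar bias.
#' @return list with `A` (N weights summing to 1) and `O` (N x d).
#' @export
importance_weighting <- function(H_prime, w, b = 0) {
  r <- importance_forward(as.matrix(H_prime), as.numeric(w), b)
  list(A = r$A, O = r$out)
}

importance_forward <- function(H, w, b) {
  s <- drop(H %*% w) + b
  assert_that(all(is.finite(s)), "non-finite importance scores")
  A <- softmax_vec(s)
  list(out = H * A, A = A, H = H, w = w)
}

importance_backward <- function(cache, dout) {
  A <- cache$A; H <- cache$H
  dH <- dout * A
  dA <- rowSums(dout * H)
  ds <- A * (dA - sum(dA * A))
  list(dH = dH + outer(ds, cache$w),
       dw = drop(crossprod(H, ds)), db = sum(ds))
}
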