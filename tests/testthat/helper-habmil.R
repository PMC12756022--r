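# Shared fixtures: tiny configurations and in-code phantom builders. All
# fixtures are generated programmatically under fixed seeds.

tiny_encoder <- function(input_shape = c(12L, 12L, 10L), embed_dim = 6L) {
  encoder_config(stage_channels = c(3L, 4L), conv_strides = c(1L, 1L),
                 pool_sizes = list(2L, 2L), dropout_rate = 0,
                 target_instance_grid = c(2L, 2L, 2L),
                 embed_dim = embed_dim, input_shape = input_shape)
}

tiny_model <- function(pos = "cle", pool = "dga", ...) {
  model_config(tiny_encoder(), pos_encoding = pos, pooling = pool,
               d_pos = 4L, pos_hidden = 5L, n_freq = 2L, att_hidden = 5L,
               lsvd_rank = 2L, att_dropout = 0, ...)
}

# A small smoke cohort on disk (16 x 16 x 12 grids), built once per test
# run and shared read-only.
smoke_cohort_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "habmil-smoke-cohort")
      if (!file.exists(file.path(dir, "manifest.tsv"))) {
        generate_cohort(4, 4, grid_shape = c(16L, 16L, 12L), seed = 11,
                        out_dir = dir)
      }
    }
    dir
  }
})

smoke_model_config <- function(pos = "cle", pool = "dga") {
  model_config(
    encoder_config(stage_channels = c(3L, 4L), conv_strides = c(1L, 1L),
                   pool_sizes = list(2L, 2L), dropout_rate = 0,
                   target_instance_grid = c(2L, 2L, 2L), embed_dim = 6L,
                   input_shape = c(16L, 16L, 12L)),
    pos_encoding = pos, pooling = pool, d_pos = 4L, pos_hidden = 5L,
    att_hidden = 5L, lsvd_rank = 2L, att_dropout = 0)
}

# Brute-force 3-D convolution oracle (zero padding 1, 3x3x3 kernel):
# direct septuple loop, deliberately independent of the im2col path.
naive_conv3d <- function(x, W, b, stride = 1L) {
  d <- dim(x)
  cin <- d[4]; cout <- ncol(W)
  no <- floor((d[1:3] - 1) / stride) + 1
  out <- array(0, c(no, cout))
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  for (co in seq_len(cout)) {
    for (oz in seq_len(no[3])) for (oy in seq_len(no[2]))
      for (ox in seq_len(no[1])) {
        cx <- (ox - 1) * stride + 1; cy <- (oy - 1) * stride + 1
        cz <- (oz - 1) * stride + 1
        acc <- b[co]
        for (ci in seq_len(cin)) for (o in seq_len(27)) {
          ix <- cx + off[o, 1]; iy <- cy + off[o, 2]; iz <- cz + off[o, 3]
          if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] &&
              iz >= 1 && iz <= d[3]) {
            acc <- acc + x[ix, iy, iz, ci] * W[(ci - 1) * 27 + o, co]
          }
        }
        out[ox, oy, oz, co] <- acc
      }
  }
  out
}

# Finite-difference gradient check utilities for the full model.
param_paths <- function(p) {
  out <- list()
  walk <- function(q, pre) {
    if (is.list(q)) for (n in seq_along(q)) walk(q[[n]], c(pre, n))
    else out[[length(out) + 1L]] <<- pre
  }
  walk(p, integer(0))
  out
}

get_leaf <- function(p, path) {
  for (i in path) p <- p[[i]]
  p
}

set_leaf <- function(p, path, v) {
  if (length(path) == 1L) {
    p[[path]] <- v
    return(p)
  }
  p[[path[1]]] <- set_leaf(p[[path[1]]], path[-1], v)
  p
}
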