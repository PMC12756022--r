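# The deep instance generator: a small 3-D fully convolutional network that
# maps a standardized multi-modal volume to a grid of instance embeddings.
# Each stage is conv(3x3x3) -> batch norm -> ReLU -> max pool -> dropout;
# a 1x1x1 projection then maps channels to the embedding dimension and an
# adaptive max pool brings the spatial grid to the exact target instance
# grid (needed because shapes such as 155 are not reachable by uniform
# strides alone).

#' Instance encoder configuration
#'
#' @param in_channels input channels (3 modalities).
#' @param stage_channels output channels per conv stage; the default first
#'   stage has 32 channels.
#' @param conv_strides integer stride per stage (length matching
#'   `stage_channels`).
#' @param pool_sizes list (or vector) of pooling factors per stage; scalars
#'   are applied isotropically.
#' @param dropout_rate dropout probability after each pool (default 0.25).
#' @param target_instance_grid integer triple: the instance grid
#'   (H*, W*, S*).
#' @param embed_dim instance embedding dimension D (default 64).
#' @param input_shape expected standardized input shape (used to validate
#'   the shape algebra up front).
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(in_channels = 3L,
                           stage_channels = c(32L, 64L, 64L),
                           conv_strides = rep(1L, length(stage_channels)),
                           pool_sizes = rep(2L, length(stage_channels)),
                           dropout_rate = 0.25,
                           target_instance_grid = c(2L, 2L, 2L),
                           embed_dim = 64L,
                           input_shape = c(48L, 48L, 32L)) {
  assert_that(length(stage_channels) >= 1L, "need at least one stage")
  assert_that(length(conv_strides) == length(stage_channels),
              "one stride per stage required")
  if (!is.list(pool_sizes)) pool_sizes <- as.list(pool_sizes)
  assert_that(length(pool_sizes) == length(stage_channels),
              "one pool size per stage required")
  pool_sizes <- lapply(pool_sizes, function(p) {
    p <- as.integer(p)
    if (length(p) == 1L) p <- rep(p, 3L)
    assert_that(length(p) == 3L && all(p >= 1L), "bad pool size")
    p
  })
  assert_that(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0,1)")
  assert_that(all(target_instance_grid >= 1L),
              "target_instance_grid must be >= 1")
  cfg <- structure(list(in_channels = as.integer(in_channels),
                        stage_channels = as.integer(stage_channels),
                        conv_strides = as.integer(conv_strides),
                        pool_sizes = pool_sizes,
                        dropout_rate = dropout_rate,
                        target_instance_grid = as.integer(target_instance_grid),
                        embed_dim = as.integer(embed_dim),
                        input_shape = as.integer(input_shape)),
                   class = "encoder_config")
  # validate the shape algebra: pooling must not undershoot the target grid
  shp <- encoder_grid_shape(cfg, input_shape)
  assert_that(all(shp$pre_adaptive >= cfg$target_instance_grid),
              sprintf("config reduces %s below the %s instance grid",
                      paste(input_shape, collapse = "x"),
                      paste(cfg$target_instance_grid, collapse = "x")))
  cfg
}

#' Reference-scale encoder configuration
#'
#' 240 x 240 x 155 input, 3x3x3 kernels, 32 first-stage channels and a
#' 2 x 2 x 2 x 64 output feature grid. The first convolution uses stride 2
#' so the full-resolution activation map is never materialized.
#' @return `encoder_config`.
#' @export
reference_encoder_config <- function() {
  encoder_config(stage_channels = c(32L, 64L, 64L),
                 conv_strides = c(2L, 1L, 1L),
                 pool_sizes = list(2L, 2L, 2L),
                 target_instance_grid = c(2L, 2L, 2L), embed_dim = 64L,
                 input_shape = c(240L, 240L, 155L))
}

#' Desk-scale encoder configuration
#'
#' A small configuration for CPU training on 48 x 48 x 32 phantom volumes:
#' one stride-2 convolution stage with 16 channels. Its receptive field (5
#' voxels) is deliberately local — wide enough to detect a cross-modality
#' lesion conjunction, but too narrow to reach the volume border from any
#' interior lesion, so instance features carry no covert position
#' signature and positional information enters only through the location
#' encoding.
#' @param embed_dim embedding dimension (default 32).
#' @return `encoder_config`.
#' @export
desk_encoder_config <- function(embed_dim = 32L) {
  encoder_config(stage_channels = c(16L),
                 conv_strides = c(2L),
                 pool_sizes = list(2L),
                 target_instance_grid = c(2L, 2L, 2L),
                 embed_dim = embed_dim,
                 input_shape = c(48L, 48L, 32L))
}

#' Predicted feature-grid geometry for an input shape
#'
#' @param config an `encoder_config`.
#' @param input_shape integer triple.
#' @return list with `stage_dims` (spatial dims after every stage),
#'   `pre_adaptive` (dims entering the adaptive pool) and `instance_grid`.
#' @export
encoder_grid_shape <- function(config, input_shape = config$input_shape) {
  dims <- as.integer(input_shape)
  stage_dims <- list()
  for (s in seq_along(config$stage_channels)) {
    dims <- vapply(dims, conv_out_dim, 1L, stride = config$conv_strides[s])
    dims <- dims %/% config$pool_sizes[[s]]
    assert_that(all(dims >= 1L), "a stage reduced the grid to nothing")
    stage_dims[[s]] <- dims
  }
  list(stage_dims = stage_dims, pre_adaptive = dims,
       instance_grid = config$target_instance_grid)
}

#' Build (initialize) an instance encoder
#'
#' He-initialized convolution and projection weights; identical seeds give
#' identical parameters.
#'
#' @param config an `encoder_config`.
#' @param seed integer seed for the initialization.
#' @return list with `params` (trainable), `state` (batch-norm running
#'   statistics) and the config.
#' @export
build_encoder <- function(config, seed = 1L) {
  with_seed(seed, {
    params <- list(stages = list(), proj = NULL)
    cin <- config$in_channels
    for (s in seq_along(config$stage_channels)) {
      cout <- config$stage_channels[s]
      fan_in <- 27L * cin
      params$stages[[s]] <- list(W = he_init(fan_in, cout, fan_in),
                                 b = rep(0, cout),
                                 gamma = rep(1, cout), beta = rep(0, cout))
      cin <- cout
    }
    params$proj <- list(W = he_init(cin, config$embed_dim, cin),
                        b = rep(0, config$embed_dim))
    state <- lapply(config$stage_channels, new_bn_state)
    list(params = params, state = state, config = config)
  })
}

# Forward pass through the encoder. Returns the (H*, W*, S*, D) feature
# grid plus caches for backprop / Grad-CAM and updated BN state.
encoder_forward <- function(params, state, x, config, training = FALSE) {
  caches <- list()
  for (s in seq_along(config$stage_channels)) {
    st <- params$stages[[s]]
    x_in <- x
    conv <- conv3d_forward(x, st$W, st$b, config$conv_strides[s],
                           keep_col = training)
    bnst <- state[[s]]
    bnst$gamma <- st$gamma; bnst$beta <- st$beta
    bn <- batchnorm_forward(conv$out, bnst, training)
    state[[s]]$running_mean <- bn$bn$running_mean
    state[[s]]$running_var <- bn$bn$running_var
    act <- pmax(bn$out, 0)
    pool <- maxpool3d_forward(act, config$pool_sizes[[s]])
    drop <- dropout_forward(pool$out, config$dropout_rate, training)
    caches[[s]] <- list(x_in = x_in, col = conv$col, bn = bn, act = act,
                        pool = pool, drop = drop)
    x <- drop$out
  }
  d <- dim(x)
  nvox <- prod(d[1:3])
  feat_m <- matrix(x, nvox, d[4])
  proj_m <- sweep(feat_m %*% params$proj$W, 2L, params$proj$b, "+")
  proj <- array(proj_m, c(d[1:3], config$embed_dim))
  ad <- adaptive_maxpool_forward(proj, config$target_instance_grid)
  list(grid = ad$out, state = state,
       cache = list(stages = caches, pre_proj = x, proj_in = feat_m,
                    adaptive = ad, pre_dims = d))
}

# Backward pass; dgrid has the feature-grid shape. Returns parameter
# gradients and (optionally) the gradient at each stage's post-ReLU
# activation map (used by Grad-CAM).
encoder_backward <- function(params, cache, dgrid, config,
                             want_stage_grads = FALSE) {
  dproj <- adaptive_maxpool_backward(cache$adaptive, dgrid)
  d <- cache$pre_dims
  nvox <- prod(d[1:3])
  dproj_m <- matrix(dproj, nvox, config$embed_dim)
  gproj <- list(W = crossprod(cache$proj_in, dproj_m),
                b = colSums(dproj_m))
  dx <- array(dproj_m %*% t(params$proj$W), d)
  gstages <- vector("list", length(config$stage_channels))
  stage_grads <- if (want_stage_grads)
    vector("list", length(config$stage_channels)) else NULL
  for (s in rev(seq_along(config$stage_channels))) {
    cs <- cache$stages[[s]]
    dx <- dropout_backward(cs$drop, dx)
    dx <- maxpool3d_backward(cs$pool, dx)
    if (want_stage_grads) stage_grads[[s]] <- dx
    dx <- dx * (cs$act > 0)
    bnb <- batchnorm_backward(cs$bn, params$stages[[s]]$gamma, dx)
    cb <- conv3d_backward(cs$x_in, params$stages[[s]]$W,
                          config$conv_strides[s], bnb$dx, col = cs$col,
                          need_dx = s > 1L)
    gstages[[s]] <- list(W = cb$dW, b = cb$db, gamma = bnb$dgamma,
                        beta = bnb$dbeta)
    dx <- cb$dx
  }
  list(grads = list(stages = gstages, proj = gproj), dinput = dx,
       stage_grads = stage_grads)
}

# Normalized instance-center coordinates for the target grid, ordered
# x-fastest to match the flattened feature grid.
instance_coords <- function(input_shape, target_grid) {
  bx <- cell_bounds(input_shape[1], target_grid[1])
  by <- cell_bounds(input_shape[2], target_grid[2])
  bz <- cell_bounds(input_shape[3], target_grid[3])
  ctr <- function(b, n) ((b[, 1] - 1) + b[, 2]) / 2 / n
  g <- expand.grid(x = ctr(bx, input_shape[1]), y = ctr(by, input_shape[2]),
                   z = ctr(bz, input_shape[3]))
  as.matrix(g)
}

#' Extract an instance bag from a volume
#'
#' Runs the encoder in evaluation mode and flattens the feature grid to N
#' instances with normalized spatial coordinates.
#'
#' @param encoder a built encoder (from [build_encoder()]).
#' @param volume a standardized `multimodal_volume` whose shape matches the
#'   encoder's `input_shape`.
#' @return object of class `instance_bag`: `features` (N x D), `coords`
#'   (N x 3 in [0,1]^3), `subject_id`.
#' @export
extract_features <- function(encoder, volume) {
  x <- volume_to_array(volume)
  cfg <- encoder$config
  assert_that(identical(dim(x)[1:3], as.integer(cfg$input_shape)),
              sprintf("volume shape %s does not match encoder input %s",
                      paste(dim(x)[1:3], collapse = "x"),
                      paste(cfg$input_shape, collapse = "x")))
  fw <- encoder_forward(encoder$params, encoder$state, x, cfg,
                        training = FALSE)
  grid_to_bag(fw$grid, cfg, volume$subject_id)
}

grid_to_bag <- function(grid, config, subject_id = NA_character_,
                        bag_label = NA_integer_) {
  t <- config$target_instance_grid
  n <- prod(t)
  features <- matrix(grid, n, config$embed_dim)
  structure(list(features = features,
                 coords = instance_coords(config$input_shape, t),
                 bag_label = bag_label, subject_id = subject_id),
            class = "instance_bag")
}

#' @export
print.instance_bag <- function(x, ...) {
  cat(sprintf("instance_bag %s: %d instances x %d features\n",
              x$subject_id, nrow(x$features), ncol(x$features)))
  invisible(x)
}
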