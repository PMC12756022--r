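# Full model assembly: encoder -> positional encoding -> fusion ->
# (optional) importance weighting -> MIL pooling -> classification head.
# One volume per forward pass; all gradients are hand-derived and verified
# by finite differences in the tests.

#' Model configuration
#'
#' @param encoder an [encoder_config()].
#' @param pos_encoding positional encoding kind: "none", "spe"
#'   (fixed sinusoidal), "npe" (learnable GELU network) or "cle" (npe plus
#'   the softmax importance weighting).
#' @param pooling MIL pooling kind: "max", "mean", "attention" or "dga".
#' @param d_pos positional encoding width for npe/cle (default 16).
#' @param pos_hidden hidden width of the positional network (default 32).
#' @param n_freq sinusoidal frequencies for spe (d_pos becomes 6 * n_freq).
#' @param att_hidden hidden width of the Tanh attention branch (default 32).
#' @param lsvd_rank rank r of the LSVD gate (default 4; must be <= the
#'   instance count N and the fused feature dimension).
#' @param att_dropout dropout rate in the Tanh branch (default 0.25).
#' @return object of class `habmil_config`.
#' @export
model_config <- function(encoder = desk_encoder_config(),
                         pos_encoding = c("cle", "npe", "spe", "none"),
                         pooling = c("dga", "attention", "mean", "max"),
                         d_pos = 16L, pos_hidden = 32L, n_freq = 3L,
                         att_hidden = 32L, lsvd_rank = 4L,
                         att_dropout = 0.25) {
  pos_encoding <- match.arg(pos_encoding)
  pooling <- match.arg(pooling)
  n_inst <- prod(encoder$target_instance_grid)
  d_enc <- if (pos_encoding == "none") 0L
           else if (pos_encoding == "spe") 6L * as.integer(n_freq)
           else as.integer(d_pos)
  d_fused <- encoder$embed_dim + d_enc
  assert_that(lsvd_rank <= min(n_inst, d_fused),
              sprintf("lsvd_rank %d exceeds min(N = %d, d = %d)",
                      lsvd_rank, n_inst, d_fused))
  structure(list(encoder = encoder, pos_encoding = pos_encoding,
                 pooling = pooling, d_pos = as.integer(d_pos),
                 pos_hidden = as.integer(pos_hidden),
                 n_freq = as.integer(n_freq),
                 att_hidden = as.integer(att_hidden),
                 lsvd_rank = as.integer(lsvd_rank),
                 att_dropout = att_dropout, d_fused = as.integer(d_fused),
                 d_enc = as.integer(d_enc)),
            class = "habmil_config")
}

#' Initialize a model
#'
#' @param config a [model_config()].
#' @param seed integer seed; identical seeds give identical parameters.
#' @return list with `params`, `state` (BN running statistics) and
#'   `config`, class `habmil_model`.
#' @export
model_init <- function(config, seed = 1L) {
  enc <- build_encoder(config$encoder, seed = derive_seed(seed, "encoder"))
  d_fused <- config$d_fused
  params <- list(
    encoder = enc$params,
    pos = posnet_init(max(config$d_pos, 1L), config$pos_hidden,
                      seed = derive_seed(seed, "pos")),
    imp = with_seed(derive_seed(seed, "imp"),
                    list(w = stats::rnorm(d_fused, sd = 1 / sqrt(d_fused)),
                         b = 0)),
    pool = pool_init(d_fused, config$att_hidden, config$lsvd_rank,
                     config$att_dropout, seed = derive_seed(seed, "pool")),
    head = with_seed(derive_seed(seed, "head"),
                     list(w = stats::rnorm(d_fused, sd = 1 / sqrt(d_fused)),
                          b = 0)))
  params$pool$dropout_rate <- NULL   # hyperparameter, not a trainable leaf
  structure(list(params = params, state = enc$state, config = config),
            class = "habmil_model")
}

# Forward pass on one stacked (nx, ny, nz, 3) array.
model_forward <- function(model, x, training = FALSE) {
  cfg <- model$config
  ec <- cfg$encoder
  enc <- encoder_forward(model$params$encoder, model$state, x, ec, training)
  n <- prod(ec$target_instance_grid)
  F <- matrix(enc$grid, n, ec$embed_dim)
  coords <- instance_coords(dim(x)[1:3], ec$target_instance_grid)
  pos_cache <- NULL; fuse_cache <- NULL; imp_cache <- NULL
  if (cfg$pos_encoding == "none") {
    H <- F
  } else {
    E <- switch(cfg$pos_encoding,
      spe = sinusoidal_encoding(coords, cfg$n_freq),
      {
        pos_cache <- encode_positions_cache(coords, model$params$pos)
        pos_cache$out
      })
    fuse_cache <- fuse_forward(F, E)
    H <- fuse_cache$out
    if (cfg$pos_encoding == "cle") {
      imp_cache <- importance_forward(H, model$params$imp$w,
                                      model$params$imp$b)
      H <- imp_cache$out
    }
  }
  pool_params <- c(model$params$pool, list(dropout_rate = cfg$att_dropout))
  pl <- pool_forward(H, pool_params, cfg$pooling, training)
  pred <- bag_classify(pl$z, model$params$head)
  list(prob = pred$probability, logit = pred$logit, z = pl$z,
       record = pl$record, weights = pl$weights, features = F,
       coords = coords, state = enc$state,
       cache = list(enc = enc$cache, F = F, pos = pos_cache,
                    fuse = fuse_cache, imp = imp_cache, pool = pl$cache,
                    x_dim = dim(x)))
}

# Backward pass from dL/dlogit; returns gradients with the same structure
# as model$params (zeros for branches the configuration does not use).
model_backward <- function(model, fw, dlogit, want_stage_grads = FALSE) {
  cfg <- model$config
  ec <- cfg$encoder
  cache <- fw$cache
  grads <- param_zeros_like(model$params)
  grads$head$w <- dlogit * fw$z
  grads$head$b <- dlogit
  dz <- dlogit * model$params$head$w
  pool_params <- c(model$params$pool, list(dropout_rate = cfg$att_dropout))
  pb <- pool_backward(cache$pool, pool_params, dz)
  dH <- pb$dH
  if (!is.null(pb$grads)) {
    grads$pool$tanh <- pb$grads$tanh
    grads$pool$lsvd <- pb$grads$lsvd
    grads$pool$linear <- pb$grads$linear
  }
  if (cfg$pos_encoding == "none") {
    dF <- dH
  } else {
    if (cfg$pos_encoding == "cle") {
      ib <- importance_backward(cache$imp, dH)
      dH <- ib$dH
      grads$imp$w <- ib$dw
      grads$imp$b <- ib$db
    }
    fb <- fuse_backward(cache$fuse, dH)
    dF <- fb$dfeatures
    if (cfg$pos_encoding %in% c("npe", "cle")) {
      posb <- encode_positions_backward(cache$pos, model$params$pos,
                                        fb$dencoding)
      grads$pos <- posb$grads
    }
  }
  dgrid <- array(dF, c(ec$target_instance_grid, ec$embed_dim))
  eb <- encoder_backward(model$params$encoder, cache$enc, dgrid, ec,
                         want_stage_grads = want_stage_grads)
  grads$encoder <- eb$grads
  list(grads = grads, stage_grads = eb$stage_grads)
}

#' Predict the bag probability for one volume
#'
#' @param model a `habmil_model`.
#' @param volume a standardized `multimodal_volume`.
#' @return a `bag_prediction` with the attention record attached.
#' @export
model_predict_volume <- function(model, volume) {
  fw <- model_forward(model, volume_to_array(volume), training = FALSE)
  structure(list(probability = fw$prob, logit = fw$logit,
                 predicted_label = as.integer(fw$prob >= 0.5),
                 threshold = 0.5, attention = fw$record,
                 weights = fw$weights, subject_id = volume$subject_id),
            class = "bag_prediction")
}
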