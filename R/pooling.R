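# MIL pooling: bag semantics, the Dynamic Gated Attention (DGA) pooling and
# the max / mean / plain-attention baselines.
#
# DGA combines two per-instance signals: a Tanh attention branch (signed
# activations in (-1,1), with dropout against overfitting) and a sigmoid
# "switch" gate obtained by reducing the LSVD low-rank affinity
# reconstruction to one scalar per instance (row mean). Their elementwise
# product passes through a scalar affine map and a softmax over instances,
# and the bag embedding is the attention-weighted sum of instance vectors.

#' Bag label from instance labels
#'
#' The defining MIL rule: a bag is positive iff at least one instance is
#' positive.
#'
#' @param instance_labels nonempty vector of 0/1 labels.
#' @return 0 or 1.
#' @export
bag_label_rule <- function(instance_labels) {
  assert_that(length(instance_labels) >= 1L, "empty instance label list")
  assert_that(all(instance_labels %in% 0:1), "instance labels must be 0/1")
  as.integer(sum(instance_labels) > 0)
}

#' Initialize MIL pooling parameters
#'
#' @param d instance feature dimension entering the pooling.
#' @param hidden hidden width of the Tanh attention branch (default 32).
#' @param r LSVD rank (default 4).
#' @param dropout_rate dropout in the Tanh branch (default 0.25).
#' @param seed integer seed.
#' @return parameter list (`tanh` branch, `lsvd`, scalar `linear`).
#' @export
pool_init <- function(d, hidden = 32L, r = 4L, dropout_rate = 0.25,
                      seed = 1L) {
  with_seed(seed, {
    tanh_p <- list(W1 = he_init(d, hidden, d), b1 = rep(0, hidden),
                   w2 = stats::rnorm(hidden, sd = sqrt(2 / hidden)),
                   b2 = 0)
    lsvd_p <- lsvd_init(d, r, seed = derive_seed(seed, "lsvd"))
    list(tanh = tanh_p, lsvd = lsvd_p,
         linear = list(scale = 1, bias = 0),
         dropout_rate = dropout_rate)
  })
}

# ---- Tanh attention branch -------------------------------------------------

tanh_branch_forward <- function(H, params, dropout_rate = 0,
                                training = FALSE) {
  z1 <- sweep(H %*% params$W1, 2L, params$b1, "+")
  t1 <- tanh(z1)
  dp <- dropout_forward(t1, dropout_rate, training)
  s2 <- drop(dp$out %*% params$w2) + params$b2
  a <- tanh(s2)
  list(a = a, z1 = z1, t1 = t1, dp = dp, s2 = s2, H = H)
}

tanh_branch_backward <- function(cache, params, da) {
  ds2 <- da * (1 - cache$a^2)
  dw2 <- drop(crossprod(cache$dp$out, ds2))
  db2 <- sum(ds2)
  ddp <- outer(ds2, params$w2)
  dt1 <- dropout_backward(cache$dp, ddp)
  dz1 <- dt1 * (1 - cache$t1^2)
  list(grads = list(W1 = crossprod(cache$H, dz1), b1 = colSums(dz1),
                    w2 = dw2, b2 = db2),
       dH = dz1 %*% t(params$W1))
}

#' Tanh attention branch scores
#'
#' Per-instance signed attention score: affine -> tanh -> dropout ->
#' affine-to-scalar -> tanh, so scores stay in (-1, 1) and carry both
#' positive and negative activation signals.
#'
#' @param instances N x D matrix.
#' @param params `tanh` component of [pool_init()] parameters.
#' @param dropout_rate dropout probability (active only when `training`).
#' @param training logical.
#' @return length-N score vector in (-1, 1).
#' @export
tanh_branch <- function(instances, params, dropout_rate = 0,
                        training = FALSE) {
  assert_that(all(is.finite(instances)), "instances must be finite")
  tanh_branch_forward(as.matrix(instances), params, dropout_rate,
                      training)$a
}

# ---- LSVD sigmoid gate -----------------------------------------------------

lsvd_gate_forward <- function(H, lsvd_params) {
  fw <- lsvd_forward(H, lsvd_params)
  g_raw <- rowMeans(fw$Ahat)
  g <- sigmoid(g_raw)
  list(g = g, g_raw = g_raw, lsvd = fw)
}

lsvd_gate_backward <- function(cache, lsvd_params, dg) {
  n <- length(cache$g)
  dg_raw <- dg * cache$g * (1 - cache$g)
  dAhat <- outer(dg_raw, rep(1 / n, n))
  bw <- lsvd_backward(cache$lsvd, lsvd_params, dAhat)
  list(grads = list(Wa = bw$dWa, ba = bw$dba, sigma = bw$dsigma),
       dH = bw$dX)
}

#' LSVD sigmoid gate
#'
#' Row means of the LSVD reconstruction (an instance's learned affinity
#' mass) passed through a sigmoid: a per-instance switch in (0, 1).
#'
#' @param instances N x D matrix.
#' @param lsvd_params parameters from [lsvd_init()].
#' @return length-N gate vector in (0, 1).
#' @export
lsvd_gate <- function(instances, lsvd_params) {
  assert_that(all(is.finite(instances)), "instances must be finite")
  lsvd_gate_forward(as.matrix(instances), lsvd_params)$g
}

# ---- poolings --------------------------------------------------------------

pool_forward <- function(H, params, kind = c("dga", "attention", "mean",
                                             "max"), training = FALSE,
                         clamp_gate = FALSE) {
  kind <- match.arg(kind)
  n <- nrow(H)
  assert_that(n >= 1L, "empty bag")
  if (kind == "mean") {
    a <- rep(1 / n, n)
    return(list(z = colMeans(H), weights = a, record = NULL,
                cache = list(kind = kind, H = H)))
  }
  if (kind == "max") {
    amax <- max.col(t(H), ties.method = "first")
    z <- H[cbind(amax, seq_len(ncol(H)))]
    w <- tabulate(amax, nbins = n) / ncol(H)
    return(list(z = z, weights = w, record = NULL,
                cache = list(kind = kind, H = H, amax = amax)))
  }
  tb <- tanh_branch_forward(H, params$tanh, params$dropout_rate, training)
  if (kind == "attention") {
    u <- tb$a
    gate <- NULL
  } else {
    gate <- lsvd_gate_forward(H, params$lsvd)
    if (clamp_gate) gate$g <- rep(1, n)   # degenerate "switch open" case
    u <- gate$g * tb$a
  }
  sc <- params$linear$scale * u + params$linear$bias
  a_final <- softmax_vec(sc)
  z <- drop(crossprod(H, a_final))
  record <- list(a_tanh = tb$a,
                 a_lsvd = if (is.null(gate)) rep(1, n) else gate$g,
                 a_final = a_final)
  list(z = z, weights = a_final, record = record,
       cache = list(kind = kind, H = H, tb = tb, gate = gate, u = u,
                    a_final = a_final))
}

pool_backward <- function(cache, params, dz) {
  H <- cache$H
  n <- nrow(H)
  kind <- cache$kind
  if (kind == "mean") {
    return(list(dH = matrix(dz, n, ncol(H), byrow = TRUE) / n, grads = NULL))
  }
  if (kind == "max") {
    dH <- matrix(0, n, ncol(H))
    dH[cbind(cache$amax, seq_len(ncol(H)))] <- dz
    return(list(dH = dH, grads = NULL))
  }
  a <- cache$a_final
  dH <- outer(a, dz)
  da <- drop(H %*% dz)
  dsc <- a * (da - sum(da * a))
  dscale <- sum(dsc * cache$u)
  dbias <- sum(dsc)
  du <- dsc * params$linear$scale
  if (kind == "attention") {
    da_tanh <- du
    gate_grads <- list(Wa = params$lsvd$Wa * 0, ba = params$lsvd$ba * 0,
                       sigma = params$lsvd$sigma * 0)
  } else {
    da_tanh <- du * cache$gate$g
    dg <- du * cache$tb$a
    gb <- lsvd_gate_backward(cache$gate, params$lsvd, dg)
    gate_grads <- gb$grads
    dH <- dH + gb$dH
  }
  tbb <- tanh_branch_backward(cache$tb, params$tanh, da_tanh)
  dH <- dH + tbb$dH
  list(dH = dH,
       grads = list(tanh = tbb$grads, lsvd = gate_grads,
                    linear = list(scale = dscale, bias = dbias)))
}

#' Dynamic Gated Attention pooling
#'
#' @param instances N x D matrix (N >= 1).
#' @param params parameters from [pool_init()].
#' @param training logical (activates the Tanh-branch dropout).
#' @param clamp_gate force the LSVD gate to 1, reducing DGA exactly to the
#'   plain attention baseline (the degenerate "switch fully open" case).
#' @return list with `z` (pooled bag embedding) and `attention`, an
#'   attention record with `a_tanh` (Tanh branch, in (-1,1)), `a_lsvd`
#'   (sigmoid gate, in (0,1)) and `a_final` (softmax weights summing
#'   to 1).
#' @export
dga_pool <- function(instances, params, training = FALSE,
                     clamp_gate = FALSE) {
  r <- pool_forward(as.matrix(instances), params, "dga", training,
                    clamp_gate = clamp_gate)
  list(z = r$z, attention = r$record)
}

#' Baseline MIL poolings
#'
#' `max` is the coordinatewise maximum (weights report how often each
#' instance is the argmax across coordinates), `mean` uses uniform weights
#' 1/N, and `attention` is the plain attention pooling: the Tanh branch
#' alone, through the scalar affine map and softmax (exactly DGA with the
#' gate clamped to 1).
#'
#' @param instances N x D matrix.
#' @param kind one of "max", "mean", "attention".
#' @param params pooling parameters (needed for "attention").
#' @return list with `z` and `weights`.
#' @export
baseline_pool <- function(instances, kind = c("max", "mean", "attention"),
                          params = NULL) {
  kind <- match.arg(kind)
  if (kind == "attention") {
    assert_that(!is.null(params), "attention baseline needs parameters")
  }
  r <- pool_forward(as.matrix(instances), params, kind, training = FALSE)
  list(z = r$z, weights = r$weights)
}

#' Classify a pooled bag embedding
#'
#' @param z bag embedding vector.
#' @param head_params list with `w` (length matching z) and scalar `b`.
#' @param threshold decision threshold (default 0.5, never tuned on test
#'   data).
#' @return object of class `bag_prediction`: `probability`,
#'   `predicted_label`.
#' @export
bag_classify <- function(z, head_params, threshold = 0.5) {
  assert_that(all(is.finite(z)), "bag embedding must be finite")
  logit <- sum(z * head_params$w) + head_params$b
  p <- sigmoid(logit)
  structure(list(probability = p, logit = logit,
                 predicted_label = as.integer(p >= threshold),
                 threshold = threshold),
            class = "bag_prediction")
}

#' @export
print.bag_prediction <- function(x, ...) {
  cat(sprintf("bag_prediction: p = %.4f -> label %d (threshold %.2f)\n",
              x$probability, x$predicted_label, x$threshold))
  invisible(x)
}
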