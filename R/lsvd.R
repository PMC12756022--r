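# Learnable Singular Value Decomposition (LSVD).
#
# A low-rank reconstruction Ahat = alpha_U diag(sigma) alpha_V^T in which
# both factor matrices are rowwise-softmax projections of the input through
# one shared affine map (alpha_U = alpha_V = softmax(X Wa + ba)) and sigma
# is a trainable diagonal. The construction is SVD-shaped — two factors
# around a diagonal — but softmax rows cannot be orthonormal, so the exact
# SVD serves only as motivation (and, through the Eckart–Young bound, as a
# test oracle); the layer itself is the learnable analogue.

#' Initialize LSVD parameters
#'
#' @param d input feature dimension.
#' @param r rank (number of latent components, default 4).
#' @param seed integer seed.
#' @param sigma_init initial value for every diagonal entry (default 1:
#'   identity-like scaling).
#' @return list with `Wa` (d x r), `ba` (length r), `sigma` (length r).
#' @export
lsvd_init <- function(d, r = 4L, seed = 1L, sigma_init = 1) {
  assert_that(is_count(r) && r >= 1L, "rank r must be >= 1")
  with_seed(seed, list(Wa = he_init(d, r, d), ba = rep(0, r),
                       sigma = rep(sigma_init, r)))
}

#' Project a bag onto softmax-constrained LSVD factors
#'
#' @param X N x d instance matrix.
#' @param params parameters from [lsvd_init()].
#' @return object of class `lsvd_factors`: `alpha_U`, `alpha_V` (N x r,
#'   rows summing to 1; identical because the projection is shared),
#'   `sigma` (length r).
#' @export
lsvd_project <- function(X, params) {
  X <- as.matrix(X)
  assert_that(all(is.finite(X)), "X must be finite")
  r <- length(params$sigma)
  assert_that(r <= min(nrow(X), ncol(X)),
              sprintf("rank r = %d exceeds min(N, d) = %d", r,
                      min(nrow(X), ncol(X))))
  s <- sweep(X %*% params$Wa, 2L, params$ba, "+")
  alpha <- softmax_rows(s)
  structure(list(alpha_U = alpha, alpha_V = alpha, sigma = params$sigma),
            class = "lsvd_factors")
}

#' Reconstruct the low-rank instance affinity matrix
#'
#' @param factors an `lsvd_factors` object.
#' @return N x N matrix `alpha_U diag(sigma) alpha_V^T` of rank <= r.
#' @export
lsvd_reconstruct <- function(factors) {
  assert_that(inherits(factors, "lsvd_factors"), "need lsvd_factors")
  factors$alpha_U %*% (factors$sigma * t(factors$alpha_V))
}

# Forward with cache: alpha (N x r), Ahat (N x N).
lsvd_forward <- function(X, params) {
  s <- sweep(X %*% params$Wa, 2L, params$ba, "+")
  alpha <- softmax_rows(s)
  Ahat <- alpha %*% (params$sigma * t(alpha))
  list(Ahat = Ahat, alpha = alpha, X = X)
}

# Backward from dL/dAhat: gradients for Wa, ba, sigma and the input X.
lsvd_backward <- function(cache, params, dAhat) {
  alpha <- cache$alpha
  G <- dAhat
  dsigma <- diag(crossprod(alpha, G %*% alpha))
  dalpha <- (G + t(G)) %*% sweep(alpha, 2L, params$sigma, "*")
  # rowwise softmax backward
  ds <- alpha * (dalpha - rowSums(dalpha * alpha))
  list(dWa = crossprod(cache$X, ds), dba = colSums(ds),
       dsigma = dsigma, dX = ds %*% t(params$Wa))
}

#' Fit the LSVD layer to reconstruct a fixed matrix
#'
#' A test harness for the layer: gradient-trains (Wa, ba, sigma) with Adam
#' so that the reconstruction from X = target approximates the target in
#' Frobenius norm. The rank-r truncated exact SVD (Eckart–Young) is the
#' unbeatable lower bound on the achievable error.
#'
#' @param target square numeric matrix (N x N).
#' @param r rank.
#' @param steps gradient steps (default 2000).
#' @param lr Adam learning rate (default 0.05).
#' @param seed integer seed for the initialization.
#' @param restarts independent initializations; the best final fit is
#'   returned (the loss surface is nonconvex, so restarts guard against
#'   poor local optima).
#' @return list with `factors`, `final_error` (Frobenius), `svd_optimum`
#'   (the truncated-SVD Frobenius error) and the loss trace.
#' @export
fit_to_matrix <- function(target, r = 4L, steps = 2000L, lr = 0.05,
                          seed = 1L, restarts = 1L) {
  target <- as.matrix(target)
  assert_that(all(is.finite(target)), "target must be finite")
  n <- nrow(target)
  assert_that(ncol(target) == n, "target must be square")
  if (restarts > 1L) {
    runs <- lapply(seq_len(restarts), function(i)
      fit_to_matrix(target, r, steps, lr,
                    seed = derive_seed(seed, "restart", i), restarts = 1L))
    best <- which.min(vapply(runs, function(x) x$final_error, numeric(1)))
    return(runs[[best]])
  }
  params <- lsvd_init(n, r, seed = seed)
  opt <- adam_init(params, lr = lr, weight_decay = 0)
  trace <- numeric(steps)
  for (step in seq_len(steps)) {
    fw <- lsvd_forward(target, params)
    resid <- fw$Ahat - target
    loss <- sum(resid^2)
    if (!is.finite(loss)) stop("fit_to_matrix diverged (non-finite loss)")
    trace[step] <- loss
    bw <- lsvd_backward(fw, params, 2 * resid)
    st <- adam_step(opt, params,
                    list(Wa = bw$dWa, ba = bw$dba, sigma = bw$dsigma))
    opt <- st$opt; params <- st$params
  }
  fw <- lsvd_forward(target, params)
  final_error <- sqrt(sum((fw$Ahat - target)^2))
  sv <- svd(target)
  k <- min(r, length(sv$d))
  svd_opt <- sqrt(sum(sv$d[-seq_len(k)]^2))
  factors <- structure(list(alpha_U = fw$alpha, alpha_V = fw$alpha,
                            sigma = params$sigma), class = "lsvd_factors")
  list(factors = factors, final_error = final_error,
       svd_optimum = svd_opt, trace = trace, params = params)
}
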