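# Positional encodings: the learnable GELU network, sinusoidal features,
# normalization + concatenation fusion and the importance weighting.

test_that("the GELU positional network matches a scalar-by-scalar oracle", {
  # identity parameters at the origin: GELU(0) = 0
  p_id <- list(a1 = diag(3), b1 = rep(0, 3), a2 = diag(3), b2 = rep(0, 3))
  out0 <- encode_positions(matrix(0, 1, 3), p_id)
  expect_equal(as.vector(out0), rep(0, 3), tolerance = 1e-12)

  # equal coordinate rows give equal encoding rows
  set.seed(1)
  params <- posnet_init(d_pos = 4L, hidden = 5L, seed = 2)
  coords <- matrix(runif(9), 3, 3)
  coords[3, ] <- coords[1, ]
  enc <- encode_positions(coords, params)
  expect_equal(enc[1, ], enc[3, ])

  # brute-force elementwise re-evaluation of a2 . GELU(a1 p + b1) + b2
  oracle <- matrix(0, nrow(coords), 4)
  for (i in seq_len(nrow(coords))) {
    h <- numeric(5)
    for (j in 1:5) {
      z <- sum(params$a1[, j] * coords[i, ]) + params$b1[j]
      h[j] <- z * pnorm(z)
    }
    for (k in 1:4) {
      oracle[i, k] <- sum(params$a2[, k] * h) + params$b2[k]
    }
  }
  expect_equal(enc, oracle, tolerance = 1e-12)

  expect_warning(encode_positions(matrix(c(2, 0, 0), 1, 3), params),
                 "extrapolates")
})

test_that("sinusoidal encoding has the stated structure and periodicity", {
  z <- sinusoidal_encoding(matrix(0, 1, 3), n_freq = 3L)
  expect_equal(ncol(z), 3 * 2 * 3)   # 3 axes x (sin, cos) x n_freq
  expect_equal(as.vector(z), rep(c(0, 1), 9), tolerance = 1e-12)
  # integer frequencies: coordinate 0 and 1 encode identically
  a <- sinusoidal_encoding(matrix(0, 1, 3), n_freq = 2L)
  b <- sinusoidal_encoding(matrix(1, 1, 3), n_freq = 2L)
  expect_equal(a, b, tolerance = 1e-9)
  expect_error(sinusoidal_encoding(matrix(0, 1, 3), n_freq = 0L), "n_freq")
})

test_that("fusion standardizes each block per instance and concatenates", {
  set.seed(3)
  F <- matrix(rnorm(8 * 5, mean = 3, sd = 2), 8, 5)
  E <- matrix(rnorm(8 * 4, mean = -1, sd = 10), 8, 4)
  H <- fuse(F, E)
  expect_equal(dim(H), c(8L, 9L))
  # column slices reconstruct the per-row standardized inputs
  std <- function(x) {
    t(apply(x, 1, function(r) {
      (r - mean(r)) / sqrt(mean(r^2) - mean(r)^2 + 1e-5)
    }))
  }
  expect_equal(H[, 1:5], std(F), tolerance = 1e-10)
  expect_equal(H[, 6:9], std(E), tolerance = 1e-10)
  # degenerate concatenation
  expect_equal(fuse(F, NULL), std(F), tolerance = 1e-10)
  expect_error(fuse(F, E[1:3, ]), "instance count")
  # no cross-instance coupling: changing one instance leaves the others
  F2 <- F
  F2[1, ] <- F2[1, ] + 100
  expect_equal(fuse(F2, E)[-1, ], H[-1, ], tolerance = 1e-12)
})

test_that("importance weights softmax over instances and rescale rows", {
  set.seed(4)
  H <- matrix(rnorm(6 * 4), 6, 4)
  w <- rnorm(4)
  r <- importance_weighting(H, w, b = 0.3)
  expect_equal(sum(r$A), 1, tolerance = 1e-12)
  expect_true(all(r$A >= 0 & r$A <= 1))
  # brute-force softmax / product oracle
  s <- as.vector(H %*% w) + 0.3
  A_or <- exp(s) / sum(exp(s))
  O_or <- H * 0
  for (i in 1:6) for (j in 1:4) O_or[i, j] <- H[i, j] * A_or[i]
  expect_equal(r$A, A_or, tolerance = 1e-12)
  expect_equal(r$O, O_or, tolerance = 1e-12)

  # singleton bag: A = 1, O = H
  r1 <- importance_weighting(H[1, , drop = FALSE], w)
  expect_equal(r1$A, 1)
  expect_equal(r1$O, H[1, , drop = FALSE])

  # identical rows: uniform weights
  Hu <- matrix(rep(H[1, ], each = 5), 5, 4)
  ru <- importance_weighting(Hu, w)
  expect_equal(ru$A, rep(1 / 5, 5), tolerance = 1e-12)

  # permutation equivariance
  perm <- c(3, 1, 6, 2, 5, 4)
  rp <- importance_weighting(H[perm, ], w, b = 0.3)
  expect_equal(rp$A, r$A[perm], tolerance = 1e-12)
  expect_equal(rp$O, r$O[perm, ], tolerance = 1e-12)

  expect_error(importance_weighting(H * NA, w), "finite")
})
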