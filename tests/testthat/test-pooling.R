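# MIL pooling: bag semantics, the Tanh branch, the LSVD gate, DGA and the
# baselines; permutation symmetry and the gate degeneracy.

test_that("bag label rule is the logical OR over instances", {
  expect_equal(bag_label_rule(c(0, 0, 0, 0)), 0L)
  expect_equal(bag_label_rule(c(0, 1, 0)), 1L)
  # exhaustive over all 2^4 label vectors
  for (code in 0:15) {
    bits <- as.integer(intToBits(code)[1:4])
    expect_equal(bag_label_rule(bits), as.integer(any(bits == 1)))
  }
  expect_error(bag_label_rule(integer(0)), "empty")
})

test_that("Tanh branch scores match an explicit per-instance oracle", {
  set.seed(1)
  H <- matrix(rnorm(6 * 5), 6, 5)
  params <- pool_init(5, hidden = 4, r = 2, seed = 2)
  a <- tanh_branch(H, params$tanh)
  expect_true(all(a > -1 & a < 1))
  oracle <- numeric(6)
  for (i in 1:6) {
    h <- tanh(as.vector(H[i, ] %*% params$tanh$W1) + params$tanh$b1)
    oracle[i] <- tanh(sum(h * params$tanh$w2) + params$tanh$b2)
  }
  expect_equal(a, oracle, tolerance = 1e-12)

  # zero parameters: all scores equal the (tanh of the) constant bias
  zp <- list(W1 = matrix(0, 5, 4), b1 = rep(0, 4), w2 = rep(0, 4), b2 = 0)
  expect_equal(tanh_branch(H, zp), rep(0, 6))
  zp$b2 <- 0.7
  expect_equal(tanh_branch(H, zp), rep(tanh(0.7), 6))
})

test_that("LSVD gate composes project -> reconstruct -> row mean -> sigmoid", {
  set.seed(3)
  H <- matrix(rnorm(7 * 5), 7, 5)
  lp <- lsvd_init(5, r = 3, seed = 4)
  g <- lsvd_gate(H, lp)
  expect_true(all(g > 0 & g < 1))
  # compositional oracle through the exported pieces
  A <- lsvd_reconstruct(lsvd_project(H, lp))
  expect_equal(g, 1 / (1 + exp(-rowMeans(A))), tolerance = 1e-12)
  # zero diagonal: sigmoid(0) = 1/2 everywhere
  lp0 <- lp
  lp0$sigma <- rep(0, 3)
  expect_equal(lsvd_gate(H, lp0), rep(0.5, 7))
})

test_that("DGA pooling is a normalized, permutation-equivariant weighted sum", {
  set.seed(5)
  H <- matrix(rnorm(8 * 6), 8, 6)
  params <- pool_init(6, hidden = 4, r = 3, seed = 6)
  r <- dga_pool(H, params)
  expect_equal(sum(r$attention$a_final), 1, tolerance = 1e-12)
  expect_true(all(r$attention$a_lsvd > 0 & r$attention$a_lsvd < 1))
  expect_true(all(abs(r$attention$a_tanh) < 1))
  # explicit weighted-sum oracle
  z_or <- rep(0, 6)
  for (i in 1:8) z_or <- z_or + r$attention$a_final[i] * H[i, ]
  expect_equal(r$z, z_or, tolerance = 1e-12)

  # single instance: weight 1, z is that instance
  r1 <- dga_pool(H[1, , drop = FALSE], params)
  expect_equal(r1$attention$a_final, 1)
  expect_equal(r1$z, H[1, ])

  # identical instances: uniform weights, z the common vector
  Hu <- matrix(rep(H[2, ], each = 5), 5, 6)
  ru <- dga_pool(Hu, params)
  expect_equal(ru$attention$a_final, rep(1 / 5, 5), tolerance = 1e-12)
  expect_equal(ru$z, H[2, ], tolerance = 1e-12)

  # permutation: weights equivariant, z invariant
  perm <- sample(8)
  rp <- dga_pool(H[perm, ], params)
  expect_equal(rp$attention$a_final, r$attention$a_final[perm],
               tolerance = 1e-12)
  expect_equal(rp$z, r$z, tolerance = 1e-12)
})

test_that("baseline poolings behave as documented", {
  set.seed(7)
  u <- rnorm(5); v <- rnorm(5)
  m <- baseline_pool(rbind(u, v), "mean")
  expect_equal(m$z, (u + v) / 2)
  expect_equal(m$weights, c(0.5, 0.5))

  dominant <- rbind(u, u + abs(rnorm(5)) + 0.1)
  mx <- baseline_pool(dominant, "max")
  expect_equal(mx$z, dominant[2, ])
  expect_equal(mx$weights, c(0, 1))

  H <- matrix(rnorm(6 * 5), 6, 5)
  params <- pool_init(5, hidden = 4, r = 2, seed = 8)
  at <- baseline_pool(H, "attention", params)
  expect_equal(sum(at$weights), 1, tolerance = 1e-12)
  expect_error(baseline_pool(H, "attention"), "parameters")
})

test_that("clamping the gate to 1 reduces DGA exactly to plain attention", {
  set.seed(9)
  H <- matrix(rnorm(7 * 5), 7, 5)
  params <- pool_init(5, hidden = 4, r = 3, seed = 10)
  dga <- dga_pool(H, params, clamp_gate = TRUE)
  att <- baseline_pool(H, "attention", params)
  expect_equal(dga$z, att$z, tolerance = 1e-12)
  expect_equal(dga$attention$a_final, att$weights, tolerance = 1e-12)
  expect_equal(dga$attention$a_lsvd, rep(1, 7))
})

test_that("bag classification is a monotone sigmoid of the head logit", {
  head <- list(w = rep(0, 4), b = 0)
  p0 <- bag_classify(rnorm(4), head)
  expect_equal(p0$probability, 0.5)
  head2 <- list(w = c(1, 0, 0, 0), b = 0)
  z <- c(0.2, 0, 0, 0)
  p1 <- bag_classify(z, head2)
  p2 <- bag_classify(z * 5, head2)
  expect_gt(p2$probability, p1$probability)
  expect_equal(p1$predicted_label, 1L)   # p >= 0.5 at positive logit
})
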