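# Instance encoder: shape algebra, seeded initialization, determinism,
# coordinate geometry and approximate translation covariance.

test_that("declared instance-grid shape equals the realized output shape", {
  set.seed(1)
  cases <- list(
    list(shape = c(12L, 12L, 10L), cfg = tiny_encoder()),
    list(shape = c(16L, 14L, 12L),
         cfg = encoder_config(stage_channels = c(3L, 4L),
                              conv_strides = c(1L, 1L),
                              pool_sizes = list(2L, 2L), dropout_rate = 0,
                              target_instance_grid = c(3L, 2L, 2L),
                              embed_dim = 5L,
                              input_shape = c(16L, 14L, 12L))),
    list(shape = c(20L, 18L, 10L),
         cfg = encoder_config(stage_channels = c(2L),
                              conv_strides = c(2L),
                              pool_sizes = list(2L), dropout_rate = 0,
                              target_instance_grid = c(2L, 2L, 2L),
                              embed_dim = 4L,
                              input_shape = c(20L, 18L, 10L))))
  for (cs in cases) {
    enc <- build_encoder(cs$cfg, seed = 2)
    x <- array(rnorm(prod(c(cs$shape, 3))), c(cs$shape, 3L))
    fw <- encoder_forward(enc$params, enc$state, x, cs$cfg)
    expect_equal(dim(fw$grid),
                 c(cs$cfg$target_instance_grid, cs$cfg$embed_dim))
  }
})

test_that("configs that undershoot the instance grid are rejected", {
  expect_error(
    encoder_config(stage_channels = c(2L, 2L),
                   conv_strides = c(1L, 1L),
                   pool_sizes = list(4L, 4L),
                   target_instance_grid = c(2L, 2L, 2L),
                   input_shape = c(16L, 16L, 16L)),
    "below")
})

test_that("identical seeds give identical parameters, different seeds differ", {
  cfg <- tiny_encoder()
  a <- build_encoder(cfg, seed = 5)
  b <- build_encoder(cfg, seed = 5)
  c <- build_encoder(cfg, seed = 6)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params, c$params))
})

test_that("extract_features flattens to N instances with cell-center coords", {
  cfg <- tiny_encoder(input_shape = c(12L, 12L, 8L))
  enc <- build_encoder(cfg, seed = 3)
  set.seed(3)
  d <- c(12, 12, 8)
  vol <- multimodal_volume("s", array(rnorm(prod(d)), d),
                           array(rnorm(prod(d)), d),
                           array(rnorm(prod(d)), d))
  bag <- extract_features(enc, vol)
  expect_s3_class(bag, "instance_bag")
  expect_equal(dim(bag$features), c(8L, cfg$embed_dim))
  # divisible grid: coordinates are the eight cell centers {0.25, 0.75}^3
  expect_setequal(round(unique(as.vector(bag$coords)), 6), c(0.25, 0.75))
  # evaluation mode is deterministic
  bag2 <- extract_features(enc, vol)
  expect_identical(bag$features, bag2$features)
  # wrong input shape is rejected
  vol_small <- multimodal_volume("s", array(0, c(8, 8, 8)),
                                 array(0, c(8, 8, 8)),
                                 array(0, c(8, 8, 8)))
  expect_error(extract_features(enc, vol_small), "shape")
})

test_that("translating a lesion by one instance cell moves the hot instance", {
  cfg <- tiny_encoder(input_shape = c(16L, 16L, 16L))
  enc <- build_encoder(cfg, seed = 11)
  mk <- function(cx) {
    spec <- phantom_spec("t", c(16, 16, 16),
                         lesions = list(list(center = c(cx, 4, 4),
                                             radii = c(3, 3, 3),
                                             class = "positive")),
                         noise_sd = 0, seed = 1)
    generate_phantom(spec)$volume
  }
  hot <- function(vol) {
    bag <- extract_features(enc, standardize(vol))
    dev <- sweep(bag$features, 2L, apply(bag$features, 2L, stats::median))
    which.max(rowSums(dev^2))
  }
  h1 <- hot(mk(4))    # lesion in the low-x half
  h2 <- hot(mk(12))   # lesion moved one cell along x
  expect_equal(h2, h1 + 1L)   # x-fastest instance ordering
})
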