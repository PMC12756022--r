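# Phantom generator: bag-label semantics, determinism, octant labeling and
# instance-level ground truth.

test_that("bag label follows the at-least-one-positive-lesion rule", {
  empty <- generate_phantom(phantom_spec("s0", c(12, 12, 10), seed = 1))
  expect_equal(empty$bag_label, 0L)
  expect_true(all(empty$lesion_mask == 0))

  pos <- generate_phantom(phantom_spec(
    "s1", c(12, 12, 10),
    lesions = list(list(center = c(6, 6, 5), radii = c(3, 3, 2),
                        class = "positive")), seed = 1))
  expect_equal(pos$bag_label, 1L)
  expect_gt(sum(pos$lesion_mask), 0)

  # distractor-only subjects are negative and leave the mask empty
  neg <- generate_phantom(phantom_spec(
    "s2", c(12, 12, 10),
    lesions = list(list(center = c(6, 6, 5), radii = c(3, 3, 2),
                        class = "distractor")), seed = 1))
  expect_equal(neg$bag_label, 0L)
  expect_true(all(neg$lesion_mask == 0))
  # ... but the distractor still brightens the T1w channel
  expect_gt(max(neg$volume$t1w), max(empty$volume$t1w))
})

test_that("identical spec and seed give voxelwise-identical phantoms", {
  spec <- phantom_spec("s1", c(12, 12, 10),
                       lesions = list(list(center = c(6, 6, 5),
                                           radii = c(3, 3, 2),
                                           class = "positive")), seed = 7)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$t1w, b$volume$t1w)
  expect_identical(a$volume$flair, b$volume$flair)
  expect_identical(a$lesion_mask, b$lesion_mask)
})

test_that("lesions outside the grid are rejected", {
  expect_error(phantom_spec("bad", c(12, 12, 10),
                            lesions = list(list(center = c(20, 6, 5),
                                                radii = c(2, 2, 2),
                                                class = "positive"))),
               "outside")
  expect_error(phantom_spec("bad", c(4, 4, 4)), ">= 8")
})

test_that("generate_cohort emits the requested counts and reproducible files", {
  d1 <- withr::local_tempdir()
  man <- generate_cohort(0, 5, grid_shape = c(12, 12, 10), seed = 3,
                         out_dir = d1)
  expect_equal(nrow(man), 5L)
  expect_true(all(man$label == 0))
  expect_true(all(file.exists(man$t1w)))

  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  m2 <- generate_cohort(3, 3, grid_shape = c(12, 12, 10), seed = 9,
                        out_dir = d2)
  m3 <- generate_cohort(3, 3, grid_shape = c(12, 12, 10), seed = 9,
                        out_dir = d3)
  expect_identical(m2$label, m3$label)
  for (i in seq_len(nrow(m2))) {
    for (col in c("t1w", "t2w", "flair", "mask")) {
      expect_identical(unname(tools::md5sum(m2[[col]][i])),
                       unname(tools::md5sum(m3[[col]][i])),
                       label = sprintf("%s of %s", col, m2$subject_id[i]))
    }
  }
})

test_that("octant labels match the predicate recomputed from saved masks", {
  d <- withr::local_tempdir()
  man <- generate_cohort(6, 6, grid_shape = c(32, 32, 32),
                         label_rule = "octant", seed = 5, out_dir = d)
  for (i in seq_len(nrow(man))) {
    mask <- as.array(RNifti::readNifti(man$mask[i]))
    idx <- which(mask != 0, arr.ind = TRUE)
    center <- colMeans(idx)
    in_oct <- all(center > dim(mask) / 2)
    expect_equal(man$label[i], as.integer(in_oct),
                 label = man$subject_id[i])
  }
})

test_that("instance ground truth matches an exhaustive voxel scan", {
  # all-zero mask
  expect_equal(instance_ground_truth(array(0, c(8, 8, 8)), c(2, 2, 2)),
               rep(0L, 8))
  # mask filling exactly one octant block
  m <- array(0, c(8, 8, 8))
  m[5:8, 1:4, 1:4] <- 1
  y <- instance_ground_truth(m, c(2, 2, 2))
  expect_equal(y, c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L))
  # random masks vs brute-force per-block scan
  set.seed(10)
  for (rep in 1:5) {
    d <- c(9L, 7L, 6L)
    t <- c(3L, 2L, 2L)
    mask <- array(rbinom(prod(d), 1, 0.05), d)
    y <- instance_ground_truth(mask, t)
    oracle <- integer(prod(t))
    n <- 0L
    bx <- cell_bounds(d[1], t[1]); by <- cell_bounds(d[2], t[2])
    bz <- cell_bounds(d[3], t[3])
    for (kz in seq_len(t[3])) for (ky in seq_len(t[2]))
      for (kx in seq_len(t[1])) {
        n <- n + 1L
        hit <- 0L
        for (x in bx[kx, 1]:bx[kx, 2]) for (yy in by[ky, 1]:by[ky, 2])
          for (z in bz[kz, 1]:bz[kz, 2]) {
            if (mask[x, yy, z] != 0) hit <- 1L
          }
        oracle[n] <- hit
      }
    expect_equal(y, oracle)
  }
})

test_that("bag label equals the OR of instance labels on presence cohorts", {
  d <- withr::local_tempdir()
  man <- generate_cohort(4, 4, grid_shape = c(16, 16, 12), seed = 21,
                         out_dir = d)
  for (i in seq_len(nrow(man))) {
    mask <- as.array(RNifti::readNifti(man$mask[i]))
    y <- instance_ground_truth(mask, c(2, 2, 2))
    expect_equal(man$label[i], bag_label_rule(y), label = man$subject_id[i])
  }
})
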