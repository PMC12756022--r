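# NIfTI I/O, standardization, augmentation and leakage-free splits.

make_vol <- function(seed = 1, d = c(10, 10, 8)) {
  set.seed(seed)
  multimodal_volume("sub-x", array(rnorm(prod(d)), d),
                    array(rnorm(prod(d)), d), array(rnorm(prod(d)), d))
}

test_that("volumes round-trip through NIfTI", {
  d <- withr::local_tempdir()
  v <- make_vol()
  paths <- file.path(d, c("t1w.nii.gz", "t2w.nii.gz", "flair.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(v$t1w), paths[1])
  RNifti::writeNifti(RNifti::asNifti(v$t2w), paths[2])
  RNifti::writeNifti(RNifti::asNifti(v$flair), paths[3])
  row <- data.frame(subject_id = "sub-x", t1w = paths[1], t2w = paths[2],
                    flair = paths[3])
  v2 <- load_volume(row)
  expect_equal(v2$t1w, v$t1w, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(v2$flair, v$flair, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("modality shape mismatches raise an error naming both shapes", {
  expect_error(
    multimodal_volume("sub-y", array(0, c(4, 4, 4)), array(0, c(4, 4, 4)),
                      array(0, c(4, 4, 5))),
    "4x4x4.*4x4x5")
  expect_error(
    multimodal_volume("sub-z", array(NaN, c(4, 4, 4)), array(0, c(4, 4, 4)),
                      array(0, c(4, 4, 4))),
    "non-finite")
})

test_that("standardize hits the target shape and z-scores nonzero support", {
  v <- make_vol(d = c(10, 10, 8))
  s <- standardize(v, c(14, 12, 10))
  expect_equal(dim(s$t1w), c(14L, 12L, 10L))
  for (m in c("t1w", "t2w", "flair")) {
    nz <- s[[m]] != 0
    expect_equal(mean(s[[m]][nz]), 0, tolerance = 1e-8)
    expect_equal(sd(s[[m]][nz]), 1, tolerance = 1e-2)
  }
  # all-zero modality passes through the guard with a warning
  v0 <- v
  v0$t2w <- v0$t2w * 0
  expect_warning(s0 <- standardize(v0, dim(v0$t1w)), "all zero")
  expect_true(all(s0$t2w == 0))
  # identity case: already-target-shaped zeros stay zeros
  z <- multimodal_volume("z", array(0, c(8, 8, 8)), array(0, c(8, 8, 8)),
                         array(0, c(8, 8, 8)))
  suppressWarnings(sz <- standardize(z, c(8, 8, 8)))
  expect_true(all(sz$t1w == 0))
})

test_that("augmentation is identity under an empty policy, involutive flips,
           exact modality dropout, and geometry-consistent across modalities", {
  v <- make_vol()
  expect_identical(augment(v, augment_policy()), v)

  f1 <- flip_axis(v$t1w, 2L)
  expect_identical(flip_axis(f1, 2L), v$t1w)

  set.seed(5)
  vd <- augment(v, augment_policy(modality_dropout = 1))
  zeroed <- vapply(MODALITIES, function(m) all(vd[[m]] == 0), logical(1))
  expect_equal(sum(zeroed), 1L)
  for (m in MODALITIES[!zeroed]) expect_identical(vd[[m]], v[[m]])

  # one geometric transform applied to all three modalities: identical
  # input grids stay identical after flip + affine
  marker <- v
  marker$t2w <- marker$t1w
  marker$flair <- marker$t1w
  set.seed(6)
  va <- augment(marker, augment_policy(flip = 1, affine = 1))
  expect_identical(va$t1w, va$t2w)
  expect_identical(va$t1w, va$flair)
  expect_false(identical(va$t1w, marker$t1w))

  # seeded reproducibility
  set.seed(9)
  a1 <- augment(v, augment_policy(flip = 1, jitter = 1))
  set.seed(9)
  a2 <- augment(v, augment_policy(flip = 1, jitter = 1))
  expect_identical(a1, a2)
})

test_that("splits are subject-level, exhaustive, disjoint and seeded", {
  man <- data.frame(subject_id = sprintf("s%02d", 1:10), label = rep(0:1, 5))
  plan <- make_splits(man, c(0.6, 0.2, 0.2), k_folds = 3L, seed = 4)
  tab <- table(plan$assignment$partition)
  expect_equal(unname(tab[c("train", "val", "test")]), c(6L, 2L, 2L),
               ignore_attr = TRUE)
  expect_setequal(plan$assignment$subject_id, man$subject_id)
  expect_equal(anyDuplicated(plan$assignment$subject_id), 0L)
  expect_true(all(!is.na(plan$assignment$fold[
    plan$assignment$partition == "train"])))

  plan2 <- make_splits(man, c(0.6, 0.2, 0.2), k_folds = 3L, seed = 4)
  expect_identical(plan$assignment, plan2$assignment)
  plan3 <- make_splits(man, c(0.6, 0.2, 0.2), k_folds = 3L, seed = 5)
  expect_false(identical(plan$assignment, plan3$assignment))

  expect_error(make_splits(man[1:4, ], k_folds = 5L), "folds")
})

test_that("split plans serialize to readable text and back", {
  man <- data.frame(subject_id = sprintf("s%02d", 1:10))
  plan <- make_splits(man, seed = 8, k_folds = 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_split_plan(plan, path)
  plan2 <- read_split_plan(path)
  expect_equal(plan$assignment, plan2$assignment)
  expect_equal(plan$seed, plan2$seed)
  expect_equal(plan$k_folds, plan2$k_folds)
})

test_that("subjects with duplicated scans never straddle partitions", {
  # scans-per-subject manifests: the split keys on subject_id, so a
  # subject's scans are constructively inseparable
  set.seed(13)
  for (rep in 1:20) {
    n_sub <- sample(6:15, 1)
    man <- data.frame(subject_id = rep(sprintf("s%02d", seq_len(n_sub)),
                                       times = sample(1:3, n_sub,
                                                      replace = TRUE)))
    plan <- make_splits(man, k_folds = 2L, seed = rep)
    merged <- merge(man, plan$assignment, by = "subject_id")
    per_sub <- tapply(merged$partition, merged$subject_id,
                      function(p) length(unique(p)))
    expect_true(all(per_sub == 1L))
  }
})

test_that("restrict_modalities zeroes exactly the dropped sequences", {
  v <- make_vol()
  r <- restrict_modalities(v, keep = "flair")
  expect_true(all(r$t1w == 0))
  expect_true(all(r$t2w == 0))
  expect_identical(r$flair, v$flair)
})
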