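# NIfTI input/output, preprocessing, augmentation, subject-level splits.
#
# Coordinate convention: volumes are indexed (x, y, z) in NIfTI array order,
# voxel indices 1-based inside R; normalized instance coordinates live in
# [0,1]^3 with 0 at the first-voxel face.

#' Construct a multi-modal volume
#'
#' @param subject_id character scalar.
#' @param t1w,t2w,flair 3-D numeric arrays of identical shape.
#' @param voxel_spacing numeric length-3 voxel size in mm.
#' @return object of class `multimodal_volume`: a list of the three grids
#'   plus metadata.
#' @export
multimodal_volume <- function(subject_id, t1w, t2w, flair,
                              voxel_spacing = c(1, 1, 1)) {
  dims <- list(dim(t1w), dim(t2w), dim(flair))
  assert_that(all(vapply(dims, length, 1L) == 3L),
              "modalities must be 3-D arrays")
  assert_that(identical(dims[[1]], dims[[2]]) &&
                identical(dims[[1]], dims[[3]]),
              sprintf("subject %s: modality shapes differ (%s vs %s vs %s)",
                      subject_id, paste(dims[[1]], collapse = "x"),
                      paste(dims[[2]], collapse = "x"),
                      paste(dims[[3]], collapse = "x")))
  for (g in list(t1w, t2w, flair)) {
    assert_that(all(is.finite(g)),
                sprintf("subject %s: non-finite voxels", subject_id))
  }
  structure(list(subject_id = as.character(subject_id),
                 t1w = t1w * 1.0, t2w = t2w * 1.0, flair = flair * 1.0,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "multimodal_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  cat(sprintf("multimodal_volume %s: %s voxels, spacing %s mm\n",
              x$subject_id, paste(dim(x$t1w), collapse = "x"),
              paste(signif(x$voxel_spacing, 3), collapse = "x")))
  invisible(x)
}

# Stack the three modalities into one (nx, ny, nz, 3) array (channel order
# t1w, t2w, flair).
volume_to_array <- function(volume) {
  d <- dim(volume$t1w)
  out <- array(0, c(d, 3L))
  out[, , , 1] <- volume$t1w; out[, , , 2] <- volume$t2w
  out[, , , 3] <- volume$flair
  out
}

#' Load one subject's volumes from a manifest row
#'
#' @param manifest_row one-row data.frame with columns subject_id, t1w,
#'   t2w, flair (NIfTI paths).
#' @return a `multimodal_volume`.
#' @export
load_volume <- function(manifest_row) {
  row <- as.list(manifest_row)
  for (m in MODALITIES) {
    assert_that(file.exists(row[[m]]),
                sprintf("subject %s: missing file '%s'",
                        row$subject_id, row[[m]]))
  }
  grids <- lapply(MODALITIES, function(m) {
    img <- RNifti::readNifti(row[[m]])
    g <- as.array(img) * 1.0
    assert_that(length(dim(g)) == 3L,
                sprintf("subject %s: %s is not a 3-D volume",
                        row$subject_id, m))
    g
  })
  spacing <- tryCatch(RNifti::pixdim(RNifti::readNifti(row$t1w))[1:3],
                      error = function(e) c(1, 1, 1))
  multimodal_volume(row$subject_id, grids[[1]], grids[[2]], grids[[3]],
                    voxel_spacing = spacing)
}

# Trilinear resampling of one 3-D grid to a target shape (align-corners
# style: voxel centers of the two grids span the same physical extent).
resample_trilinear <- function(grid, target_shape) {
  d <- dim(grid)
  t <- as.integer(target_shape)
  if (identical(d, t)) return(grid)
  src <- function(n_out, n_in) {
    if (n_out == 1L) return(rep((n_in + 1) / 2, 1))
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  cx <- src(t[1], d[1]); cy <- src(t[2], d[2]); cz <- src(t[3], d[3])
  fx <- pmin(floor(cx), d[1] - 1L); wx <- cx - fx
  fy <- pmin(floor(cy), d[2] - 1L); wy <- cy - fy
  fz <- pmin(floor(cz), d[3] - 1L); wz <- cz - fz
  if (d[1] == 1L) { fx <- rep(1, t[1]); wx <- rep(0, t[1]) }
  if (d[2] == 1L) { fy <- rep(1, t[2]); wy <- rep(0, t[2]) }
  if (d[3] == 1L) { fz <- rep(1, t[3]); wz <- rep(0, t[3]) }
  g <- expand.grid(i = seq_len(t[1]), j = seq_len(t[2]), k = seq_len(t[3]))
  acc <- numeric(nrow(g))
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    ix <- pmin(fx[g$i] + ox, d[1]); iy <- pmin(fy[g$j] + oy, d[2])
    iz <- pmin(fz[g$k] + oz, d[3])
    w <- (if (ox == 1) wx[g$i] else 1 - wx[g$i]) *
      (if (oy == 1) wy[g$j] else 1 - wy[g$j]) *
      (if (oz == 1) wz[g$k] else 1 - wz[g$k])
    acc <- acc + w * grid[cbind(ix, iy, iz)]
  }
  array(acc, t)
}

# Nearest-neighbour resampling (for label masks).
resample_nearest <- function(grid, target_shape) {
  d <- dim(grid)
  t <- as.integer(target_shape)
  if (identical(d, t)) return(grid)
  idx <- function(n_out, n_in) {
    pmax(1L, pmin(n_in, as.integer(round(1 + (seq_len(n_out) - 1) *
                                           (n_in - 1) / max(n_out - 1, 1)))))
  }
  grid[idx(t[1], d[1]), idx(t[2], d[2]), idx(t[3], d[3]), drop = FALSE]
}

#' Standardize a volume to a target shape and intensity scale
#'
#' Resamples each modality trilinearly to `target_shape` and z-scores its
#' intensities over the nonzero support (all-zero modalities pass through a
#' unit-denominator guard with a warning).
#'
#' @param volume a `multimodal_volume`.
#' @param target_shape integer triple; default keeps the input shape.
#' @return a standardized `multimodal_volume`.
#' @export
standardize <- function(volume, target_shape = dim(volume$t1w)) {
  assert_that(all(target_shape >= 1), "target_shape must be positive")
  out <- volume
  for (m in MODALITIES) {
    g <- resample_trilinear(volume[[m]], target_shape)
    nz <- g != 0
    if (!any(nz)) {
      warning(sprintf("subject %s: modality %s is all zero; z-score skipped",
                      volume$subject_id, m))
    } else {
      mu <- mean(g[nz])
      sd <- stats::sd(g[nz])
      if (!is.finite(sd) || sd < 1e-12) sd <- 1
      g <- (g - mu) / sd
    }
    out[[m]] <- g
  }
  out
}

#' Augmentation policy
#'
#' @param flip probability of a random axis flip (applied to one random
#'   axis, consistently across modalities).
#' @param affine probability of a small random affine resampling
#'   (scale in `1 +/- affine_mag`, translation up to `affine_mag` of the
#'   grid).
#' @param affine_mag magnitude of the affine perturbation.
#' @param intensity_scale probability of a global intensity scaling.
#' @param jitter probability of brightness/contrast jitter (the grayscale
#'   reading of color jitter).
#' @param modality_dropout probability of zeroing one whole modality.
#' @return list of class `augment_policy`.
#' @export
augment_policy <- function(flip = 0, affine = 0, affine_mag = 0.1,
                           intensity_scale = 0, jitter = 0,
                           modality_dropout = 0) {
  structure(list(flip = flip, affine = affine, affine_mag = affine_mag,
                 intensity_scale = intensity_scale, jitter = jitter,
                 modality_dropout = modality_dropout),
            class = "augment_policy")
}

flip_axis <- function(grid, axis) {
  d <- dim(grid)
  idx <- rep(list(quote(expr = )), 3L)
  idx[[axis]] <- rev(seq_len(d[axis]))
  do.call(`[`, c(list(grid), idx, list(drop = FALSE)))
}

# Affine resample of one grid: scale about the center plus translation,
# trilinear interpolation, constant (edge-clamped) boundary.
affine_resample <- function(grid, scale, shift) {
  d <- dim(grid)
  ctr <- (d + 1) / 2
  ax <- (seq_len(d[1]) - ctr[1]) / scale[1] + ctr[1] + shift[1]
  ay <- (seq_len(d[2]) - ctr[2]) / scale[2] + ctr[2] + shift[2]
  az <- (seq_len(d[3]) - ctr[3]) / scale[3] + ctr[3] + shift[3]
  clamp <- function(v, n) pmax(1, pmin(n, v))
  ax <- clamp(ax, d[1]); ay <- clamp(ay, d[2]); az <- clamp(az, d[3])
  fx <- pmin(floor(ax), d[1] - 1L); wx <- ax - fx
  fy <- pmin(floor(ay), d[2] - 1L); wy <- ay - fy
  fz <- pmin(floor(az), d[3] - 1L); wz <- az - fz
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  acc <- numeric(nrow(g))
  for (ox in 0:1) for (oy in 0:1) for (oz in 0:1) {
    ix <- pmin(fx[g$i] + ox, d[1]); iy <- pmin(fy[g$j] + oy, d[2])
    iz <- pmin(fz[g$k] + oz, d[3])
    w <- (if (ox == 1) wx[g$i] else 1 - wx[g$i]) *
      (if (oy == 1) wy[g$j] else 1 - wy[g$j]) *
      (if (oz == 1) wz[g$k] else 1 - wz[g$k])
    acc <- acc + w * grid[cbind(ix, iy, iz)]
  }
  array(acc, d)
}

#' Apply label-preserving augmentation to a volume
#'
#' Geometric transforms (flip, affine) are drawn once and applied
#' identically to all three modalities; intensity transforms are drawn per
#' modality. With an all-zero policy this is the identity. Deterministic
#' given the RNG state (seed before calling for reproducibility).
#'
#' @param volume a `multimodal_volume`.
#' @param policy an [augment_policy()].
#' @return augmented `multimodal_volume`.
#' @export
augment <- function(volume, policy = augment_policy()) {
  out <- volume
  if (stats::runif(1) < policy$flip) {
    axis <- sample(1:3, 1)
    for (m in MODALITIES) out[[m]] <- flip_axis(out[[m]], axis)
  }
  if (stats::runif(1) < policy$affine) {
    scale <- 1 + stats::runif(3, -policy$affine_mag, policy$affine_mag)
    shift <- stats::runif(3, -policy$affine_mag, policy$affine_mag) *
      dim(out$t1w)
    for (m in MODALITIES) out[[m]] <- affine_resample(out[[m]], scale, shift)
  }
  if (stats::runif(1) < policy$intensity_scale) {
    s <- stats::runif(1, 0.9, 1.1)
    for (m in MODALITIES) out[[m]] <- out[[m]] * s
  }
  if (stats::runif(1) < policy$jitter) {
    for (m in MODALITIES) {
      bright <- stats::rnorm(1, 0, 0.1)
      contrast <- stats::runif(1, 0.9, 1.1)
      mu <- mean(out[[m]])
      out[[m]] <- (out[[m]] - mu) * contrast + mu + bright
    }
  }
  if (stats::runif(1) < policy$modality_dropout) {
    m <- sample(MODALITIES, 1)
    out[[m]] <- out[[m]] * 0
  }
  out
}

#' Zero a subset of modalities
#'
#' Restricting the input to a modality subset is done by setting the other
#' sequences to zero while keeping the three-channel input layout, so one
#' architecture serves all modality-combination experiments.
#'
#' @param volume a `multimodal_volume`.
#' @param keep character vector, subset of `c("t1w","t2w","flair")`.
#' @return `multimodal_volume` with non-kept modalities zeroed.
#' @export
restrict_modalities <- function(volume, keep = MODALITIES) {
  assert_that(all(keep %in% MODALITIES), "unknown modality in subset")
  for (m in setdiff(MODALITIES, keep)) volume[[m]] <- volume[[m]] * 0
  volume
}

#' Build a leakage-free subject-level split plan
#'
#' Subjects (not scans) are partitioned into train/val/test by `ratios`,
#' and the training subjects are further assigned to `k_folds`
#' cross-validation folds. Every scan of a subject follows its subject, so
#' no subject can appear in two partitions.
#'
#' @param manifest cohort manifest data.frame (column subject_id; repeated
#'   rows per subject are allowed and treated as multiple scans).
#' @param ratios numeric length-3 train/val/test fractions summing to 1.
#' @param k_folds folds within the training partition.
#' @param seed integer seed.
#' @return object of class `split_plan`: data.frame (subject_id,
#'   partition, fold) plus the seed.
#' @export
make_splits <- function(manifest, ratios = c(0.6, 0.2, 0.2), k_folds = 5L,
                        seed = 1L) {
  assert_that(abs(sum(ratios) - 1) < 1e-8, "ratios must sum to 1")
  subjects <- unique(manifest$subject_id)
  n <- length(subjects)
  n_train <- round(n * ratios[1])
  n_val <- round(n * ratios[2])
  n_test <- n - n_train - n_val
  assert_that(n_train >= 1 && n_test >= 0 && n_val >= 0,
              "too few subjects for the requested ratios")
  assert_that(n_train >= k_folds,
              sprintf("%d training subjects cannot form %d folds",
                      n_train, k_folds))
  ord <- with_seed(seed, sample(subjects))
  partition <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
  fold <- rep(NA_integer_, n)
  fold[partition == "train"] <- rep_len(seq_len(k_folds), n_train)
  plan <- data.frame(subject_id = ord, partition = partition, fold = fold,
                     stringsAsFactors = FALSE)
  plan <- plan[order(plan$subject_id), ]
  rownames(plan) <- NULL
  structure(list(assignment = plan,
                 seed = as.integer(seed), k_folds = as.integer(k_folds)),
            class = "split_plan")
}

split_subjects <- function(plan, partition) {
  plan$assignment$subject_id[plan$assignment$partition == partition]
}

#' @export
print.split_plan <- function(x, ...) {
  tab <- table(x$assignment$partition)
  cat(sprintf("split_plan (seed %d): %s; %d CV folds in train\n", x$seed,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$k_folds))
  invisible(x)
}

#' Serialize / read a split plan as tab-delimited text
#' @param plan a `split_plan`.
#' @param path output path.
#' @export
write_split_plan <- function(plan, path) {
  header <- sprintf("# split_plan seed=%d k_folds=%d", plan$seed,
                    plan$k_folds)
  writeLines(header, path)
  suppressWarnings(utils::write.table(plan$assignment, path, sep = "\t",
                                      row.names = FALSE, quote = FALSE,
                                      append = TRUE))
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header, gregexpr("[0-9]+", header))[[1]]
  assignment <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                                  stringsAsFactors = FALSE)
  structure(list(assignment = assignment, seed = as.integer(meta[1]),
                 k_folds = as.integer(meta[2])), class = "split_plan")
}
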