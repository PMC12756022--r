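# Synthetic multi-modal phantom cohorts with known lesion masks.
#
# Phantoms emulate the statistical structure of a weakly labeled glioma MRI
# bag: three co-registered modalities over a constant-background volume with
# white Gaussian noise, plus implanted axis-aligned ellipsoidal lesions with
# smooth boundaries. Lesion class drives the bag label: a subject is
# positive iff it carries at least one positive-class lesion — a lesion
# bright in T1w, T2w AND FLAIR at one location (the conjunction a glioma
# presents across sequences). Negative subjects carry the same total
# contrast split over two spatially separated partial lesions (one
# T1w/T2w-bright, one FLAIR-only), so global per-modality statistics do not
# separate the classes and only instance-level co-location carries the
# label. This is what makes attention localization meaningfully testable:
# a pooled-mean shortcut cannot solve the task.

MODALITIES <- c("t1w", "t2w", "flair")

# Default per-modality additive lesion contrasts (arbitrary units on a
# background of base intensity 10, noise sd 0.5). "positive" is the full
# cross-sequence conjunction; "t1t2" and "flair" are its complementary
# partial patterns used as distractors; "distractor" is a generic
# T1w-dominant benign-looking blob for single-lesion scenarios.
LESION_CONTRASTS <- list(
  positive = c(t1w = 1.0, t2w = 2.0, flair = 3.0),
  t1t2 = c(t1w = 1.0, t2w = 2.0, flair = 0.0),
  flair = c(t1w = 0.0, t2w = 0.0, flair = 3.0),
  distractor = c(t1w = 2.5, t2w = 0.8, flair = 0.0))
BACKGROUND_BASE <- 10
DEFAULT_NOISE_SD <- 0.5

#' Specification of one synthetic phantom subject
#'
#' @param subject_id character scalar.
#' @param grid_shape integer triple of voxel counts, all >= 8.
#' @param lesions list of lesions, each a list with `center` (voxel triple,
#'   1-based), `radii` (positive voxel triple) and `class` (a name of
#'   `modality_contrasts`; `"positive"` labels the bag, all other classes
#'   are background-like).
#' @param modality_contrasts named list of numeric length-3 contrast
#'   vectors (additive lesion intensity per modality, ordered t1w, t2w,
#'   flair); the default provides `positive`, the complementary partial
#'   patterns `t1t2` and `flair`, and a generic `distractor`.
#' @param noise_sd standard deviation of the white background noise (>= 0).
#' @param seed integer seed controlling the noise field.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(subject_id, grid_shape, lesions = list(),
                         modality_contrasts = LESION_CONTRASTS,
                         noise_sd = DEFAULT_NOISE_SD, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  assert_that(length(grid_shape) == 3L && all(grid_shape >= 8L),
              "grid_shape must be three integers, all >= 8")
  assert_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  for (les in lesions) {
    assert_that(all(c("center", "radii", "class") %in% names(les)),
                "each lesion needs center, radii and class")
    assert_that(all(les$radii > 0), "lesion radii must be positive")
    assert_that(all(les$center >= 1) && all(les$center <= grid_shape),
                sprintf("lesion center (%s) lies outside the %s grid",
                        paste(les$center, collapse = ","),
                        paste(grid_shape, collapse = "x")))
    assert_that(les$class %in% names(modality_contrasts),
                sprintf("unknown lesion class '%s'", les$class))
  }
  structure(list(subject_id = as.character(subject_id),
                 grid_shape = grid_shape, lesions = lesions,
                 modality_contrasts = modality_contrasts,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth ellipsoidal intensity profile: 1 inside the ellipsoid, sigmoid
# fall-off across the boundary (in units of the normalized radius).
ellipsoid_profile <- function(grid_shape, center, radii, edge = 0.15) {
  gx <- seq_len(grid_shape[1]); gy <- seq_len(grid_shape[2])
  gz <- seq_len(grid_shape[3])
  dx2 <- ((gx - center[1]) / radii[1])^2
  dy2 <- ((gy - center[2]) / radii[2])^2
  dz2 <- ((gz - center[3]) / radii[3])^2
  rho <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
  1 / (1 + exp((rho - 1) / edge))
}

ellipsoid_mask <- function(grid_shape, center, radii) {
  gx <- seq_len(grid_shape[1]); gy <- seq_len(grid_shape[2])
  gz <- seq_len(grid_shape[3])
  dx2 <- ((gx - center[1]) / radii[1])^2
  dy2 <- ((gy - center[2]) / radii[2])^2
  dz2 <- ((gz - center[3]) / radii[3])^2
  (outer(outer(dx2, dy2, "+"), dz2, "+")) <= 1
}

#' Generate one multi-modal phantom volume
#'
#' Renders a `phantom_spec` into three modality grids, the binary mask of
#' its positive-class lesions and the bag label under the at-least-one-
#' positive-instance rule. Identical spec and seed give bit-identical
#' output.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `volume` (a `multimodal_volume`), `lesion_mask`
#'   (binary 3-D array covering positive lesions) and `bag_label` (0/1).
#' @export
generate_phantom <- function(spec) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  gs <- spec$grid_shape
  vols <- with_seed(spec$seed, {
    lapply(seq_along(MODALITIES), function(m) {
      array(stats::rnorm(prod(gs), mean = BACKGROUND_BASE,
                         sd = spec$noise_sd), gs)
    })
  })
  names(vols) <- MODALITIES
  mask <- array(FALSE, gs)
  for (les in spec$lesions) {
    prof <- ellipsoid_profile(gs, les$center, les$radii)
    contrast <- spec$modality_contrasts[[les$class]]
    for (m in seq_along(MODALITIES)) {
      vols[[m]] <- vols[[m]] + contrast[m] * prof
    }
    if (les$class == "positive") {
      mask <- mask | ellipsoid_mask(gs, les$center, les$radii)
    }
  }
  label <- as.integer(any(vapply(spec$lesions, function(l)
    l$class == "positive", logical(1))))
  vol <- multimodal_volume(spec$subject_id, vols$t1w, vols$t2w, vols$flair)
  list(volume = vol, lesion_mask = array(as.integer(mask), gs),
       bag_label = label)
}

# Octant (2x2x2 instance cell) index of a voxel center, 1..8.
octant_id <- function(center, grid_shape) {
  bits <- as.integer(center > grid_shape / 2)
  1L + bits[1] + 2L * bits[2] + 4L * bits[3]
}

# Sample a random lesion whose ellipsoid fits inside the grid. The octant
# predicate, when given, constrains the center's octant membership;
# `avoid` lists existing lesions the new one must neither overlap (kept
# apart by the sum of the largest radii plus a 2-voxel margin, and by at
# least `min_dist` between centers) nor share an octant cell with —
# distractor pairs must stay separable at the granularity the encoder
# resolves, i.e. farther apart than its receptive field. Best effort over
# 200 draws.
sample_lesion <- function(grid_shape, class, in_octant = NULL,
                          avoid = list(), min_dist = 0,
                          contain_octant = FALSE) {
  best <- NULL
  best_sep <- -Inf
  for (attempt in 1:20000) {
    # radii are redrawn per attempt so tight placement constraints stay
    # satisfiable for some size draw
    rfrac <- stats::runif(3, 0.10, 0.18)
    radii <- pmax(2, rfrac * grid_shape)
    # keep the whole smoothed profile (tail ~1.4 r) clear of the volume
    # border: border-clipped lesions carry a permutation-invariant
    # position signature that would contaminate the octant task
    center <- vapply(seq_len(3L), function(a) {
      lo <- ceiling(1.4 * radii[a]) + 2
      hi <- grid_shape[a] - ceiling(1.4 * radii[a]) - 2
      stats::runif(1, lo, hi)
    }, numeric(1))
    center <- round(center)
    if (!is.null(in_octant) &&
        octant_predicate(center, grid_shape) != in_octant) next
    if (contain_octant) {
      # the whole ellipsoid must sit inside one octant cell, so the
      # lesion's instance-cell coordinate is an unambiguous position
      # readout (a boundary-straddling lesion would contradict its
      # center-based label)
      half <- grid_shape / 2
      lo_ok <- center - radii >= ifelse(center > half, half + 1, 1)
      hi_ok <- center + radii <= ifelse(center > half, grid_shape, half)
      if (!all(lo_ok & hi_ok)) next
    }
    sep <- Inf
    for (other in avoid) {
      if (octant_id(center, grid_shape) ==
          octant_id(other$center, grid_shape)) sep <- min(sep, -1e9)
      dist <- sqrt(sum((center - other$center)^2))
      gap <- dist - max(max(radii) + max(other$radii), min_dist)
      sep <- min(sep, gap)
    }
    if (sep > best_sep) {
      best <- list(center = center, radii = radii, class = class)
      best_sep <- sep
    }
    if (sep >= 2) break
  }
  assert_that(!is.null(best), "could not place a lesion inside the grid")
  best
}

# TRUE iff a voxel center lies in the designated octant (all coordinates in
# the upper half of their axis).
octant_predicate <- function(center, grid_shape) {
  all(center > grid_shape / 2)
}

#' Generate a phantom cohort on disk
#'
#' Writes NIfTI volumes (three modalities plus positive-lesion mask) and a
#' tab-delimited manifest for a cohort of synthetic subjects.
#'
#' Under `label_rule = "presence"` positive subjects carry one
#' positive-class lesion (bright in all three sequences) plus, with
#' probability 1/2, one partial distractor; negative subjects carry a
#' spatially separated complementary pair (one T1w/T2w-bright lesion, one
#' FLAIR-only lesion) whose summed contrast matches a positive lesion, so
#' only the instance-level conjunction of sequences — not any global
#' intensity statistic — carries the label (`distractors = FALSE` drops
#' all background-like lesions and negatives become pure noise). Under
#' `label_rule = "octant"` every subject carries exactly one
#' positive-class lesion and the label is 1 iff its center lies in the
#' upper-half octant of all three axes, making spatial position the only
#' informative signal.
#'
#' @param n_positive,n_negative subject counts (>= 0).
#' @param grid_shape integer triple; default the desk-scale 48 x 48 x 32.
#' @param label_rule `"presence"` or `"octant"`.
#' @param seed integer master seed; everything derives from it.
#' @param out_dir output directory (created if needed).
#' @param distractors logical; implant distractor lesions in
#'   presence-rule subjects (default TRUE).
#' @param noise_sd background noise standard deviation.
#' @return the cohort manifest as a data.frame (invisibly also written to
#'   `manifest.tsv` in `out_dir`), with columns subject_id, t1w, t2w,
#'   flair, mask, label.
#' @export
generate_cohort <- function(n_positive, n_negative,
                            grid_shape = c(48L, 48L, 32L),
                            label_rule = c("presence", "octant"),
                            seed = 1L, out_dir = tempfile("cohort"),
                            distractors = TRUE,
                            noise_sd = DEFAULT_NOISE_SD) {
  label_rule <- match.arg(label_rule)
  assert_that(is_count(n_positive) && is_count(n_negative),
              "subject counts must be non-negative integers")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create '%s'", out_dir))
  n <- n_positive + n_negative
  labels <- rep(c(1L, 0L), c(n_positive, n_negative))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("sub-%03d", i)
    sseed <- derive_seed(seed, paste0("subject-", label_rule), i)
    lesions <- with_seed(sseed, {
      if (label_rule == "presence") {
        if (labels[i] == 1L) {
          les <- list(sample_lesion(grid_shape, "positive"))
          if (distractors && stats::runif(1) < 0.5) {
            les <- c(les, list(sample_lesion(
              grid_shape, sample(c("t1t2", "flair"), 1), avoid = les,
              min_dist = 0.5 * max(grid_shape))))
          }
          les
        } else if (distractors) {
          # complementary pair: same total contrast as one positive
          # lesion, but separated beyond the encoder's receptive field
          # so no local window ever sees the full conjunction
          les <- list(sample_lesion(grid_shape, "t1t2"))
          c(les, list(sample_lesion(grid_shape, "flair", avoid = les,
                                    min_dist = 0.5 * max(grid_shape))))
        } else {
          list()
        }
      } else {                       # octant rule: position is the label
        list(sample_lesion(grid_shape, "positive",
                           in_octant = labels[i] == 1L,
                           contain_octant = TRUE))
      }
    })
    spec <- phantom_spec(sid, grid_shape, lesions, noise_sd = noise_sd,
                         seed = derive_seed(sseed, "noise"))
    ph <- generate_phantom(spec)
    paths <- file.path(out_dir, paste0(sid, "_", MODALITIES, ".nii.gz"))
    names(paths) <- MODALITIES
    for (m in MODALITIES) {
      RNifti::writeNifti(RNifti::asNifti(ph$volume[[m]]), paths[[m]])
    }
    mask_path <- file.path(out_dir, paste0(sid, "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(ph$lesion_mask + 0), mask_path)
    rows[[i]] <- data.frame(subject_id = sid, t1w = paths[["t1w"]],
                            t2w = paths[["t2w"]], flair = paths[["flair"]],
                            mask = mask_path, label = labels[i],
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Read a cohort manifest
#' @param path path to a tab-delimited manifest with header
#'   subject_id, t1w, t2w, flair, mask, label.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  assert_that(all(c("subject_id", "t1w", "t2w", "flair", "label") %in%
                    names(m)), "manifest is missing required columns")
  assert_that(!anyDuplicated(m$subject_id), "duplicate subject_ids in manifest")
  assert_that(all(m$label %in% 0:1), "labels must be 0/1")
  m
}

#' Per-instance ground-truth labels from a lesion mask
#'
#' Partitions the volume grid into the encoder's instance cells (the same
#' partition used by adaptive pooling and key-patch geometry) and labels an
#' instance 1 iff its cell overlaps the positive-lesion mask. Instances are
#' ordered x-fastest, then y, then z, matching the flattened feature grid.
#'
#' @param lesion_mask binary 3-D array.
#' @param instance_grid_shape integer triple (cells per axis).
#' @return integer vector of 0/1 labels, length `prod(instance_grid_shape)`.
#' @export
instance_ground_truth <- function(lesion_mask, instance_grid_shape) {
  d <- dim(lesion_mask)
  assert_that(length(d) == 3L, "lesion_mask must be a 3-D array")
  t <- as.integer(instance_grid_shape)
  assert_that(all(d >= t), "instance grid exceeds mask grid")
  bx <- cell_bounds(d[1], t[1]); by <- cell_bounds(d[2], t[2])
  bz <- cell_bounds(d[3], t[3])
  y <- integer(prod(t))
  n <- 0L
  for (kz in seq_len(t[3])) for (ky in seq_len(t[2]))
    for (kx in seq_len(t[1])) {
      n <- n + 1L
      blk <- lesion_mask[bx[kx, 1]:bx[kx, 2], by[ky, 1]:by[ky, 2],
                         bz[kz, 1]:bz[kz, 2]]
      y[n] <- as.integer(any(blk != 0))
    }
  y
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s, grid %s, %d lesion(s), noise sd %.3g\n",
              x$subject_id, paste(x$grid_shape, collapse = "x"),
              length(x$lesions), x$noise_sd))
  invisible(x)
}
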