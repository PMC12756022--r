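# Interpretability: key-patch extraction from the final attention weights
# and 3-D Grad-CAM saliency, both verifiable against the synthetic lesion
# masks.

as_habmil_model <- function(object) {
  if (inherits(object, "habmil")) object$model
  else if (inherits(object, "habmil_model")) object
  else stop("need a habmil fit or habmil_model", call. = FALSE)
}

#' Instance-cell voxel boxes for the encoder's instance grid
#'
#' The instance cells partition the input volume exactly (no overlap, no
#' gaps): cell i along an axis of n voxels covers
#' (floor(n(i-1)/t)+1)..floor(n i/t).
#'
#' @param input_shape volume shape (integer triple).
#' @param instance_grid instance grid (integer triple).
#' @return data.frame with one row per instance (x-fastest order) and
#'   columns x0, x1, y0, y1, z0, z1 (inclusive voxel bounds).
#' @export
instance_boxes <- function(input_shape, instance_grid) {
  bx <- cell_bounds(input_shape[1], instance_grid[1])
  by <- cell_bounds(input_shape[2], instance_grid[2])
  bz <- cell_bounds(input_shape[3], instance_grid[3])
  g <- expand.grid(ix = seq_len(instance_grid[1]),
                   iy = seq_len(instance_grid[2]),
                   iz = seq_len(instance_grid[3]))
  data.frame(instance = seq_len(nrow(g)),
             x0 = bx[g$ix, 1], x1 = bx[g$ix, 2],
             y0 = by[g$iy, 1], y1 = by[g$iy, 2],
             z0 = bz[g$iz, 1], z1 = bz[g$iz, 2])
}

#' Key patches: top-k instances by final attention weight
#'
#' Maps the k highest-weighted instances of a bag back to their voxel
#' boxes. Ties in weight are broken by instance index (lower index first).
#'
#' @param object a fitted `habmil` object or a `habmil_model`.
#' @param volume a standardized `multimodal_volume`.
#' @param k number of patches (1 <= k <= N).
#' @return object of class `key_patch_set`: data.frame sorted by weight
#'   descending with instance index, weight and voxel bounds.
#' @export
key_patches <- function(object, volume, k = 1L) {
  model <- as_habmil_model(object)
  fw <- model_forward(model, volume_to_array(volume), training = FALSE)
  w <- fw$weights
  n <- length(w)
  assert_that(is_count(k) && k >= 1L && k <= n,
              sprintf("k must be in 1..%d", n))
  boxes <- instance_boxes(model$config$encoder$input_shape,
                          model$config$encoder$target_instance_grid)
  ord <- order(-w, boxes$instance)
  out <- cbind(boxes[ord[seq_len(k)], ], weight = w[ord[seq_len(k)]])
  out <- out[, c("instance", "weight", "x0", "x1", "y0", "y1", "z0", "z1")]
  rownames(out) <- NULL
  structure(list(patches = out, subject_id = volume$subject_id,
                 weights = w), class = "key_patch_set")
}

#' @export
print.key_patch_set <- function(x, ...) {
  cat(sprintf("key_patch_set %s: top %d of %d instances\n", x$subject_id,
              nrow(x$patches), length(x$weights)))
  print(x$patches, row.names = FALSE)
  invisible(x)
}

#' 3-D Grad-CAM saliency volume
#'
#' Gradient-weighted class activation map of an encoder stage with respect
#' to the bag logit, ReLU-rectified, trilinearly upsampled to the input
#' shape and min-max scaled to [0,1] (a flat map is returned as all
#' zeros).
#'
#' The default `"elementwise"` method sums the per-voxel product of
#' gradients and activations over channels, which stays faithful under the
#' max pooling used throughout this encoder; `"channel"` is the classic
#' variant with spatially averaged gradients as channel weights (those
#' averages largely cancel under max pooling, so it is mainly of
#' comparative interest here).
#'
#' @param object a fitted `habmil` object or a `habmil_model`.
#' @param volume a standardized `multimodal_volume`.
#' @param target_stage encoder stage index (default: the last stage, the
#'   finest grid with class-relevant gradients).
#' @param method `"elementwise"` (default) or `"channel"`.
#' @return object of class `saliency_volume`: `heat` (3-D array in [0,1]
#'   of the input shape), `source_layer`, `subject_id`.
#' @export
gradcam3d <- function(object, volume, target_stage = NULL,
                      method = c("elementwise", "channel")) {
  method <- match.arg(method)
  model <- as_habmil_model(object)
  n_stages <- length(model$config$encoder$stage_channels)
  if (is.null(target_stage)) target_stage <- n_stages
  assert_that(target_stage >= 1 && target_stage <= n_stages,
              "target_stage out of range")
  x <- volume_to_array(volume)
  fw <- model_forward(model, x, training = FALSE)
  bw <- model_backward(model, fw, dlogit = 1, want_stage_grads = TRUE)
  act <- fw$cache$enc$stages[[target_stage]]$act
  grad <- bw$stage_grads[[target_stage]]
  cam <- array(0, dim(act)[1:3])
  if (method == "elementwise") {
    for (c in seq_len(dim(act)[4])) cam <- cam + grad[, , , c] * act[, , , c]
  } else {
    ch_w <- apply(grad, 4L, mean)
    for (c in seq_along(ch_w)) cam <- cam + ch_w[c] * act[, , , c]
  }
  cam <- pmax(cam, 0)
  heat <- resample_trilinear(cam, dim(x)[1:3])
  rng <- range(heat)
  heat <- if (diff(rng) < 1e-12) heat * 0 else (heat - rng[1]) / diff(rng)
  structure(list(heat = heat,
                 source_layer = sprintf("stage%d", target_stage),
                 subject_id = volume$subject_id),
            class = "saliency_volume")
}

#' Write a saliency volume as NIfTI
#' @param saliency a `saliency_volume`.
#' @param path output .nii.gz path.
#' @export
write_saliency <- function(saliency, path) {
  RNifti::writeNifti(RNifti::asNifti(saliency$heat), path)
  invisible(path)
}

#' Render per-subject interpretation panels
#'
#' Writes three PNG panels for one subject: the original FLAIR slice, the
#' key-patch overlay and the saliency overlay. The displayed axial slice
#' is the lesion-mask center of mass when a mask is given, otherwise the
#' volume center.
#'
#' @param volume a `multimodal_volume`.
#' @param saliency a `saliency_volume` (or NULL to skip that panel).
#' @param patches a `key_patch_set` (or NULL to skip that panel).
#' @param out_dir output directory.
#' @param lesion_mask optional binary 3-D array for slice selection.
#' @return character vector of written file paths.
#' @export
render_report <- function(volume, saliency = NULL, patches = NULL,
                          out_dir = tempfile("report"),
                          lesion_mask = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create '%s'", out_dir))
  d <- dim(volume$flair)
  slice <- if (!is.null(lesion_mask) && any(lesion_mask != 0)) {
    idx <- which(lesion_mask != 0, arr.ind = TRUE)
    round(mean(idx[, 3]))
  } else {
    round(d[3] / 2)
  }
  base <- volume$flair[, , slice]
  files <- character(0)
  panel <- function(name, draw) {
    path <- file.path(out_dir, sprintf("%s_%s.png", volume$subject_id, name))
    grDevices::png(path, width = 480, height = 480)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mar = c(1, 1, 2, 1))
    graphics::image(seq_len(d[1]), seq_len(d[2]), base,
                    col = grDevices::gray.colors(128), axes = FALSE,
                    xlab = "", ylab = "",
                    main = sprintf("%s %s (z=%d)", volume$subject_id, name,
                                   slice))
    draw()
    path
  }
  files <- c(files, panel("original", function() NULL))
  if (!is.null(patches)) {
    files <- c(files, panel("keypatch", function() {
      p <- patches$patches
      for (i in seq_len(nrow(p))) {
        if (slice >= p$z0[i] && slice <= p$z1[i]) {
          graphics::rect(p$x0[i], p$y0[i], p$x1[i], p$y1[i], border = "red",
                         lwd = 2)
        }
      }
    }))
  }
  if (!is.null(saliency)) {
    files <- c(files, panel("saliency", function() {
      heat <- saliency$heat[, , slice]
      cols <- grDevices::hcl.colors(64, "YlOrRd", rev = TRUE, alpha = 0.4)
      graphics::image(seq_len(d[1]), seq_len(d[2]), heat, col = cols,
                      add = TRUE)
    }))
  }
  files
}
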