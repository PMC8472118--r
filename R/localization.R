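# Stage 1: whole-image six-class segmentation, medial/lateral splitting and
# std-margin ROI extraction.
#
# Conventions: volumes are dense arrays with axis order (row y, column x,
# slice z), 1-based inclusive index ranges throughout. Class codes:
# 0 background, 1 femur, 2 femoral cartilage, 3 tibia, 4 tibial cartilage,
# 5 meniscus.

MENISCUS_CLASS <- 5L
N_CLASSES <- 6L

#' Construct an MR volume object
#'
#' @param voxels 3-d numeric array (rows, columns, slices) of intensities.
#' @param pixel_size_mm In-plane pixel size in millimetres.
#' @param slice_thickness_mm Slice thickness in millimetres.
#' @param patient_id Identifier string.
#' @param laterality `"left"` or `"right"` knee.
#' @return An object of class `mr_volume`.
#' @export
mr_volume <- function(voxels, pixel_size_mm = 0.3125, slice_thickness_mm = 0.5,
                      patient_id = "anon", laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (length(dim(voxels)) != 3) stop("voxels must be a 3-d array")
  if (!all(is.finite(voxels))) stop("voxel intensities must be finite")
  structure(list(voxels = voxels, pixel_size_mm = pixel_size_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 patient_id = patient_id, laterality = laterality),
            class = "mr_volume")
}

#' @export
print.mr_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<mr_volume> %s (%s knee): %d x %d x %d, pixel %.4f mm, slice %.2f mm\n",
              x$patient_id, x$laterality, d[1], d[2], d[3],
              x$pixel_size_mm, x$slice_thickness_mm))
  invisible(x)
}

#' Construct a label volume
#'
#' @param labels 3-d integer array with values in `0:5`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels) {
  if (length(dim(labels)) != 3) stop("labels must be a 3-d array")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:(N_CLASSES - 1L))) {
    stop("labels must take values in 0..5")
  }
  structure(list(labels = labels), class = "label_volume")
}

#' Z-score normalize an MR volume
#'
#' Standardizes intensities to zero mean and unit standard deviation computed
#' over the whole volume, as applied to every input volume before
#' segmentation.
#'
#' @param volume An [mr_volume()].
#' @return The normalized `mr_volume`.
#' @export
normalize_zscore <- function(volume) {
  stopifnot(inherits(volume, "mr_volume"))
  v <- volume$voxels
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))   # population standard deviation
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score normalize a constant-intensity volume")
  }
  volume$voxels <- (v - m) / s
  volume
}

#' Six-class segmentation of a whole volume
#'
#' Runs the localizer slice by slice and takes the per-pixel argmax of the
#' class probabilities; ties are broken toward the lowest class code.
#'
#' @param volume An [mr_volume()].
#' @param net A `unet_network` with six output classes.
#' @param batch_size Slices per forward pass.
#' @return A [label_volume()].
#' @export
segment_multiclass <- function(volume, net, batch_size = 8L) {
  stopifnot(inherits(volume, "mr_volume"), inherits(net, "unet_network"))
  if (net$config$n_classes != N_CLASSES) {
    stop("segment_multiclass requires a 6-class network")
  }
  prob <- predict_prob_volume(net, volume$voxels, batch_size)
  label_volume(prob_argmax(prob))
}

# prob: (H, W, K, Z) -> integer (H, W, Z) with lowest-code tie-break
prob_argmax <- function(prob) {
  d <- dim(prob)
  m <- matrix(aperm(prob, c(1, 2, 4, 3)), ncol = d[3])
  lab <- max.col(m, ties.method = "first") - 1L
  array(lab, c(d[1], d[2], d[4]))
}

# slice-batched eval-mode forward over a full volume; returns (H, W, K, Z)
predict_prob_volume <- function(net, voxels, batch_size = 8L) {
  d <- dim(voxels)
  K <- net$config$n_classes
  prob <- array(0, c(d[1], d[2], K, d[3]))
  for (start in seq(1L, d[3], by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, d[3])
    x <- array(voxels[, , idx], c(d[1], d[2], 1L, length(idx)))
    fw <- unet_forward(net, x, train = FALSE)
    prob[, , , idx] <- fw$prob
  }
  prob
}

#' Split the meniscus class into medial and lateral components
#'
#' Extracts the two largest 3-d connected components (6-connectivity) of the
#' meniscus class and assigns each to the medial or lateral side from its
#' x-centroid relative to the image midline: the medial meniscus lies toward
#' the body midline, so it maps to the higher column indices on a right knee
#' and the lower ones on a left knee. Smaller components are discarded as
#' outliers; degenerate localizations (a single component, or both major
#' components on one side) yield a one-sided result with a warning.
#'
#' @param labels A [label_volume()] or binary/integer 3-d array where the
#'   meniscus voxels carry class code 5 (or any non-zero value for a binary
#'   mask).
#' @param laterality `"left"` or `"right"`.
#' @return A list with binary 3-d arrays `medial` and `lateral`.
#' @export
split_meniscus <- function(labels, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  arr <- if (inherits(labels, "label_volume")) labels$labels else labels
  mask <- arr == MENISCUS_CLASS
  if (!any(mask)) mask <- arr != 0
  if (!any(mask)) stop("no meniscus voxels to split")
  storage.mode(mask) <- "integer"
  comp <- cpp_label3d(mask)
  sizes <- tabulate(comp)
  keep <- order(sizes, decreasing = TRUE)[seq_len(min(2L, length(sizes)))]
  W <- dim(arr)[2]
  midline <- (W + 1) / 2
  centroid_x <- vapply(keep, function(k) {
    mean(arrayInd(which(comp == k), dim(comp))[, 2])
  }, 0)
  empty <- array(FALSE, dim(arr))
  # side of each component from its centroid relative to the midline;
  # medial lies toward the body midline (higher x on a right knee)
  side_of <- ifelse(xor(centroid_x > midline, laterality == "left"),
                    "medial", "lateral")
  if (length(keep) == 1L) {
    warning("only one meniscus component found; returning a one-sided result")
    m1 <- comp == keep[1]
    return(if (side_of[1] == "medial") list(medial = m1, lateral = empty)
           else list(medial = empty, lateral = m1))
  }
  if (side_of[1] == side_of[2]) {
    warning("both major meniscus components lie on the ", side_of[1],
            " side; keeping the larger")
    out <- list(medial = empty, lateral = empty)
    out[[side_of[1]]] <- comp == keep[1]
    return(out)
  }
  out <- list(medial = empty, lateral = empty)
  out[[side_of[1]]] <- comp == keep[1]
  out[[side_of[2]]] <- comp == keep[2]
  out
}

#' Compute a margin-padded ROI box around a meniscus component
#'
#' For each in-plane axis the per-slice foreground minimum and maximum
#' coordinates are pooled over all foreground-bearing slices and the margin is
#' the rounded standard deviation of that pooled sample; the ROI extends the
#' global extrema by the margin, clamped to the volume. The slice axis uses
#' the analogous rule with the roles of slice and column exchanged: per-column
#' minimum and maximum slice indices are pooled. In-plane axes are finally
#' expanded symmetrically to at least `min_size`.
#'
#' @param mask Binary 3-d array (rows, columns, slices).
#' @param min_size Minimum in-plane ROI side length, in pixels.
#' @param margin_mode `"population"` (divide by n) or `"sample"` (n - 1)
#'   standard deviation.
#' @return An object of class `roi_box` with fields `y_range`, `x_range`,
#'   `z_range` (1-based inclusive) and `margin`.
#' @export
compute_roi <- function(mask, min_size = 32L, margin_mode = c("population", "sample")) {
  margin_mode <- match.arg(margin_mode)
  if (!any(mask)) stop("cannot compute an ROI for an empty mask")
  d <- dim(mask)
  idx <- arrayInd(which(mask != 0), d)
  pooled_std <- function(v) {
    if (length(v) < 2) return(0)
    if (margin_mode == "sample") stats::sd(v)
    else sqrt(mean((v - mean(v))^2))
  }
  per_slice_extents <- function(axis) {
    unlist(lapply(split(idx[, axis], idx[, 3]), range), use.names = FALSE)
  }
  y_vals <- per_slice_extents(1)
  x_vals <- per_slice_extents(2)
  z_vals <- unlist(lapply(split(idx[, 3], idx[, 2]), range), use.names = FALSE)
  margin <- c(y = round(pooled_std(y_vals)),
              x = round(pooled_std(x_vals)),
              z = round(pooled_std(z_vals)))
  clamp <- function(r, n) c(max(1L, r[1]), min(n, r[2]))
  y_range <- clamp(range(idx[, 1]) + c(-1, 1) * margin["y"], d[1])
  x_range <- clamp(range(idx[, 2]) + c(-1, 1) * margin["x"], d[2])
  z_range <- clamp(range(idx[, 3]) + c(-1, 1) * margin["z"], d[3])
  y_range <- expand_range(y_range, min_size, d[1])
  x_range <- expand_range(x_range, min_size, d[2])
  structure(list(y_range = as.integer(y_range), x_range = as.integer(x_range),
                 z_range = as.integer(z_range),
                 margin = vapply(margin, as.integer, 0L),
                 margin_mode = margin_mode, vol_dim = d),
            class = "roi_box")
}

# symmetric expansion to at least `size`, clamped to [1, n]
expand_range <- function(r, size, n) {
  size <- min(size, n)
  while (r[2] - r[1] + 1 < size) {
    if (r[1] > 1) r[1] <- r[1] - 1
    if (r[2] - r[1] + 1 < size && r[2] < n) r[2] <- r[2] + 1
  }
  r
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> y [%d, %d], x [%d, %d], z [%d, %d], margin (y %d, x %d, z %d)\n",
              x$y_range[1], x$y_range[2], x$x_range[1], x$x_range[2],
              x$z_range[1], x$z_range[2], x$margin["y"], x$margin["x"],
              x$margin["z"]))
  invisible(x)
}

#' Crop an ROI from a volume and resample it to a square stack
#'
#' Per-slice crop followed by resampling to `target_size` squared: bilinear
#' interpolation for intensities and nearest-neighbour for labels. Six-class
#' labels are reduced to the binary meniscus-vs-rest form used by the stage-two
#' generator. When crop and target sizes coincide the result is bit-exact.
#'
#' @param volume An [mr_volume()] or a 3-d intensity array.
#' @param labels Optional [label_volume()], 6-class or binary 3-d array.
#' @param roi An [compute_roi()] box.
#' @param target_size Output side length in pixels.
#' @return An object of class `roi_stack` with `images` (target, target, nz),
#'   optional binary `masks`, and the source `roi`.
#' @export
crop_resize <- function(volume, labels = NULL, roi, target_size = 64L) {
  stopifnot(inherits(roi, "roi_box"))
  vox <- if (inherits(volume, "mr_volume")) volume$voxels else volume
  d <- dim(vox)
  if (roi$y_range[1] < 1 || roi$x_range[1] < 1 || roi$z_range[1] < 1 ||
      roi$y_range[2] > d[1] || roi$x_range[2] > d[2] || roi$z_range[2] > d[3]) {
    stop("ROI lies outside the volume")
  }
  ys <- roi$y_range[1]:roi$y_range[2]
  xs <- roi$x_range[1]:roi$x_range[2]
  zs <- roi$z_range[1]:roi$z_range[2]
  nz <- length(zs)
  images <- array(0, c(target_size, target_size, nz))
  masks <- NULL
  lab_arr <- NULL
  if (!is.null(labels)) {
    lab_arr <- if (inherits(labels, "label_volume")) labels$labels else labels
    lab_arr <- binarize_meniscus(lab_arr)
    masks <- array(0L, c(target_size, target_size, nz))
  }
  for (k in seq_len(nz)) {
    images[, , k] <- cpp_resize_bilinear(vox[ys, xs, zs[k], drop = TRUE],
                                         as.integer(target_size),
                                         as.integer(target_size))
    if (!is.null(masks)) {
      masks[, , k] <- as.integer(cpp_resize_nearest(
        lab_arr[ys, xs, zs[k], drop = TRUE] + 0,
        as.integer(target_size), as.integer(target_size)))
    }
  }
  structure(list(images = images, masks = masks, roi = roi,
                 target_size = as.integer(target_size)),
            class = "roi_stack")
}

# reduce a 6-class label array to binary meniscus; pass binary arrays through
binarize_meniscus <- function(lab) {
  u <- unique(as.vector(lab))
  if (all(u %in% c(0L, 1L, FALSE, TRUE))) {
    return(array(as.integer(lab != 0), dim(lab)))
  }
  array(as.integer(lab == MENISCUS_CLASS), dim(lab))
}

#' Paste predicted ROI masks back into full-volume coordinates
#'
#' Inverse of [crop_resize()]: each predicted square mask is resampled
#' (nearest-neighbour) to the native crop size and written into a
#' zero-initialized volume; voxels outside the ROI stay background.
#'
#' @param pred_masks Binary (target, target, nz) array or a `roi_stack` whose
#'   `masks` hold the predictions.
#' @param roi The originating [compute_roi()] box.
#' @param volume_shape Integer vector, dimensions of the output volume.
#' @return Binary 3-d array of shape `volume_shape`.
#' @export
paste_back <- function(pred_masks, roi, volume_shape) {
  stopifnot(inherits(roi, "roi_box"))
  if (inherits(pred_masks, "roi_stack")) pred_masks <- pred_masks$masks
  ys <- roi$y_range[1]:roi$y_range[2]
  xs <- roi$x_range[1]:roi$x_range[2]
  zs <- roi$z_range[1]:roi$z_range[2]
  if (dim(pred_masks)[3] != length(zs)) {
    stop("predicted stack depth does not match the ROI")
  }
  out <- array(0L, volume_shape)
  for (k in seq_along(zs)) {
    out[ys, xs, zs[k]] <- as.integer(cpp_resize_nearest(
      pred_masks[, , k] + 0, length(ys), length(xs)))
  }
  out
}

#' Merge binary masks by voxel-wise union
#'
#' Combines per-side predictions pasted back into full-volume coordinates;
#' overlapping regions take the logical OR.
#'
#' @param ... Binary arrays of identical shape.
#' @return Binary integer array.
#' @export
merge_masks <- function(...) {
  ms <- list(...)
  out <- Reduce(pmax, ms)
  array(as.integer(out != 0), dim(ms[[1]]))
}

#' Extract both meniscus ROI stacks from a labeled volume
#'
#' Convenience wrapper chaining [split_meniscus()], [compute_roi()] and
#' [crop_resize()] for the medial and lateral sides.
#'
#' @param volume An [mr_volume()].
#' @param labels A [label_volume()] (predicted or ground truth).
#' @param gt_labels Optional [label_volume()] providing the mask channel of
#'   the stacks (ground truth for training/evaluation).
#' @param target_size,min_size,margin_mode Passed to [compute_roi()] and
#'   [crop_resize()].
#' @return Named list of `roi_stack` objects (`medial`, `lateral`); a side
#'   without a component is `NULL`.
#' @export
extract_roi_stacks <- function(volume, labels, gt_labels = NULL,
                               target_size = 64L, min_size = 32L,
                               margin_mode = "population") {
  sides <- split_meniscus(labels, volume$laterality)
  out <- list(medial = NULL, lateral = NULL)
  for (side in c("medial", "lateral")) {
    m <- sides[[side]]
    if (!any(m)) next
    roi <- compute_roi(m, min_size = min_size, margin_mode = margin_mode)
    lab <- if (is.null(gt_labels)) NULL else gt_labels
    st <- crop_resize(volume, lab, roi, target_size)
    st$side <- side
    out[[side]] <- st
  }
  out
}
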