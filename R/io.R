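# File formats: NIfTI volumes via RNifti, JSON for ROI boxes and manifests.
# Arrays are written with axis order (row y, column x, slice z); ranges in
# serialized ROI boxes are 1-based inclusive.

#' Read an MR volume from a NIfTI file
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param patient_id,laterality Metadata not carried by NIfTI.
#' @return An [mr_volume()]; pixel size and slice thickness are taken from
#'   the NIfTI header.
#' @export
read_mr_volume <- function(path, patient_id = basename(path),
                           laterality = "right") {
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)
  mr_volume(array(as.numeric(img), dim(img)),
            pixel_size_mm = pix[1], slice_thickness_mm = pix[3],
            patient_id = patient_id, laterality = laterality)
}

#' Write an MR volume (or plain array) to NIfTI
#'
#' @param volume An [mr_volume()], [label_volume()] or 3-d array.
#' @param path Output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(volume, path) {
  if (inherits(volume, "mr_volume")) {
    img <- RNifti::asNifti(volume$voxels)
    RNifti::pixdim(img) <- c(volume$pixel_size_mm, volume$pixel_size_mm,
                             volume$slice_thickness_mm)
  } else if (inherits(volume, "label_volume")) {
    img <- RNifti::asNifti(volume$labels)
  } else {
    img <- RNifti::asNifti(volume + 0)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(array(as.integer(round(as.numeric(img))), dim(img)))
}

#' Serialize an ROI box to JSON
#'
#' @param roi An [compute_roi()] box.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_roi_box <- function(roi, path) {
  stopifnot(inherits(roi, "roi_box"))
  jsonlite::write_json(unclass(roi), path, auto_unbox = FALSE)
  invisible(path)
}

#' Read an ROI box written by [write_roi_box()]
#'
#' @param path `.json` path.
#' @return An `roi_box`.
#' @export
read_roi_box <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(y_range = as.integer(x$y_range),
                 x_range = as.integer(x$x_range),
                 z_range = as.integer(x$z_range),
                 margin = stats::setNames(as.integer(x$margin), c("y", "x", "z")),
                 margin_mode = x$margin_mode,
                 vol_dim = as.integer(x$vol_dim)),
            class = "roi_box")
}

# write every case of a manifest as NIfTI plus a JSON manifest
write_dataset <- function(manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- lapply(seq_len(nrow(manifest$cases)), function(i) {
    row <- manifest$cases[i, ]
    cs <- generate_case(manifest$params, row$case_seed)
    base <- file.path(out_dir, row$patient_id)
    write_nifti_volume(cs$volume, paste0(base, "_volume.nii.gz"))
    write_nifti_volume(cs$labels6, paste0(base, "_labels6.nii.gz"))
    write_nifti_volume(cs$side_masks$medial + 0, paste0(base, "_medial.nii.gz"))
    write_nifti_volume(cs$side_masks$lateral + 0, paste0(base, "_lateral.nii.gz"))
    list(volume = paste0(row$patient_id, "_volume.nii.gz"),
         labels6 = paste0(row$patient_id, "_labels6.nii.gz"),
         laterality = cs$volume$laterality)
  })
  meta <- list(seed = manifest$seed, params = unclass(manifest$params),
               cases = cbind(manifest$cases,
                             laterality = vapply(files, `[[`, "", "laterality")))
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
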