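#' Construct a lesion region
#'
#' A single lesion's voxel set: intensities, 0-based voxel coordinates, and
#' derived size measures. The equivalent diameter is that of the sphere whose
#' volume matches the lesion's total voxel volume, the size proxy used for
#' the minimum-size exclusion rule.
#'
#' @param lesion_id Integer lesion label.
#' @param patient_id Patient identifier (character).
#' @param intensities Numeric vector of voxel intensities (HU).
#' @param coords Integer matrix (n x 3) of 0-based voxel indices.
#' @param spacing Voxel spacing (sx, sy, sz) in mm.
#' @return An object of class `lesion_region`.
#' @export
lesion_region <- function(lesion_id, patient_id, intensities, coords,
                          spacing) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("a lesion region must contain >= 1 voxel")
  if (ncol(coords) != 3L) stop("`coords` must be an n x 3 matrix")
  if (length(intensities) != nrow(coords))
    stop("`intensities` and `coords` lengths differ")
  if (anyDuplicated(coords))
    stop("`coords` contains duplicated voxels")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three positive values")
  storage.mode(coords) <- "integer"
  voxvol <- prod(spacing)
  vol <- nrow(coords) * voxvol
  structure(list(
    lesion_id = as.integer(lesion_id),
    patient_id = as.character(patient_id),
    intensities = as.numeric(intensities),
    coords = coords,
    spacing = spacing,
    n_voxels = nrow(coords),
    voxel_volume_mm3 = voxvol,
    volume_mm3 = vol,
    equivalent_diameter_mm = (6 * vol / pi)^(1 / 3)
  ), class = "lesion_region")
}

#' @export
print.lesion_region <- function(x, ...) {
  cat(sprintf("<lesion_region> patient %s, lesion %d: %d voxels, %.1f mm3, d_eq %.2f mm\n",
              x$patient_id, x$lesion_id, x$n_voxels, x$volume_mm3,
              x$equivalent_diameter_mm))
  invisible(x)
}

#' Split a label mask into individual lesion regions
#'
#' Each distinct positive label becomes one region. A purely binary mask
#' (labels 0/1 only, more than one blob possible) is first separated into
#' 26-connected components, so touching-by-corner voxels belong to the same
#' lesion.
#'
#' @param mask A [label_mask()].
#' @param volume The paired [image_volume()]; shapes must match.
#' @param patient_id Patient identifier attached to every region.
#' @return A list of [lesion_region()] objects, ordered by label.
#' @export
split_lesions <- function(mask, volume, patient_id) {
  if (!inherits(mask, "label_mask")) stop("`mask` must be a label_mask")
  if (!inherits(volume, "image_volume"))
    stop("`volume` must be an image_volume")
  if (!identical(dim(mask$labels), dim(volume$data)))
    stop("mask shape (", paste(dim(mask$labels), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$data), collapse = "x"), ")")
  labels <- mask$labels
  pos <- sort(unique(labels[labels > 0L]))
  if (length(pos) == 0L) return(list())
  if (identical(pos, 1L)) {
    labels <- cpp_label26(labels, dim(labels), FALSE)
    pos <- sort(unique(labels[labels > 0L]))
  }
  lapply(pos, function(k) {
    idx <- which(labels == k)
    lesion_region(k, patient_id, volume$data[idx],
                  arrayInd(idx, dim(labels)) - 1L, volume$spacing)
  })
}

#' Exclude lesions below a minimum equivalent diameter
#'
#' Retains regions whose equivalent-sphere diameter is at least
#' `min_diameter_mm` (boundary inclusive); input order is preserved. The
#' 5 mm default implements the exclusion of lesions smaller than 0.5 cm.
#'
#' @param regions List of [lesion_region()] objects.
#' @param min_diameter_mm Positive threshold in mm.
#' @return The retained sublist.
#' @export
filter_by_size <- function(regions, min_diameter_mm = 5) {
  if (!is.numeric(min_diameter_mm) || min_diameter_mm <= 0)
    stop("`min_diameter_mm` must be > 0")
  keep <- vapply(regions, function(r)
    r$equivalent_diameter_mm >= min_diameter_mm, TRUE)
  regions[keep]
}
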