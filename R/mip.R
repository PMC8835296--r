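#' Thin maximum-intensity-projection slab stack
#'
#' Collapses a native CT volume into consecutive, non-overlapping slabs of
#' approximately `slab_thickness_mm`, each slab pixel being the maximum HU
#' over its constituent native slices. With the default 5-mm slabs on 1-mm
#' slices a 300-slice exam reduces to 60 images, which is the point of the
#' preprocessing: fewer images to segment while plaques — brighter than lung
#' and fat — survive the maximum.
#'
#' Slabs partition the slice index range. The trailing slab may contain fewer
#' slices; it keeps its true thickness (`n_slices_in_slab * dz`) so the
#' scanned z-extent is conserved in volumetrics. If `slab_thickness_mm` is
#' not an integer multiple of the slice spacing, the per-slab slice count is
#' `round(slab_thickness_mm / dz)` and a message reports the deviation.
#'
#' @param vol A [ct_volume].
#' @param slab_thickness_mm Slab thickness in mm; must be at least the slice
#'   spacing.
#' @return An object of class `mip_stack`: list with `slabs` (array rows x
#'   cols x n_slabs), `slab_thickness` (nominal, mm), `slab_to_slices` (list
#'   of native 1-based slice indices per slab), `slab_actual_mm` (per-slab
#'   true thickness), `pixel_area` (mm^2), `exam_id`.
#' @export
compute_mip <- function(vol, slab_thickness_mm = 5) {
  stopifnot(inherits(vol, "ct_volume"))
  dz <- vol$spacing[3]
  if (slab_thickness_mm < dz)
    stop("slab thickness (", slab_thickness_mm,
         " mm) must be at least one slice spacing (", dz, " mm)")
  k <- max(1L, as.integer(round(slab_thickness_mm / dz)))
  if (abs(k * dz - slab_thickness_mm) > 1e-9)
    message("compute_mip: ", slab_thickness_mm, " mm is not a multiple of dz = ",
            dz, " mm; using ", k, " slices (", k * dz, " mm) per slab")
  n <- dim(vol$voxels)[3]
  n_slabs <- ceiling(n / k)
  groups <- split(seq_len(n), ceiling(seq_len(n) / k))
  slabs <- array(0, dim = c(dim(vol$voxels)[1:2], n_slabs))
  for (s in seq_len(n_slabs)) {
    idx <- groups[[s]]
    slabs[, , s] <- if (length(idx) == 1L) vol$voxels[, , idx]
                    else apply(vol$voxels[, , idx, drop = FALSE], c(1, 2), max)
  }
  structure(list(slabs = slabs, slab_thickness = slab_thickness_mm,
                 slab_to_slices = unname(groups),
                 slab_actual_mm = unname(vapply(groups, length, integer(1))) * dz,
                 pixel_area = vol$spacing[1] * vol$spacing[2],
                 spacing = vol$spacing, exam_id = vol$exam_id),
            class = "mip_stack")
}

#' @export
print.mip_stack <- function(x, ...) {
  d <- dim(x$slabs)
  cat(sprintf("<mip_stack %s> %d slabs of %g mm (%d x %d px, pixel area %.3g mm^2)\n",
              x$exam_id, d[3], x$slab_thickness, d[1], d[2], x$pixel_area))
  invisible(x)
}

#' Project a native-geometry mask onto a MIP stack
#'
#' A slab-mask pixel is positive when any constituent native slice is
#' positive — the projection under which a mask delineated on MIP images
#' corresponds to the native ground truth.
#'
#' @param mask 3-D [binary_mask] in the native volume geometry.
#' @param stack The [compute_mip()] result for the same volume.
#' @return A 3-D [binary_mask] over the slab stack.
#' @export
mask_to_mip <- function(mask, stack) {
  stopifnot(inherits(stack, "mip_stack"))
  n_slabs <- length(stack$slab_to_slices)
  out <- array(0L, dim = c(dim(mask)[1:2], n_slabs))
  for (s in seq_len(n_slabs)) {
    idx <- stack$slab_to_slices[[s]]
    out[, , s] <- as.integer(
      apply(mask[, , idx, drop = FALSE], c(1, 2), max))
  }
  binary_mask(out, source_dim = dim(stack$slabs))
}

#' Mask volumes in millilitres
#'
#' `slab_mask_volume_ml` integrates a slab-geometry mask: positive pixels x
#' pixel area x the slab's true thickness, summed over slabs; a trailing
#' partial slab contributes its actual thickness. `native_mask_volume_ml`
#' is the native-geometry analogue with per-slice thickness dz.
#'
#' @param mask A [binary_mask] matching the stack/volume geometry.
#' @param stack A [compute_mip()] result.
#' @return Volume in mL.
#' @export
slab_mask_volume_ml <- function(mask, stack) {
  stopifnot(inherits(stack, "mip_stack"))
  if (!identical(dim(mask), dim(stack$slabs)))
    stop("mask geometry (", paste(dim(mask), collapse = "x"),
         ") does not match slab stack (",
         paste(dim(stack$slabs), collapse = "x"), ")")
  counts <- vapply(seq_len(dim(mask)[3]),
                   function(s) sum(mask[, , s]), numeric(1))
  sum(counts * stack$pixel_area * stack$slab_actual_mm) / 1000
}

#' @rdname slab_mask_volume_ml
#' @param vol A [ct_volume] matching the mask geometry.
#' @export
native_mask_volume_ml <- function(mask, vol) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!identical(dim(mask), dim(vol$voxels)))
    stop("mask geometry (", paste(dim(mask), collapse = "x"),
         ") does not match volume (",
         paste(dim(vol$voxels), collapse = "x"), ")")
  sum(mask) * prod(vol$spacing) / 1000
}

#' Persist a MIP stack
#'
#' Writes the slab images as a NIfTI volume (one "slice" per slab, with the
#' nominal slab thickness as z-spacing) plus a JSON sidecar holding the
#' slab-to-slice mapping and per-slab true thicknesses.
#'
#' @param stack A [compute_mip()] result.
#' @param path Output NIfTI path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_mip <- function(stack, path) {
  stopifnot(inherits(stack, "mip_stack"))
  img <- RNifti::asNifti(stack$slabs)
  RNifti::pixdim(img) <- c(stack$spacing[1:2], stack$slab_thickness)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(exam_id = stack$exam_id, slab_thickness = stack$slab_thickness,
         slab_to_slices = stack$slab_to_slices,
         slab_actual_mm = stack$slab_actual_mm),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
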