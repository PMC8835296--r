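#' CT volume container
#'
#' Wraps a 3-D grid of Hounsfield-unit voxels together with its physical
#' voxel spacing and study identifiers. The array layout is
#' `[row, col, slice]`: axial slice `i` is `voxels[, , i]` and slice indices
#' are 1-based throughout the package.
#'
#' @param voxels Numeric 3-D array of HU values, dim `c(rows, cols, slices)`.
#' @param spacing Numeric length-3 vector `c(dy, dx, dz)` in mm: in-plane row
#'   and column spacing, then slice spacing.
#' @param exam_id,participant_id Character identifiers.
#' @param round Screening round (integer, e.g. 2 or 3).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, exam_id = "exam", participant_id = "p",
                      round = 1L) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array (rows x cols x slices)")
  if (!all(is.finite(voxels)))
    stop("`voxels` contains non-finite HU values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values c(dy, dx, dz) in mm")
  structure(
    list(voxels = voxels, spacing = spacing,
         exam_id = as.character(exam_id),
         participant_id = as.character(participant_id),
         round = as.integer(round)),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume %s> participant %s, round %d: %d x %d x %d voxels @ %.3g x %.3g x %.3g mm (z-extent %.1f mm)\n",
    x$exam_id, x$participant_id, x$round, d[1], d[2], d[3],
    x$spacing[1], x$spacing[2], x$spacing[3], d[3] * x$spacing[3]))
  invisible(x)
}

#' Binary mask container
#'
#' A segmentation mask geometry-locked to a source image grid: values are
#' strictly 0/1 and the array shape must equal the source grid shape.
#'
#' @param pixels Array (2-D or 3-D) with values in \{0, 1\}.
#' @param source_dim Integer dims of the source grid the mask refers to; the
#'   mask is rejected if its shape differs.
#' @return An object of class `binary_mask` (the integer array, with
#'   attributes).
#' @export
binary_mask <- function(pixels, source_dim = dim(pixels)) {
  if (is.null(dim(pixels))) stop("`pixels` must be a matrix or 3-D array")
  bad <- !(pixels %in% c(0, 1))
  if (any(bad))
    stop(sprintf("mask contains %d value(s) outside {0, 1} (e.g. %s)",
                 sum(bad), format(pixels[which(bad)[1]])))
  if (!identical(as.integer(dim(pixels)), as.integer(source_dim)))
    stop(sprintf("mask shape (%s) does not match source grid (%s)",
                 paste(dim(pixels), collapse = "x"),
                 paste(source_dim, collapse = "x")))
  m <- array(as.integer(pixels), dim = dim(pixels))
  class(m) <- c("binary_mask", class(m))
  m
}

#' Read and write CT volumes as NIfTI
#'
#' Volumes are stored as standard NIfTI-1 files with voxel spacing in the
#' header `pixdim`. A write/read round trip preserves the voxel grid exactly
#' and the spacing to float precision.
#'
#' @param vol A [ct_volume].
#' @param path File path (`.nii` or `.nii.gz`).
#' @param exam_id,participant_id,round Identifiers to attach on read (NIfTI
#'   has no native fields for them; they normally come from the manifest CSV).
#' @return `read_volume` returns a [ct_volume]; `write_volume` returns `path`
#'   invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, exam_id = "exam", participant_id = "p",
                        round = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("NIfTI header of ", path, " carries no usable voxel spacing")
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing = sp[1:3],
            exam_id = exam_id, participant_id = participant_id, round = round)
}

#' @rdname write_volume
#' @param mask A [binary_mask] (for `write_mask`).
#' @param source_dim Expected grid shape used to validate the mask on read.
#' @export
write_mask <- function(mask, spacing, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_mask <- function(path, source_dim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  px <- array(as.numeric(img), dim = dim(img))
  binary_mask(px, source_dim = if (is.null(source_dim)) dim(px) else source_dim)
}

#' Seeded participant-level train/test split
#'
#' Splits exams into non-overlapping train and test groups at the participant
#' level, so that every exam (e.g. both screening rounds) of one participant
#' lands on the same side — the leakage guard used when a cohort contributes
#' repeated examinations.
#'
#' @param manifest Data frame with at least `exam_id` and `participant_id`.
#' @param train_fraction Fraction of participants assigned to training,
#'   strictly between 0 and 1.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with data frames `train` and `test` (subsets of `manifest`),
#'   plus `train_participants` / `test_participants`.
#' @export
split_exams <- function(manifest, train_fraction, seed = 1L) {
  stopifnot(is.data.frame(manifest),
            all(c("exam_id", "participant_id") %in% names(manifest)))
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("`train_fraction` must be strictly between 0 and 1")
  participants <- unique(as.character(manifest$participant_id))
  n <- length(participants)
  if (n < 2L) stop("need at least 2 participants to split, got ", n)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L) # both sides non-empty
  train_p <- with_seed_(seed, sample(participants, n_train))
  in_train <- manifest$participant_id %in% train_p
  list(train = manifest[in_train, , drop = FALSE],
       test = manifest[!in_train, , drop = FALSE],
       train_participants = sort(train_p),
       test_participants = sort(setdiff(participants, train_p)))
}
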