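#' Read and write volumes and masks as NIfTI
#'
#' Volumes and masks are stored as 3D NIfTI files.  On disk the array axes
#' follow NIfTI convention `(x = col, y = row, z = slice)`; in memory the
#' first axis is the slice (proximal to distal).  NIfTI carries a single
#' through-plane spacing, which is interpreted as the slice *pitch*
#' (thickness + gap); `slice_gap` decomposes it back into thickness and gap
#' (protocol default 0.4 mm).  Masks are written as unsigned 8-bit labels.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param slice_gap Assumed inter-slice gap in mm when reading (default 0.4).
#' @param subject_id Subject id to attach; defaults to the file stem.
#' @return `read_volume()` an [image_volume()]; `read_mask()` a
#'   [segmentation_mask()]; the writers return the path invisibly.
#' @examples
#' g <- voxel_geometry(1, 1, n_rows = 16, n_cols = 16, n_slices = 3)
#' vol <- image_volume(array(runif(3 * 16 * 16), c(3, 16, 16)), g, "s1")
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(vol, f)
#' vol2 <- read_volume(f, subject_id = "s1")
#' max(abs(vol2$voxels - vol$voxels)) < 1e-6
#' @export
read_volume <- function(path, slice_gap = 0.4, subject_id = NULL) {
  img <- read_nifti_array(path)
  geom <- geometry_from_nifti(img, slice_gap)
  vox <- aperm(unclass(img), c(3, 2, 1))
  attributes(vox) <- list(dim = dim(vox))
  if (is.null(subject_id)) subject_id <- file_stem(path)
  image_volume(vox, geom, subject_id)
}

#' @rdname read_volume
#' @export
read_mask <- function(path, slice_gap = 0.4, subject_id = NULL) {
  img <- read_nifti_array(path)
  geom <- geometry_from_nifti(img, slice_gap)
  vox <- aperm(unclass(img), c(3, 2, 1))
  attributes(vox) <- list(dim = dim(vox))
  vox <- (vox > 0.5) * 1L
  if (is.null(subject_id)) subject_id <- file_stem(path)
  segmentation_mask(vox, geom, subject_id)
}

#' @rdname read_volume
#' @param volume An [image_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  write_nifti_array(aperm(volume$voxels, c(3, 2, 1)), volume$geometry, path,
                    datatype = "float")
}

#' @rdname read_volume
#' @param mask A [segmentation_mask()].
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "segmentation_mask"))
  write_nifti_array(aperm(mask$labels, c(3, 2, 1)), mask$geometry, path,
                    datatype = "uint8")
}

read_nifti_array <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected a 3D NIfTI volume")
  img
}

geometry_from_nifti <- function(img, slice_gap) {
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3 || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0)) {
    stop("NIfTI header lacks usable pixel spacing metadata")
  }
  thickness <- pd[3] - slice_gap
  if (thickness <= 0) {
    stop("slice pitch in header is not larger than the assumed slice gap")
  }
  d <- dim(img)  # (x = col, y = row, z = slice)
  voxel_geometry(
    row_spacing_mm = pd[2], col_spacing_mm = pd[1],
    slice_thickness_mm = thickness, slice_gap_mm = slice_gap,
    n_rows = d[2], n_cols = d[1], n_slices = d[3]
  )
}

write_nifti_array <- function(arr, geometry, path, datatype) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(geometry$col_spacing_mm, geometry$row_spacing_mm,
                           slice_pitch_mm(geometry))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

file_stem <- function(path) {
  sub("\\.nii(\\.gz)?$", "", basename(path))
}
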