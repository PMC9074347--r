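#' Voxel geometry of an axial slice stack
#'
#' Physical grid metadata that turns pixel counts into areas (cm^2) and
#' volumes (cm^3).  Axial knee MR protocols acquire slices with a finite
#' thickness plus an inter-slice gap; the effective per-slice extent used in
#' volumetry is the *slice pitch*, thickness + gap (4.0 + 0.4 = 4.4 mm in
#' the default protocol).
#'
#' @param row_spacing_mm,col_spacing_mm In-plane pixel spacing in mm.
#' @param slice_thickness_mm Acquired slice thickness in mm (default 4.0).
#' @param slice_gap_mm Inter-slice gap in mm (default 0.4).
#' @param n_rows,n_cols,n_slices Grid dimensions (slices are the first axis
#'   of the voxel array, ordered proximal to distal).
#'
#' @return An object of class `voxel_geometry`.
#' @examples
#' g <- voxel_geometry(0.3125, 0.3125, n_rows = 512, n_cols = 512, n_slices = 12)
#' slice_pitch_mm(g)  # 4.4
#' pixel_area_cm2(g)
#' @export
voxel_geometry <- function(row_spacing_mm, col_spacing_mm,
                           slice_thickness_mm = 4.0, slice_gap_mm = 0.4,
                           n_rows = 512L, n_cols = 512L, n_slices = 1L) {
  stopifnot(
    is.numeric(row_spacing_mm), row_spacing_mm > 0,
    is.numeric(col_spacing_mm), col_spacing_mm > 0,
    is.numeric(slice_thickness_mm), slice_thickness_mm > 0,
    is.numeric(slice_gap_mm), slice_gap_mm >= 0,
    n_rows >= 1, n_cols >= 1, n_slices >= 1
  )
  structure(
    list(
      row_spacing_mm = as.numeric(row_spacing_mm),
      col_spacing_mm = as.numeric(col_spacing_mm),
      slice_thickness_mm = as.numeric(slice_thickness_mm),
      slice_gap_mm = as.numeric(slice_gap_mm),
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      n_slices = as.integer(n_slices)
    ),
    class = "voxel_geometry"
  )
}

#' @export
print.voxel_geometry <- function(x, ...) {
  cat(sprintf(
    "<voxel_geometry> %d slices x %d x %d, %.4f x %.4f mm in-plane, pitch %.2f mm\n",
    x$n_slices, x$n_rows, x$n_cols, x$row_spacing_mm, x$col_spacing_mm,
    slice_pitch_mm(x)
  ))
  invisible(x)
}

#' Slice pitch (thickness + gap) in mm
#'
#' @param geometry A [voxel_geometry()].
#' @return Slice pitch in mm.
#' @export
slice_pitch_mm <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$slice_thickness_mm + geometry$slice_gap_mm
}

#' In-plane pixel area in cm^2
#'
#' 2D areas are measured by counting foreground pixels; each pixel
#' contributes `row_spacing_mm * col_spacing_mm / 100` cm^2.
#'
#' @param geometry A [voxel_geometry()].
#' @return Pixel area in cm^2.
#' @export
pixel_area_cm2 <- function(geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  geometry$row_spacing_mm * geometry$col_spacing_mm / 100
}

#' 3D image volume and binary segmentation mask containers
#'
#' `image_volume()` wraps a 3D intensity array; `segmentation_mask()` wraps a
#' 3D binary (0/1) array.  Both carry a [voxel_geometry()] and a subject id.
#' The voxel array is indexed `[slice, row, col]` with slices ordered
#' proximal to distal.
#'
#' @param voxels 3D numeric array, dim `(n_slices, n_rows, n_cols)`.
#' @param geometry A [voxel_geometry()] whose counts match `dim(voxels)`.
#' @param subject_id Subject identifier string.
#' @return An `image_volume` or `segmentation_mask` object.
#' @export
image_volume <- function(voxels, geometry, subject_id = "subject") {
  check_grid(voxels, geometry)
  if (!all(is.finite(voxels))) stop("image intensities must all be finite")
  structure(
    list(voxels = voxels, geometry = geometry,
         subject_id = as.character(subject_id)),
    class = "image_volume"
  )
}

#' @rdname image_volume
#' @param labels 3D array with values in \{0, 1\}.
#' @export
segmentation_mask <- function(labels, geometry, subject_id = "subject") {
  check_grid(labels, geometry)
  if (!all(labels %in% c(0, 1))) stop("mask labels must be 0 or 1")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, geometry = geometry,
         subject_id = as.character(subject_id)),
    class = "segmentation_mask"
  )
}

check_grid <- function(arr, geometry) {
  stopifnot(inherits(geometry, "voxel_geometry"))
  d <- dim(arr)
  if (is.null(d) || length(d) != 3) stop("voxel grid must be a 3D array")
  expected <- c(geometry$n_slices, geometry$n_rows, geometry$n_cols)
  if (!all(d == expected)) {
    stop(sprintf("grid shape (%s) does not match geometry (%s)",
                 paste(d, collapse = "x"), paste(expected, collapse = "x")))
  }
  invisible(TRUE)
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> subject %s, %d x %d x %d\n", x$subject_id,
              dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3]))
  invisible(x)
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> subject %s, %d x %d x %d, %d foreground voxels\n",
              x$subject_id, dim(x$labels)[1], dim(x$labels)[2],
              dim(x$labels)[3], sum(x$labels)))
  invisible(x)
}
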