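#' Area of one binary mask slice
#'
#' Foreground pixel count times the physical pixel area.
#'
#' @param mask_slice Binary matrix (values 0/1).
#' @param geometry A [voxel_geometry()].
#' @return Area in cm^2.
#' @examples
#' g <- voxel_geometry(1, 1, n_rows = 10, n_cols = 10)
#' slice_area(matrix(1, 10, 10), g)  # 1 cm^2
#' @export
slice_area <- function(mask_slice, geometry) {
  if (!all(mask_slice %in% c(0, 1))) {
    stop("slice_area expects a binary mask slice")
  }
  sum(mask_slice) * pixel_area_cm2(geometry)
}

#' Physical notch volume of a binary mask
#'
#' The measurement rule of slice-wise MR volumetry: per-slice ROI areas
#' `s_z` (pixel counting) summed and multiplied by the slice pitch `d`
#' (slice thickness + inter-slice gap, 4.0 + 0.4 = 4.4 mm under the default
#' protocol): `V = sum_z s_z * d`, reported in cm^3.  The pitch is applied
#' uniformly to every slice, which is the stated measurement convention
#' even though the gap is not physically part of any slice.
#'
#' @param mask A [segmentation_mask()], or a binary 3D array if `geometry`
#'   is supplied.
#' @param geometry A [voxel_geometry()] (only when `mask` is a bare array).
#' @return A `volume_measurement` object with fields `subject_id`,
#'   `per_slice_areas_cm2`, `volume_cm3`, `n_slices_with_roi`.
#' @examples
#' g <- voxel_geometry(0.3125, 0.3125, 4.0, 0.4, 16, 16, 3)
#' lab <- array(0L, c(3, 16, 16)); lab[, 1:10, 1:10] <- 1L
#' notch_volume(segmentation_mask(lab, g))$volume_cm3
#' @export
notch_volume <- function(mask, geometry = NULL) {
  if (inherits(mask, "segmentation_mask")) {
    labels <- mask$labels
    geometry <- mask$geometry
    subject_id <- mask$subject_id
  } else {
    stopifnot(!is.null(geometry))
    if (!all(mask %in% c(0, 1))) stop("mask must be binary")
    labels <- mask
    subject_id <- "subject"
  }
  areas <- apply(labels, 1, sum) * pixel_area_cm2(geometry)
  pitch_cm <- slice_pitch_mm(geometry) / 10
  structure(
    list(
      subject_id = subject_id,
      per_slice_areas_cm2 = as.numeric(areas),
      volume_cm3 = sum(areas) * pitch_cm,
      n_slices_with_roi = sum(areas > 0)
    ),
    class = "volume_measurement"
  )
}

#' @export
print.volume_measurement <- function(x, ...) {
  cat(sprintf("<volume_measurement> subject %s: %.3f cm^3 over %d ROI slices\n",
              x$subject_id, x$volume_cm3, x$n_slices_with_roi))
  invisible(x)
}

#' @method tidy volume_measurement
#' @export
tidy.volume_measurement <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, volume_cm3 = x$volume_cm3,
                 n_slices_with_roi = x$n_slices_with_roi)
}

#' Volume table for a set of masks
#'
#' @param masks A list of [segmentation_mask()] objects.
#' @return A tibble with columns `subject_id`, `n_slices_with_roi`,
#'   `volume_cm3`.
#' @export
volume_table <- function(masks) {
  rows <- lapply(masks, function(m) tidy(notch_volume(m)))
  dplyr::select(dplyr::bind_rows(rows), "subject_id", "n_slices_with_roi",
                "volume_cm3")
}

#' Relative volume error E = (R - P) / R
#'
#' Signed relative error of a predicted volume `P` against the real
#' (reference) volume `R`; negative when the prediction overshoots.
#' Cohort-level error is conventionally reported as the mean and SD of the
#' per-subject values.
#'
#' @param real_cm3 Reference volume(s), must be positive.
#' @param predicted_cm3 Predicted volume(s), same length.
#' @return Numeric vector of relative errors.
#' @examples
#' relative_error(10, 9)          # 0.1
#' relative_error(6.874, 6.576)   # ~0.0434
#' @export
relative_error <- function(real_cm3, predicted_cm3) {
  if (any(real_cm3 <= 0)) stop("real volume must be positive")
  if (length(real_cm3) != length(predicted_cm3)) {
    stop("real and predicted volumes must have equal length")
  }
  (real_cm3 - predicted_cm3) / real_cm3
}
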