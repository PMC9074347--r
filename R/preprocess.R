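#' Per-slice training sample
#'
#' The training unit for slice-wise segmentation: one axial image slice and
#' its aligned binary mask, tagged with the subject id and the slice index
#' within the stack.
#'
#' @param image_2d Numeric matrix of intensities.
#' @param mask_2d Binary matrix (0/1) of the same shape.
#' @param subject_id Subject identifier.
#' @param slice_index 1-based slice index within the parent stack.
#' @return A `slice_sample` object.
#' @export
slice_sample <- function(image_2d, mask_2d, subject_id = "subject",
                         slice_index = 1L) {
  stopifnot(is.matrix(image_2d), is.matrix(mask_2d),
            all(dim(image_2d) == dim(mask_2d)))
  if (!all(mask_2d %in% c(0, 1))) stop("mask values must be 0 or 1")
  structure(
    list(image_2d = image_2d, mask_2d = mask_2d,
         subject_id = as.character(subject_id),
         slice_index = as.integer(slice_index)),
    class = "slice_sample"
  )
}

#' Augmentation parameters
#'
#' Random augmentation applied on the fly to each training slice: rotation
#' uniform in +/- `max_rotation_deg` about the image centre, integer
#' translations uniform in +/- `max_shift_voxels` per in-plane axis, and a
#' horizontal flip with probability `horizontal_flip`.  Rotation is applied
#' first, then shift, then flip; the same transform is applied to the image
#' (bilinear) and the mask (nearest neighbour, re-binarized).
#'
#' @param max_rotation_deg Maximum absolute rotation in degrees (default 10).
#' @param max_shift_voxels Maximum absolute shift in voxels (default 20).
#' @param horizontal_flip Flip probability in `[0, 1]` (default 0.5).
#' @param seed Integer seed for the augmentation stream.
#' @return An `augmentation_spec` object.
#' @export
augmentation_spec <- function(max_rotation_deg = 10, max_shift_voxels = 20L,
                              horizontal_flip = 0.5, seed = 1L) {
  stopifnot(max_rotation_deg >= 0, max_shift_voxels >= 0,
            horizontal_flip >= 0, horizontal_flip <= 1)
  structure(
    list(max_rotation_deg = max_rotation_deg,
         max_shift_voxels = as.integer(max_shift_voxels),
         horizontal_flip = horizontal_flip, seed = as.integer(seed)),
    class = "augmentation_spec"
  )
}

#' Randomly augment a training slice
#'
#' Draws one transform from the spec (using the current RNG stream) and
#' applies it jointly to image and mask.  Out-of-frame regions are filled
#' with zero.
#'
#' @param sample A [slice_sample()].
#' @param spec An [augmentation_spec()].
#' @return The transformed [slice_sample()].
#' @export
augment <- function(sample, spec) {
  stopifnot(inherits(sample, "slice_sample"),
            inherits(spec, "augmentation_spec"))
  angle <- runif(1, -spec$max_rotation_deg, spec$max_rotation_deg)
  shifts <- if (spec$max_shift_voxels > 0) {
    sample.int(2L * spec$max_shift_voxels + 1L, 2, replace = TRUE) -
      spec$max_shift_voxels - 1L
  } else c(0L, 0L)
  flip <- runif(1) < spec$horizontal_flip
  img <- sample$image_2d
  msk <- sample$mask_2d
  if (angle != 0) {
    img <- rotate_matrix(img, angle, "bilinear")
    msk <- rotate_matrix(msk, angle, "nearest")
  }
  if (any(shifts != 0)) {
    img <- shift_matrix(img, shifts[1], shifts[2])
    msk <- shift_matrix(msk, shifts[1], shifts[2])
  }
  if (flip) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  slice_sample(img, (msk > 0.5) * 1, sample$subject_id, sample$slice_index)
}

# Rotate about the image centre; inverse mapping with bilinear or nearest
# interpolation, zero fill outside the frame.
rotate_matrix <- function(m, angle_deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(m); w <- ncol(m)
  th <- angle_deg * pi / 180
  ci <- (h + 1) / 2; cj <- (w + 1) / 2
  i <- matrix(seq_len(h), h, w) - ci
  j <- matrix(seq_len(w), h, w, byrow = TRUE) - cj
  # inverse rotation of output coordinates into the source frame
  si <- cos(th) * i + sin(th) * j + ci
  sj <- -sin(th) * i + cos(th) * j + cj
  interp_matrix(m, si, sj, method)
}

# Integer translation by (di, dj) with zero fill.
shift_matrix <- function(m, di, dj) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  src_i <- seq_len(h) - di
  src_j <- seq_len(w) - dj
  ok_i <- src_i >= 1 & src_i <= h
  ok_j <- src_j >= 1 & src_j <= w
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j], drop = FALSE]
  out
}

# Gather m at fractional coordinates (si, sj); zero outside.
interp_matrix <- function(m, si, sj, method) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, nrow(si), ncol(si))
  if (method == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= h & rj >= 1 & rj <= w
    out[ok] <- m[cbind(ri[ok], rj[ok])]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    ok <- i0 >= 1 & i0 + 1 <= h & j0 >= 1 & j0 + 1 <= w
    # interior bilinear blend; border pixels fall back to nearest
    out[ok] <- (1 - fi[ok]) * (1 - fj[ok]) * m[cbind(i0[ok], j0[ok])] +
      fi[ok] * (1 - fj[ok]) * m[cbind(i0[ok] + 1, j0[ok])] +
      (1 - fi[ok]) * fj[ok] * m[cbind(i0[ok], j0[ok] + 1)] +
      fi[ok] * fj[ok] * m[cbind(i0[ok] + 1, j0[ok] + 1)]
    edge <- !ok
    ri <- round(si); rj <- round(sj)
    edge <- edge & ri >= 1 & ri <= h & rj >= 1 & rj <= w
    out[edge] <- m[cbind(ri[edge], rj[edge])]
  }
  out
}

#' Resize a slice sample to a square target size
#'
#' The image is bilinearly resampled; the mask is resampled with nearest
#' neighbour and re-binarized at 0.5 so that it stays strictly binary for
#' pixel-count volumetry.
#'
#' @param sample A [slice_sample()].
#' @param target Target side length in pixels (>= 8).
#' @return The resized [slice_sample()].
#' @export
resize_to <- function(sample, target) {
  stopifnot(inherits(sample, "slice_sample"))
  if (target < 8) stop("target size must be at least 8")
  target <- as.integer(target)
  if (all(dim(sample$image_2d) == c(target, target))) return(sample)
  img <- resize_matrix(sample$image_2d, target, target, "bilinear")
  msk <- resize_matrix(sample$mask_2d, target, target, "nearest")
  slice_sample(img, (msk > 0.5) * 1, sample$subject_id, sample$slice_index)
}

resize_matrix <- function(m, h2, w2, method) {
  h <- nrow(m); w <- ncol(m)
  si <- (seq_len(h2) - 0.5) * h / h2 + 0.5  # centre-aligned source rows
  sj <- (seq_len(w2) - 0.5) * w / w2 + 0.5
  si <- pmin(pmax(si, 1), h)
  sj <- pmin(pmax(sj, 1), w)
  SI <- matrix(si, h2, w2)
  SJ <- matrix(sj, h2, w2, byrow = TRUE)
  interp_matrix(m, SI, SJ, method)
}

#' Match an image's histogram to a reference
#'
#' Monotone intensity remap sending the empirical distribution of `image_2d`
#' onto that of `reference_2d` (rank-based quantile mapping).  Matching an
#' image to itself is the identity up to quantization; constant inputs are
#' returned unchanged with a warning.
#'
#' @param image_2d Numeric matrix to remap.
#' @param reference_2d Numeric matrix supplying the target distribution.
#' @return The remapped matrix.
#' @export
histogram_match <- function(image_2d, reference_2d) {
  stopifnot(is.matrix(image_2d), is.matrix(reference_2d))
  if (diff(range(image_2d)) == 0 || diff(range(reference_2d)) == 0) {
    warning("constant input to histogram_match; returning input unchanged")
    return(image_2d)
  }
  r <- rank(image_2d, ties.method = "average")
  q <- (r - 1) / (length(image_2d) - 1)
  ref <- sort(as.numeric(reference_2d))
  probs <- seq(0, 1, length.out = length(ref))
  out <- approx(probs, ref, xout = q, rule = 2, ties = "ordered")$y
  matrix(out, nrow(image_2d), ncol(image_2d))
}

#' Rescale intensities to the unit interval
#'
#' `(x - min) / (max - min)`; a constant image yields all zeros with a
#' warning.  Idempotent on already-rescaled images.
#'
#' @param image_2d Numeric matrix.
#' @return Matrix with range exactly `[0, 1]`.
#' @export
rescale_unit <- function(image_2d) {
  stopifnot(all(is.finite(image_2d)))
  rng <- range(image_2d)
  if (diff(rng) == 0) {
    warning("constant image; rescale_unit returns all zeros")
    return(image_2d * 0)
  }
  (image_2d - rng[1]) / (rng[2] - rng[1])
}

#' Extract the slices that contain ROI
#'
#' Returns, in stack order, one [slice_sample()] per slice whose mask has at
#' least one foreground voxel — the slices actually used for training, so
#' that structure-free layers do not dilute the segmentation loss.
#'
#' @param volume An [image_volume()].
#' @param mask The aligned [segmentation_mask()].
#' @return A list of [slice_sample()] objects (possibly empty).
#' @export
extract_roi_slices <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(mask, "segmentation_mask"),
            all(dim(volume$voxels) == dim(mask$labels)))
  keep <- which(apply(mask$labels, 1, sum) > 0)
  lapply(keep, function(z) {
    slice_sample(volume$voxels[z, , ], mask$labels[z, , ],
                 volume$subject_id, z)
  })
}
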