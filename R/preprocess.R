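# Slice preprocessing: locate the patient center and replace the
# high-frequency structures (bone, gas pockets, fiducials) with water so
# they cannot perturb the low-frequency bias fit.  Only the estimation
# copy of the slice is ever filled; the corrected output is always the
# original image divided by the (smooth) bias field.

disk_offsets <- function(radius) {
  radius <- as.integer(radius)
  g <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

shift_mask <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  xs <- seq_len(nr) - dx
  ys <- seq_len(nc) - dy
  okx <- xs >= 1 & xs <= nr
  oky <- ys >= 1 & ys <= nc
  out[okx, oky] <- m[xs[okx], ys[oky]]
  out
}

binary_dilate <- function(m, radius) {
  if (radius < 1L) return(m)
  off <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out | shift_mask(m, off$dx[i], off$dy[i])
  out
}

binary_erode <- function(m, radius) {
  if (radius < 1L) return(m)
  off <- disk_offsets(radius)
  out <- matrix(TRUE, nrow(m), ncol(m))
  for (i in seq_len(nrow(off)))
    out <- out & shift_mask(m, off$dx[i], off$dy[i])
  out
}

binary_open <- function(m, radius) binary_dilate(binary_erode(m, radius), radius)

#' Estimate the in-plane processing center of a slice
#'
#' Returns the centroid of the largest connected component of
#' `{HU > body_threshold}` in continuous 0-based `(x, y)` voxel
#' coordinates.  The centroid is translation-equivariant and robust to
#' internal structure, making it a deterministic stand-in for the
#' (unspecified) centering step of the published workflow.
#'
#' @param slice_hu 2D numeric matrix in HU, indexed `[x, y]`.
#' @param body_threshold HU threshold defining the body.
#' @return numeric `(x, y)` center, or `NULL` if the slice contains no
#'   body voxel (an empty-slice signal; the pipeline skips such slices).
#' @export
estimate_center <- function(slice_hu, body_threshold = -300) {
  mask <- slice_hu > body_threshold
  if (!any(mask)) return(NULL)
  lab <- cpp_label_components(mask)
  counts <- tabulate(lab[lab > 0L])
  biggest <- which.max(counts)
  idx <- which(lab == biggest, arr.ind = TRUE)
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
}

#' Mask bone and gas structures in a slice
#'
#' Bone (and fiducial) voxels are `HU > bone_threshold`; gas/cavity voxels
#' lie in `gas_range` (inclusive).  Each mask undergoes a binary opening
#' (erosion then dilation, disk of `open_radius`) to remove speckle, then
#' a dilation by `dilate_radius` adding a safety margin over
#' partial-volume rims.  If the combined mask covers more than 90% of the
#' body support the slice carries no usable soft tissue and is flagged
#' `rejected` (the pipeline falls back to an identity bias there).
#'
#' @param slice_hu 2D numeric matrix in HU.
#' @param cfg a [correction_config()].
#' @return an object of class `structure_mask` with logical matrices
#'   `bone`, `gas`, `combined` and a `rejected` flag.
#' @export
mask_structures <- function(slice_hu, cfg = correction_config()) {
  bone <- slice_hu > cfg$bone_threshold
  gas <- slice_hu >= cfg$gas_range[1] & slice_hu <= cfg$gas_range[2]
  bone <- binary_dilate(binary_open(bone, cfg$open_radius), cfg$dilate_radius)
  gas <- binary_dilate(binary_open(gas, cfg$open_radius), cfg$dilate_radius)
  combined <- bone | gas
  body <- slice_hu > cfg$body_threshold
  rejected <- sum(body) > 0 && sum(combined & body) > 0.9 * sum(body)
  structure(list(bone = bone, gas = gas, combined = combined,
                 rejected = rejected),
            class = "structure_mask")
}

#' Fill masked structures with water
#'
#' Sets masked voxels to 0 HU (water) and leaves all others untouched.
#' Idempotent.  The filled slice is used only for bias estimation and
#' never becomes part of the corrected image.
#'
#' @param slice_hu 2D numeric matrix in HU.
#' @param mask a `structure_mask` (or a logical matrix).
#' @return the filled 2D matrix.
#' @export
fill_with_water <- function(slice_hu, mask) {
  m <- if (inherits(mask, "structure_mask")) mask$combined else mask
  if (!identical(dim(m), dim(slice_hu)))
    stop("mask and slice shapes differ", call. = FALSE)
  slice_hu[m] <- 0
  slice_hu
}
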