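#' CT volume container
#'
#' A `ct_volume` is a 3D voxel grid together with its value domain and
#' geometry.  Values are either CT numbers in Hounsfield units (`"HU"`,
#' water = 0, air = -1000) or relative attenuation (`"REL_MU"`,
#' `HU/1000 + 1`, water = 1, air = 0).  The array is indexed
#' `values[x, y, z]` with `z` the longitudinal (slice) axis, so
#' `values[, , k]` is the k-th transverse slice.
#'
#' On construction HU values are floored at -1000 (air) and REL_MU values
#' at 0: neither domain admits values below air.
#'
#' @param values numeric 3D array, `x` by `y` by `z`.
#' @param unit `"HU"` or `"REL_MU"`.
#' @param spacing numeric length-3 voxel size in mm, all positive.
#' @param center_xy optional per-slice in-plane processing center: an
#'   `n_z` by 2 matrix of continuous 0-based `(x, y)` voxel coordinates.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(values, unit = c("HU", "REL_MU"), spacing = c(1, 1, 1),
                      center_xy = NULL) {
  unit <- match.arg(unit)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  d <- dim(values)
  if (d[1] < 8L || d[2] < 8L)
    stop("in-plane dimensions must be >= 8 voxels", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  if (!is.null(center_xy)) {
    center_xy <- as.matrix(center_xy)
    if (nrow(center_xy) != d[3] || ncol(center_xy) != 2L)
      stop("`center_xy` must be an n_z x 2 matrix", call. = FALSE)
  }
  storage.mode(values) <- "double"
  floor_val <- if (unit == "HU") -1000 else 0
  if (any(values < floor_val)) values[values < floor_val] <- floor_val
  structure(list(values = values, unit = unit, spacing = spacing,
                 center_xy = center_xy),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, unit %s, spacing %s mm\n",
              d[1], d[2], d[3], x$unit,
              paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  value range [%.1f, %.1f]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

stop_unit <- function(volume, expected) {
  if (!inherits(volume, "ct_volume"))
    stop("expected a `ct_volume`", call. = FALSE)
  if (volume$unit != expected)
    stop(sprintf("volume must be in %s (got %s)", expected, volume$unit),
         call. = FALSE)
}

#' Convert a volume from Hounsfield units to relative attenuation
#'
#' Applies `mu_rel = HU/1000 + 1` (water maps to exactly 1, air to 0) and
#' clamps at 0 from below.  This is the domain in which the multiplicative
#' bias-field division is well posed: a dimensionless field multiplying
#' values that are ~1 in soft tissue.
#'
#' @param volume a `ct_volume` in HU.
#' @return a `ct_volume` in REL_MU with identical geometry.
#' @seealso [rel_mu_to_hu()] for the inverse (the final HU calibration).
#' @export
hu_to_rel_mu <- function(volume) {
  stop_unit(volume, "HU")
  v <- volume$values / 1000 + 1
  v[v < 0] <- 0
  volume$values <- v
  volume$unit <- "REL_MU"
  volume
}

#' Convert a volume from relative attenuation back to Hounsfield units
#'
#' Applies `HU = 1000 * (mu_rel - 1)`, the exact inverse of
#' [hu_to_rel_mu()] on the non-clamped range.  This is the water
#' calibration step closing the correction pipeline.
#'
#' @param volume a `ct_volume` in REL_MU.
#' @return a `ct_volume` in HU with identical geometry.
#' @export
rel_mu_to_hu <- function(volume) {
  stop_unit(volume, "REL_MU")
  volume$values <- 1000 * (volume$values - 1)
  volume$unit <- "HU"
  volume
}

#' Axis-aligned region of interest
#'
#' ROI boxes use 0-based half-open voxel index ranges: voxel `(i, j, k)` is
#' inside when `lo <= (i, j, k) < hi` component-wise.  This matches the
#' on-disk ROI file format (see [read_roi_file()]).
#'
#' @param label character label.
#' @param lo,hi integer length-3 corners, `lo < hi` component-wise.
#' @return an object of class `roi_box`.
#' @export
roi_box <- function(label, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(is.na(c(lo, hi))))
    stop("`lo` and `hi` must be integer triples", call. = FALSE)
  if (any(lo < 0L) || any(lo >= hi))
    stop("need 0 <= lo < hi component-wise", call. = FALSE)
  structure(list(label = as.character(label), lo = lo, hi = hi),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> %s: [%s) - [%s)\n", x$label,
              paste(x$lo, collapse = ","), paste(x$hi, collapse = ",")))
  invisible(x)
}

#' Extract the voxel values inside an ROI box
#'
#' @param volume a `ct_volume`.
#' @param roi a `roi_box`; must lie inside the volume.
#' @return numeric vector of voxel values.
#' @export
roi_values <- function(volume, roi) {
  if (!inherits(roi, "roi_box")) stop("expected a `roi_box`", call. = FALSE)
  d <- dim(volume$values)
  if (any(roi$hi > d))
    stop(sprintf("ROI '%s' extends outside the volume", roi$label),
         call. = FALSE)
  volume$values[(roi$lo[1] + 1):roi$hi[1],
                (roi$lo[2] + 1):roi$hi[2],
                (roi$lo[3] + 1):roi$hi[3]]
}
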