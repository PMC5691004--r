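# Polar-coordinate resampling.  Shading artifacts in circular-scan CBCT
# are predominantly radial, so each transverse slice is rebinned onto an
# (r, theta) grid about the patient center before the directional median
# filtering.  Conventions: theta = 0 along +x (first array index
# increasing), counter-clockwise, in degrees; angular bin centers sit at
# (j + 0.5) * angular_step; radial bin i sits at r = i * radial_step
# voxels from the center, with the step chosen so the outermost bin
# reaches the farthest slice corner.

#' Resample a transverse slice onto a polar grid
#'
#' Values are interpolated with cubic convolution (a C1 spline-class
#' kernel that reproduces cubics exactly); samples falling outside the
#' Cartesian grid take the air value for the slice's unit and are flagged
#' invalid.
#'
#' @param slice 2D numeric matrix indexed `[x, y]`.
#' @param center_xy continuous 0-based `(x, y)` center; must lie inside
#'   the slice.
#' @param n_radial,n_angular polar grid size.
#' @param unit `"HU"` or `"REL_MU"`; sets the air fill value (-1000 or 0).
#' @return an object of class `polar_slice`: `values` and `valid`
#'   (`n_radial` x `n_angular` matrices), `center_xy`, `radial_step`
#'   (voxels per bin), `angular_step` (degrees per bin), `unit`.
#' @export
to_polar <- function(slice, center_xy, n_radial = 600L, n_angular = 360L,
                     unit = c("HU", "REL_MU")) {
  unit <- match.arg(unit)
  d <- dim(slice)
  if (center_xy[1] < 0 || center_xy[1] > d[1] - 1 ||
      center_xy[2] < 0 || center_xy[2] > d[2] - 1)
    stop("center_xy lies outside the slice", call. = FALSE)
  # cover the largest center-to-corner distance
  corners_x <- c(0, d[1] - 1)
  corners_y <- c(0, d[2] - 1)
  half_diag <- max(sqrt(outer((corners_x - center_xy[1])^2,
                              (corners_y - center_xy[2])^2, "+")))
  radial_step <- half_diag / (n_radial - 1)
  angular_step <- 360 / n_angular
  r <- (seq_len(n_radial) - 1) * radial_step
  theta <- ((seq_len(n_angular) - 1) + 0.5) * angular_step * pi / 180
  xs <- center_xy[1] + outer(r, cos(theta))
  ys <- center_xy[2] + outer(r, sin(theta))
  fill <- if (unit == "HU") -1000 else 0
  res <- cpp_bicubic_sample(slice, as.vector(xs), as.vector(ys), fill)
  structure(list(values = matrix(res$values, n_radial, n_angular),
                 valid = matrix(res$inside, n_radial, n_angular),
                 center_xy = as.numeric(center_xy),
                 radial_step = radial_step,
                 angular_step = angular_step,
                 unit = unit),
            class = "polar_slice")
}

#' @export
print.polar_slice <- function(x, ...) {
  cat(sprintf(
    "<polar_slice> %d radial x %d angular bins, step %.3f vox / %.2f deg, unit %s\n",
    nrow(x$values), ncol(x$values), x$radial_step, x$angular_step, x$unit))
  invisible(x)
}

#' Resample a polar grid back onto a Cartesian slice
#'
#' The inverse of [to_polar()] on the same center and bin steps.  The
#' angular axis is treated as periodic; radially, Cartesian points beyond
#' the outermost bin (or inside the first) receive the nearest bin's
#' value (constant extrapolation), so a bias field defined on the polar
#' grid exists everywhere the division needs it.
#'
#' @param polar a `polar_slice` (its `values` may have been replaced by a
#'   derived field on the same grid).
#' @param out_shape integer `(nx, ny)` of the output slice.
#' @return 2D numeric matrix.
#' @export
from_polar <- function(polar, out_shape) {
  nx <- out_shape[1]; ny <- out_shape[2]
  x <- (seq_len(nx) - 1) - polar$center_xy[1]
  y <- (seq_len(ny) - 1) - polar$center_xy[2]
  xm <- matrix(x, nx, ny)
  ym <- matrix(y, nx, ny, byrow = TRUE)
  r <- sqrt(xm^2 + ym^2)
  theta <- atan2(ym, xm) * 180 / pi
  rad_bin <- r / polar$radial_step
  ang_bin <- theta / polar$angular_step - 0.5
  v <- cpp_polar_sample(polar$values, as.vector(rad_bin), as.vector(ang_bin))
  matrix(v, nx, ny)
}

#' Detect the patient boundary angle by angle
#'
#' For each angular bin the boundary is the radial bin maximizing the
#' magnitude of the outward radial finite difference, searched beyond
#' `min_radius` bins (the center is excluded because gradients there are
#' dominated by sampling noise).  All bins strictly beyond the boundary
#' are air and are marked invalid.  An angle whose strongest gradient
#' stays below `gradient_floor` (in HU per voxel, so the test is
#' independent of how finely the radial axis is binned) contains no
#' body/air edge and is invalidated entirely.
#'
#' In addition to the strictly-outside bins, a safety margin of
#' `margin_vox` Cartesian voxels just inside the boundary is invalidated:
#' interpolation spreads the body/air edge over about two voxels, and
#' those partial-volume bins would otherwise drag the polynomial fits
#' (the fits extrapolate across them, so the bias still covers them).
#'
#' @param polar a `polar_slice` in HU (the gradient floor is an HU scale).
#' @param min_radius minimum radial bin for the gradient search.
#' @param gradient_floor minimum |HU difference| per voxel.
#' @param margin_vox partial-volume margin in voxels, invalidated inside
#'   the boundary.
#' @return the input `polar_slice` with an added integer vector
#'   `boundary` (0-based radial bin per angle, 0 = all air) and its
#'   `valid` mask updated.
#' @export
detect_air_boundary <- function(polar, min_radius = 5L,
                                gradient_floor = 100, margin_vox = 2) {
  if (polar$unit != "HU")
    stop("air-boundary detection runs on the HU-domain polar slice",
         call. = FALSE)
  v <- polar$values
  nr <- nrow(v); na <- ncol(v)
  # outward finite difference in HU per voxel (bin-width independent)
  dv <- abs(v[-1, , drop = FALSE] - v[-nr, , drop = FALSE]) /
    polar$radial_step
  if (min_radius > 0) dv[seq_len(min(min_radius, nr - 1)), ] <- 0
  margin_bins <- as.integer(ceiling(margin_vox / polar$radial_step))
  boundary <- integer(na)
  for (a in seq_len(na)) {
    best <- which.max(dv[, a])
    if (dv[best, a] < gradient_floor) {
      boundary[a] <- 0L
      polar$valid[, a] <- FALSE
    } else {
      # dv row i is the edge between 0-based bins i-1 and i; the last
      # body bin is i-1, everything beyond it is air
      boundary[a] <- best - 1L
      first_bad <- max(1L, best + 1L - margin_bins)
      polar$valid[first_bad:nr, a] <- FALSE
    }
  }
  polar$boundary <- boundary
  polar
}

# Affine HU -> REL_MU on a polar slice (interpolation commutes with the
# affine map, so converting after resampling is exact).
polar_to_rel_mu <- function(polar) {
  stopifnot(polar$unit == "HU")
  v <- polar$values / 1000 + 1
  v[v < 0] <- 0
  polar$values <- v
  polar$unit <- "REL_MU"
  polar
}
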