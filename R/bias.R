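# Bias-field estimation: the heart of the correction.  Per slice, in
# polar space: (pass 1) a wide circular median along the angular axis
# followed by an order-8 polynomial fit of each angle's radial profile;
# (pass 2) a radial median (width 1 by default, i.e. none) followed by an
# order-3 polynomial fit along the radius.  The wide angular median
# supplies the angular smoothing; the fits supply the radial smoothing
# and extrapolate the field across masked and air bins.  The per-slice
# fields are mapped back to Cartesian space, stacked, and 3D
# median-filtered.

#' Bias field container
#'
#' A strictly positive, dimensionless multiplicative 3D field on the same
#' grid as the volume it corrects.
#'
#' @param values numeric 3D array, all values > 0.
#' @param provenance `"PRECORRECTION"`, `"MAIN"`, `"COMBINED"` (pipeline
#'   stages) or `"TRUTH"` (simulator ground truth).
#' @return an object of class `bias_field`.
#' @export
bias_field <- function(values, provenance = c("MAIN", "PRECORRECTION",
                                              "COMBINED", "TRUTH")) {
  provenance <- match.arg(provenance)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(values <= 0))
    stop("bias field must be strictly positive", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, provenance = provenance),
            class = "bias_field")
}

#' @export
print.bias_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bias_field> %d x %d x %d, provenance %s, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], x$provenance, min(x$values), max(x$values)))
  invisible(x)
}

#' Circular median filter along the angular axis
#'
#' For every polar bin, the median of the valid values within
#' `width_deg / 2` degrees on either side (circularly).  Invalid bins are
#' excluded from the window; a bin whose window holds no valid value is
#' itself marked invalid.  A window covering the full circle uses each
#' angular bin exactly once.
#'
#' @param polar a `polar_slice`.
#' @param width_deg window width in degrees, in `[1, 360]`.
#' @return a `polar_slice` with filtered `values` and updated `valid`.
#' @export
angular_median <- function(polar, width_deg = 80) {
  if (width_deg < 1 || width_deg > 360)
    stop("width_deg must be in [1, 360]", call. = FALSE)
  width_bins <- max(1L, as.integer(round(width_deg / polar$angular_step)))
  res <- cpp_angular_median(polar$values, polar$valid, width_bins)
  polar$values <- res$values
  polar$valid <- res$valid
  polar
}

#' Least-squares 1D polynomial fit with a validity mask
#'
#' Fits a polynomial of the given order to the valid samples of a
#' profile, with the abscissa rescaled to `[-1, 1]` over the full profile
#' length for conditioning, and evaluates it at every position (masked
#' positions receive the extrapolated value).
#'
#' @param profile numeric vector.
#' @param valid logical vector; positions used in the fit.
#' @param order polynomial order, >= 0; a fit needs more than `order`
#'   valid points.
#' @return list with `fitted` (numeric vector, full length) and
#'   `degenerate` (TRUE when too few valid points or a rank-deficient
#'   system forced the fallback: the constant median of the valid values,
#'   or NA if none).
#' @export
fit_polynomial_1d <- function(profile, valid = NULL, order = 3L) {
  n <- length(profile)
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- valid & is.finite(profile)
  x <- if (n > 1) seq(-1, 1, length.out = n) else 0
  nv <- sum(valid)
  fallback <- function() {
    fit <- if (nv > 0) rep(stats::median(profile[valid]), n) else
      rep(NA_real_, n)
    list(fitted = fit, degenerate = TRUE)
  }
  if (nv <= order) return(fallback())
  V <- outer(x, 0:order, "^")
  fit <- stats::.lm.fit(V[valid, , drop = FALSE], profile[valid])
  if (any(is.na(fit$coefficients)) || fit$rank < order + 1L)
    return(fallback())
  coef <- fit$coefficients
  # .lm.fit may pivot columns; un-pivot
  coef[fit$pivot] <- fit$coefficients
  list(fitted = as.vector(V %*% coef), degenerate = FALSE)
}

#' Estimate the bias field of one slice in polar space
#'
#' Implements the two directional low-pass passes on a water-filled,
#' air-flagged polar slice in the relative-attenuation domain; see the
#' package vignette for the full construction.  The output grid is fully
#' populated (fits extrapolate over masked/air bins) and clamped to
#' `[clamp_lo, clamp_hi]`.
#'
#' @param polar a `polar_slice` with `unit == "REL_MU"`, structures
#'   filled and air flagged.
#' @param cfg a [correction_config()].
#' @return list with `bias` (n_radial x n_angular matrix, strictly
#'   positive), `n_degenerate` (count of per-line fit fallbacks) and
#'   `empty` (TRUE when no angle had valid data; `bias` is then all 1).
#' @export
estimate_slice_bias <- function(polar, cfg = correction_config()) {
  if (polar$unit != "REL_MU")
    stop("bias estimation runs in the REL_MU domain", call. = FALSE)
  nr <- nrow(polar$values); na <- ncol(polar$values)
  if (!any(polar$valid))
    return(list(bias = matrix(1, nr, na), n_degenerate = 0L, empty = TRUE))
  am <- angular_median(polar, cfg$angular_width_deg)
  n_degenerate <- 0L
  initial <- matrix(NA_real_, nr, na)
  if (cfg$angular_fit_axis == "radial") {
    for (a in seq_len(na)) {
      f <- fit_polynomial_1d(am$values[, a], am$valid[, a], cfg$order_angular)
      if (f$degenerate) n_degenerate <- n_degenerate + 1L
      initial[, a] <- f$fitted
    }
  } else {
    # alternative reading: the order-8 fit runs along the angular axis
    for (r in seq_len(nr)) {
      f <- fit_polynomial_1d(am$values[r, ], am$valid[r, ], cfg$order_angular)
      if (f$degenerate) n_degenerate <- n_degenerate + 1L
      initial[r, ] <- f$fitted
    }
  }
  # second pass: radial median (width 1 = identity) + order-3 radial fit
  fit_valid <- am$valid & is.finite(initial)
  rm_ <- cpp_radial_median(initial, fit_valid, cfg$radial_width_bins)
  bias <- matrix(NA_real_, nr, na)
  for (a in seq_len(na)) {
    f <- fit_polynomial_1d(rm_$values[, a], rm_$valid[, a], cfg$order_radial)
    if (f$degenerate) n_degenerate <- n_degenerate + 1L
    bias[, a] <- f$fitted
  }
  bias[!is.finite(bias)] <- 1
  bias <- pmin(pmax(bias, cfg$clamp_lo), cfg$clamp_hi)
  list(bias = matrix(bias, nr, na), n_degenerate = n_degenerate,
       empty = FALSE)
}

#' Precorrect globally radial (ring) shading
#'
#' First-pass removal of the largely uniform ring shading typical of
#' half-fan/bowtie acquisitions.  Per slice, a single full-circle radial
#' median profile is computed; the ring transition is located as the
#' contiguous radial band around the maximum-magnitude derivative of that
#' profile (where the derivative exceeds `transition_deriv_factor` times
#' its median absolute value); the precorrection bias is the profile's
#' inner mean inside the band, its outer mean beyond it, and the profile
#' itself across the band, normalized so the inner level is 1
#' (precorrection fixes relative shading only).  Slices with no
#' detectable transition get an identity precorrection.
#'
#' @param volume a [ct_volume()] in REL_MU.
#' @param cfg a [correction_config()].
#' @return list with `volume` (precorrected, REL_MU) and `bias` (a
#'   `bias_field` with provenance `"PRECORRECTION"`).
#' @export
precorrect_global_radial <- function(volume, cfg = correction_config()) {
  stop_unit(volume, "REL_MU")
  d <- dim(volume$values)
  bias <- array(1, dim = d)
  out <- volume$values
  for (k in seq_len(d[3])) {
    rel_slice <- volume$values[, , k]
    hu_slice <- 1000 * (rel_slice - 1)
    center <- estimate_center(hu_slice, cfg$body_threshold)
    if (is.null(center)) next
    center <- center + cfg$center_offset
    mask <- mask_structures(hu_slice, cfg)
    if (mask$rejected) next
    filled <- fill_with_water(hu_slice, mask)
    polar <- to_polar(filled, center, cfg$n_radial, cfg$n_angular,
                      unit = "HU")
    polar <- detect_air_boundary(polar, cfg$min_boundary_radius,
                                 cfg$boundary_gradient_floor)
    polar <- polar_to_rel_mu(polar)
    prof_res <- radial_median_profile(polar)
    prof <- prof_res$profile
    pvalid <- prof_res$valid
    # derivative window of ~4 voxels: wide enough that the interpolation
    # noise of neighbouring (sub-voxel) radial bins averages out, narrow
    # against any plausible ring transition
    smooth_bins <- max(1L, as.integer(round(4 / polar$radial_step)))
    band <- find_transition_band(prof, pvalid, cfg$transition_deriv_factor,
                                 smooth_bins)
    if (is.null(band)) next
    inner_idx <- which(pvalid & seq_along(prof) < band[1])
    outer_idx <- which(pvalid & seq_along(prof) > band[2])
    if (length(inner_idx) == 0 || length(outer_idx) == 0) next
    bias_r <- rep(NA_real_, length(prof))
    bias_r[inner_idx] <- mean(prof[inner_idx])
    bias_r[outer_idx] <- mean(prof[outer_idx])
    bias_r[band[1]:band[2]] <- prof[band[1]:band[2]]
    bias_r <- bias_r / mean(prof[inner_idx])   # inner level := 1
    # radially symmetric field: evaluate at each pixel's radius
    known <- which(is.finite(bias_r))
    r_known <- (known - 1) * polar$radial_step
    x <- (seq_len(d[1]) - 1) - center[1]
    y <- (seq_len(d[2]) - 1) - center[2]
    r_pix <- sqrt(outer(x^2, y^2, "+"))
    b <- stats::approx(r_known, bias_r[known], xout = as.vector(r_pix),
                       rule = 2)$y
    b <- pmin(pmax(b, cfg$clamp_lo), cfg$clamp_hi)
    bias[, , k] <- matrix(b, d[1], d[2])
    out[, , k] <- rel_slice / bias[, , k]
  }
  list(volume = ct_volume(out, unit = "REL_MU", spacing = volume$spacing,
                          center_xy = volume$center_xy),
       bias = bias_field(bias, provenance = "PRECORRECTION"))
}

# full-circle (360 degree) radial median profile of a polar slice
radial_median_profile <- function(polar) {
  res <- cpp_angular_median(polar$values, polar$valid,
                            ncol(polar$values) + 1L)
  list(profile = res$values[, 1], valid = res$valid[, 1])
}

# Contiguous radial interval around the maximum-magnitude radial
# derivative of the profile, where |derivative| exceeds
# factor * median(|derivative|).  The derivative is taken over a window
# of `smooth_bins` bins (about two voxels): the radial axis oversamples
# the image, so a single-bin difference is dominated by interpolation
# noise while the ring transition is a many-bin feature.  Returns
# c(start, end) 1-based profile indices, or NULL when no derivative
# stands out (constant or featureless profile).
find_transition_band <- function(profile, valid, factor = 5,
                                 smooth_bins = 1L) {
  idx <- which(valid & is.finite(profile))
  if (length(idx) < 4) return(NULL)
  # restrict to the contiguous valid body range
  lo <- min(idx); hi <- max(idx)
  p <- profile[lo:hi]
  w <- max(1L, min(as.integer(smooth_bins), length(p) - 1L))
  np <- length(p)
  # centered difference over w bins, one value per interior edge
  dp <- abs(p[(1 + w):np] - p[1:(np - w)]) / w
  mad0 <- stats::median(dp)
  thr <- factor * mad0
  if (!is.finite(thr) || max(dp) <= thr || max(dp) == 0) return(NULL)
  best <- which.max(dp)
  above <- dp > thr
  s <- best
  while (s > 1 && above[s - 1]) s <- s - 1
  e <- best
  while (e < length(dp) && above[e + 1]) e <- e + 1
  # windowed derivative i spans profile indices i .. i+w
  c(lo + s - 1, min(hi, lo + e - 1 + w))
}

#' 3D median filtering of an assembled bias stack
#'
#' Removes residual high-frequency components (including slice-to-slice
#' outliers) from the stacked per-slice bias fields.  Edges are handled
#' by replication; the result is clamped to `[clamp_lo, clamp_hi]`.
#'
#' @param bias_stack numeric 3D array.
#' @param kernel odd per-axis kernel sizes, default `c(3, 3, 3)`.
#' @param clamp_lo,clamp_hi positivity clamps.
#' @return a `bias_field` with provenance `"MAIN"`.
#' @export
smooth_bias_3d <- function(bias_stack, kernel = c(3L, 3L, 3L),
                           clamp_lo = 0.2, clamp_hi = 5.0) {
  kernel <- as.integer(kernel)
  if (any(kernel %% 2L != 1L)) stop("kernel sizes must be odd", call. = FALSE)
  d <- dim(bias_stack)
  v <- cpp_median3d(as.vector(bias_stack), d, kernel[1], kernel[2], kernel[3])
  v <- pmin(pmax(v, clamp_lo), clamp_hi)
  bias_field(array(v, dim = d), provenance = "MAIN")
}
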