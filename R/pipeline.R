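# End-to-end correction: (1) preprocess each slice, (2) polar transform,
# (3) directional median + polynomial bias estimation, (4) back to
# Cartesian, (5) 3D median of the stacked bias, (6) division and HU
# recalibration -- optionally preceded by the global-ring precorrection
# round.  Everything is deterministic.

# mean over f x f blocks (edge blocks may be smaller)
block_mean <- function(m, f) {
  if (f <= 1L) return(m)
  ri <- ceiling(seq_len(nrow(m)) / f)
  ci <- ceiling(seq_len(ncol(m)) / f)
  sums <- t(rowsum(t(rowsum(m, ri, reorder = TRUE)), ci, reorder = TRUE))
  counts <- outer(tabulate(ri), tabulate(ci))
  sums / counts
}

# coarse-grid 0-based coordinate of a fine-grid 0-based coordinate
to_coarse <- function(x, f) (x + 0.5) / f - 0.5

# upsample a coarse slice to fine shape by cubic interpolation with
# edge clamping
upsample_slice <- function(coarse, fine_shape, f) {
  if (f <= 1L) return(coarse)
  xs <- to_coarse((seq_len(fine_shape[1]) - 1), f)
  ys <- to_coarse((seq_len(fine_shape[2]) - 1), f)
  xs <- pmin(pmax(xs, 0), nrow(coarse) - 1)
  ys <- pmin(pmax(ys, 0), ncol(coarse) - 1)
  xm <- matrix(xs, fine_shape[1], fine_shape[2])
  ym <- matrix(ys, fine_shape[1], fine_shape[2], byrow = TRUE)
  res <- cpp_bicubic_sample(coarse, as.vector(xm), as.vector(ym), 1)
  matrix(res$values, fine_shape[1], fine_shape[2])
}

#' Correct the shading of a CBCT volume
#'
#' Runs the full image-domain shading correction on an HU volume:
#' optional global-ring precorrection, then per slice centering,
#' bone/gas masking and water fill, polar resampling, air flagging,
#' angular-median + polynomial bias estimation, Cartesian mapping, 3D
#' median filtering of the bias stack, water-anchored normalization,
#' division in the relative-attenuation domain, and HU recalibration.
#' Degenerate slices (no body, or masks covering the body) fall back to
#' an identity bias and are noted in the log; they never abort the run.
#'
#' @param volume a [ct_volume()] in HU.
#' @param cfg a [correction_config()].
#' @return an object of class `correction_result`: `corrected` (HU
#'   [ct_volume()]), `bias` (`bias_field`, provenance `"COMBINED"`),
#'   `bias_pre` and `bias_main` (the two factors), and `per_slice_log`
#'   (data frame with one row per slice: center, boundary range,
#'   fallbacks triggered).
#' @export
correct_volume <- function(volume, cfg = correction_config()) {
  stop_unit(volume, "HU")
  d <- dim(volume$values)
  if (!any(volume$values > cfg$body_threshold))
    stop("volume contains no body voxels above the body threshold",
         call. = FALSE)
  rel0 <- hu_to_rel_mu(volume)

  if (cfg$precorrection) {
    pre <- precorrect_global_radial(rel0, cfg)
    rel_work <- pre$volume
    bias_pre <- pre$bias
  } else {
    rel_work <- rel0
    bias_pre <- bias_field(array(1, dim = d), provenance = "PRECORRECTION")
  }

  f <- cfg$downsample_factor
  bias_stack <- array(1, dim = d)
  soft_sel <- array(FALSE, dim = d)
  log_rows <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    rel_slice <- rel_work$values[, , k]
    hu_slice <- 1000 * (rel_slice - 1)
    fallback <- ""
    center <- estimate_center(hu_slice, cfg$body_threshold)
    boundary_rng <- c(NA_integer_, NA_integer_)
    if (is.null(center)) {
      fallback <- "empty_slice"
      center <- c(NA_real_, NA_real_)
    } else {
      center <- center + cfg$center_offset
      mask <- mask_structures(hu_slice, cfg)
      if (mask$rejected) {
        fallback <- "mask_covers_body"
      } else {
        filled <- fill_with_water(hu_slice, mask)
        soft_sel[, , k] <- hu_slice > cfg$body_threshold & !mask$combined
        work <- if (f > 1L) block_mean(filled, f) else filled
        center_ds <- to_coarse(center, f)
        polar <- to_polar(work, center_ds, cfg$n_radial, cfg$n_angular,
                          unit = "HU")
        polar <- detect_air_boundary(polar, cfg$min_boundary_radius,
                                     cfg$boundary_gradient_floor)
        boundary_rng <- range(polar$boundary)
        polar <- polar_to_rel_mu(polar)
        est <- estimate_slice_bias(polar, cfg)
        if (est$empty) {
          fallback <- "no_valid_angle"
        } else {
          polar$values <- est$bias
          bias_ds <- from_polar(polar, dim(work))
          bias_stack[, , k] <- upsample_slice(bias_ds, d[1:2], f)
          if (est$n_degenerate > 0)
            fallback <- sprintf("degenerate_fits:%d", est$n_degenerate)
        }
      }
    }
    log_rows[[k]] <- data.frame(slice = k, center_x = center[1],
                                center_y = center[2],
                                boundary_min = boundary_rng[1],
                                boundary_max = boundary_rng[2],
                                fallback = fallback,
                                stringsAsFactors = FALSE)
  }
  bias_main <- smooth_bias_3d(bias_stack, cfg$median3d_kernel,
                              cfg$clamp_lo, cfg$clamp_hi)
  # water anchoring: scale the bias so that dividing leaves the median
  # unmasked soft-tissue voxel at the image's own soft-tissue level
  if (any(soft_sel)) {
    scale <- stats::median(rel_work$values[soft_sel]) /
      stats::median(bias_main$values[soft_sel])
    bias_main$values <- bias_main$values * scale
  }
  corrected_rel <- rel_work$values / bias_main$values
  corrected <- rel_mu_to_hu(
    ct_volume(corrected_rel, unit = "REL_MU", spacing = volume$spacing))
  combined <- bias_field(bias_pre$values * bias_main$values,
                         provenance = "COMBINED")
  structure(list(corrected = corrected,
                 bias = combined,
                 bias_pre = bias_pre,
                 bias_main = bias_main,
                 per_slice_log = do.call(rbind, log_rows)),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  d <- dim(x$corrected$values)
  nfb <- sum(nzchar(x$per_slice_log$fallback))
  cat(sprintf("<correction_result> %d x %d x %d volume, %d/%d slice fallbacks\n",
              d[1], d[2], d[3], nfb, nrow(x$per_slice_log)))
  cat(sprintf("  combined bias range [%.3f, %.3f]\n",
              min(x$bias$values), max(x$bias$values)))
  invisible(x)
}
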