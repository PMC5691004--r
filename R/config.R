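#' Correction configuration
#'
#' Collects every tunable of the shading-correction pipeline.  Defaults
#' follow the published operating point for a pelvis-like acquisition: a
#' 600 x 360 polar grid, an 80-degree angular median width (use 40 for
#' head-like cases), a radial median width of 1 bin, and polynomial orders
#' 8 (first, angular-direction pass) and 3 (second, radial pass).  HU
#' thresholds: bone > 100 HU, gas in \[-750, -500\] HU, body > -300 HU.
#'
#' @param bone_threshold HU above which voxels are masked as bone (and
#'   fiducial inserts).
#' @param gas_range inclusive HU interval masked as gas/cavity.
#' @param body_threshold HU above which a voxel counts as patient body,
#'   used for centering and for the bias normalization support.
#' @param n_radial,n_angular polar grid size (radial bins x angular bins).
#' @param angular_width_deg width in degrees of the circular angular
#'   median window.
#' @param radial_width_bins width in bins of the radial median window of
#'   the second pass (1 = no radial median).
#' @param order_angular,order_radial polynomial orders of the first and
#'   second fitting passes.
#' @param median3d_kernel odd per-axis sizes of the 3D median filter
#'   applied to the assembled bias stack.
#' @param precorrection logical; run the global-ring precorrection round
#'   first (recommended for half-fan/bowtie acquisitions).
#' @param clamp_lo,clamp_hi hard limits on the estimated bias field.
#' @param open_radius disk radius (voxels) of the binary opening applied
#'   to structure masks.
#' @param dilate_radius disk radius (voxels) of the safety-margin dilation
#'   applied after opening.
#' @param downsample_factor integer in-plane downsampling factor used for
#'   bias estimation only (the bias is low-frequency, so it can be
#'   estimated on a coarser grid and upsampled).
#' @param center_offset in-plane offset (voxels) added to the detected
#'   slice center; a small non-zero offset mitigates artifacts from ring
#'   structures exactly concentric with the processing origin.
#' @param angular_fit_axis `"radial"` (default) fits the first-pass
#'   order-8 polynomial along the radial coordinate of each angle's median
#'   profile; `"angular"` fits it along the angular coordinate at each
#'   radius instead (alternative reading of the construction).
#' @param min_boundary_radius radial bins excluded from the air-boundary
#'   gradient search near the center.
#' @param boundary_gradient_floor minimum HU-per-bin gradient magnitude
#'   for a detected patient boundary; angles below it are treated as air.
#' @param transition_deriv_factor ring-transition detection threshold as a
#'   multiple of the median absolute radial derivative of the full-circle
#'   median profile.
#' @return an object of class `correction_config`.
#' @export
correction_config <- function(bone_threshold = 100,
                              gas_range = c(-750, -500),
                              body_threshold = -300,
                              n_radial = 600L,
                              n_angular = 360L,
                              angular_width_deg = 80,
                              radial_width_bins = 1L,
                              order_angular = 8L,
                              order_radial = 3L,
                              median3d_kernel = c(3L, 3L, 3L),
                              precorrection = TRUE,
                              clamp_lo = 0.2,
                              clamp_hi = 5.0,
                              open_radius = 1L,
                              dilate_radius = 2L,
                              downsample_factor = 2L,
                              center_offset = c(0, 0),
                              angular_fit_axis = c("radial", "angular"),
                              min_boundary_radius = 5L,
                              boundary_gradient_floor = 100,
                              transition_deriv_factor = 5) {
  cfg <- list(bone_threshold = as.numeric(bone_threshold),
              gas_range = as.numeric(gas_range),
              body_threshold = as.numeric(body_threshold),
              n_radial = as.integer(n_radial),
              n_angular = as.integer(n_angular),
              angular_width_deg = as.numeric(angular_width_deg),
              radial_width_bins = as.integer(radial_width_bins),
              order_angular = as.integer(order_angular),
              order_radial = as.integer(order_radial),
              median3d_kernel = as.integer(median3d_kernel),
              precorrection = isTRUE(precorrection),
              clamp_lo = as.numeric(clamp_lo),
              clamp_hi = as.numeric(clamp_hi),
              open_radius = as.integer(open_radius),
              dilate_radius = as.integer(dilate_radius),
              downsample_factor = as.integer(downsample_factor),
              center_offset = as.numeric(center_offset),
              angular_fit_axis = match.arg(angular_fit_axis),
              min_boundary_radius = as.integer(min_boundary_radius),
              boundary_gradient_floor = as.numeric(boundary_gradient_floor),
              transition_deriv_factor = as.numeric(transition_deriv_factor))
  validate_config(cfg)
  structure(cfg, class = "correction_config")
}

validate_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg)
    if (!ok) stop("invalid configuration: ", msg, call. = FALSE)
  stopifnot_cfg(length(cfg$gas_range) == 2L &&
                  cfg$gas_range[1] < cfg$gas_range[2] &&
                  cfg$gas_range[2] < cfg$bone_threshold,
                "need gas_lo < gas_hi < bone_threshold")
  stopifnot_cfg(cfg$n_radial >= 8L && cfg$n_angular >= 8L,
                "polar grid too small")
  stopifnot_cfg(cfg$angular_width_deg >= 1 && cfg$angular_width_deg <= 360,
                "angular_width_deg must be in [1, 360]")
  stopifnot_cfg(cfg$radial_width_bins >= 1L, "radial_width_bins must be >= 1")
  stopifnot_cfg(cfg$order_angular >= 0L && cfg$order_radial >= 0L,
                "polynomial orders must be >= 0")
  stopifnot_cfg(length(cfg$median3d_kernel) == 3L &&
                  all(cfg$median3d_kernel >= 1L) &&
                  all(cfg$median3d_kernel %% 2L == 1L),
                "median3d_kernel sizes must be odd and >= 1")
  stopifnot_cfg(cfg$clamp_lo > 0 && cfg$clamp_hi > cfg$clamp_lo,
                "need 0 < clamp_lo < clamp_hi")
  stopifnot_cfg(cfg$downsample_factor >= 1L, "downsample_factor must be >= 1")
  stopifnot_cfg(length(cfg$center_offset) == 2L, "center_offset must be (x, y)")
  invisible(cfg)
}

#' @export
print.correction_config <- function(x, ...) {
  cat("<correction_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k, paste(v, collapse = " ")))
  }
  invisible(x)
}

#' Read or write a correction configuration file
#'
#' Configuration files are JSON objects whose keys mirror the arguments of
#' [correction_config()] exactly; unknown keys are an error (they usually
#' indicate a typo, and a silently ignored tunable is worse than a
#' failure).  Keys that are absent keep their defaults.
#'
#' @param path file path.
#' @return `read_config()`: a `correction_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(correction_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(correction_config, raw)
}

#' @param cfg a `correction_config`.
#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  if (!inherits(cfg, "correction_config"))
    stop("expected a `correction_config`", call. = FALSE)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
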