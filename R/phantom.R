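# Digital phantom generator.  Produces elliptical "patients" with bone,
# gas, and soft-tissue inserts plus ground-truth multiplicative shading
# fields, so that every pipeline stage can be verified end to end without
# patient data.  Inserts are extruded through all slices.

#' Specify a synthetic phantom
#'
#' The default phantom mimics a pelvis-scale acquisition downsampled for
#' desk-scale processing: a 256 x 256 x 32 grid at ~1.37 mm isotropic
#' spacing (~350 mm in-plane extent), an elliptical soft-tissue body of
#' 0 HU (water-equivalent), surrounded by -1000 HU air.
#'
#' Insert HU values must belong to one of the tissue classes the
#' correction distinguishes: bone (> 100 HU), gas (\[-750, -500\] HU), or
#' soft-tissue contrast ((-100, 100) HU); anything else would be neither
#' masked nor plausible and is rejected.
#'
#' @param grid_shape integer length-3 volume dimensions (x, y, z).
#' @param spacing voxel size in mm.
#' @param body list with `semi_axes` (in-plane ellipse semi-axes, mm) and
#'   `hu` (soft-tissue CT number).
#' @param inserts list of inserts, each a list with `shape` ("ellipse" or
#'   "box"), `hu`, `center` (in-plane offset from the body center, mm) and
#'   `semi_axes` (in-plane semi-axes or half-widths, mm).
#' @param noise_sigma standard deviation (HU) of additive Gaussian noise
#'   applied by [apply_shading()]; the default 20 HU is typical of
#'   clinical CBCT soft-tissue noise.
#' @param seed integer seed driving the noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(256L, 256L, 32L),
                         spacing = c(350 / 256, 350 / 256, 350 / 256),
                         body = list(semi_axes = c(150, 110), hu = 0),
                         inserts = list(),
                         noise_sigma = 20,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape[1:2] < 8L) ||
      grid_shape[3] < 1L)
    stop("grid_shape must be 3 dimensions, in-plane >= 8", call. = FALSE)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  if (is.null(body$semi_axes) || length(body$semi_axes) != 2L ||
      is.null(body$hu))
    stop("body must provide `semi_axes` (2, mm) and `hu`", call. = FALSE)
  half_extent <- (grid_shape[1:2] - 1) / 2 * spacing[1:2]
  if (any(body$semi_axes >= half_extent))
    stop("body does not fit inside the grid", call. = FALSE)
  for (ins in inserts) {
    if (is.null(ins$shape) || !ins$shape %in% c("ellipse", "box") ||
        is.null(ins$hu) || is.null(ins$center) || is.null(ins$semi_axes))
      stop("each insert needs shape, hu, center, semi_axes", call. = FALSE)
    hu <- ins$hu
    ok <- hu > 100 || (hu >= -750 && hu <= -500) || (hu > -100 && hu < 100)
    if (!ok)
      stop("insert HU must be bone (>100), gas ([-750,-500]) or ",
           "soft-tissue contrast ((-100,100)): got ", hu, call. = FALSE)
    # the insert's bounding ellipse/box must stay inside the body ellipse
    corners <- rbind(ins$center + ins$semi_axes, ins$center - ins$semi_axes,
                     ins$center + c(1, -1) * ins$semi_axes,
                     ins$center + c(-1, 1) * ins$semi_axes)
    u <- sweep(corners, 2, body$semi_axes, "/")
    if (any(rowSums(u^2) > 1))
      stop("insert '", if (is.null(ins$label)) ins$hu else ins$label,
           "' extends outside the body", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing = spacing, body = body,
                 inserts = inserts, noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# in-plane physical coordinates (mm) of voxel centers, origin at grid center
plane_coords <- function(grid_shape, spacing) {
  x <- (seq_len(grid_shape[1]) - (grid_shape[1] + 1) / 2) * spacing[1]
  y <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * spacing[2]
  list(x = matrix(x, grid_shape[1], grid_shape[2]),
       y = matrix(y, grid_shape[1], grid_shape[2], byrow = TRUE))
}

PHANTOM_LABELS <- c(air = 0L, body = 1L, bone = 2L, gas = 3L, insert = 4L)

#' Build the ground-truth phantom volume
#'
#' @param spec a [phantom_spec()].
#' @return a list with `truth` (a noise-free HU [ct_volume()]) and
#'   `labels` (an integer array coded 0 = air, 1 = body, 2 = bone,
#'   3 = gas, 4 = soft-tissue insert).
#' @export
make_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("expected a `phantom_spec`", call. = FALSE)
  d <- spec$grid_shape
  pc <- plane_coords(d, spec$spacing)
  inside_body <- (pc$x / spec$body$semi_axes[1])^2 +
    (pc$y / spec$body$semi_axes[2])^2 <= 1
  slice_hu <- matrix(-1000, d[1], d[2])
  slice_hu[inside_body] <- spec$body$hu
  slice_lab <- matrix(PHANTOM_LABELS[["air"]], d[1], d[2])
  slice_lab[inside_body] <- PHANTOM_LABELS[["body"]]
  for (ins in spec$inserts) {
    dx <- pc$x - ins$center[1]
    dy <- pc$y - ins$center[2]
    inside <- if (ins$shape == "ellipse")
      (dx / ins$semi_axes[1])^2 + (dy / ins$semi_axes[2])^2 <= 1
    else
      abs(dx) <= ins$semi_axes[1] & abs(dy) <= ins$semi_axes[2]
    code <- if (ins$hu > 100) PHANTOM_LABELS[["bone"]]
            else if (ins$hu <= -500) PHANTOM_LABELS[["gas"]]
            else PHANTOM_LABELS[["insert"]]
    slice_hu[inside] <- ins$hu
    slice_lab[inside] <- code
  }
  truth <- array(slice_hu, dim = d)
  labels <- array(slice_lab, dim = d)
  list(truth = ct_volume(truth, unit = "HU", spacing = spec$spacing),
       labels = labels)
}

#' Specify a multiplicative shading field
#'
#' Three artifact classes are modelled, mirroring the shading taxonomy of
#' circular-scan CBCT:
#' \describe{
#'   \item{GLOBAL_RING}{radially symmetric cupping with a sharp ring
#'     transition, as produced by half-fan acquisition with a bowtie
#'     filter: the field equals `inner_level` inside `inner_radius`,
#'     `outer_level` beyond `inner_radius + transition_width`, with a
#'     monotone cubic smoothstep ramp between.}
#'   \item{LOCAL_RADIAL}{a smooth cupping lobe of full `amplitude` at the
#'     center, decaying as a cubic smoothstep of radius, with a mild
#'     first-harmonic angular modulation that grows linearly with radius
#'     (so the field stays smooth through the center):
#'     `B = 1 - amplitude * q(r/R) * (1 + modulation * (r/R) *
#'     cos(theta - theta0))` with `q(u) = 1 - smoothstep(u)`.}
#'   \item{SMOOTH_POLY}{a low-order 2D polynomial in normalized in-plane
#'     coordinates (by default a tilted quadratic cup reaching full
#'     `amplitude` at the center):
#'     `B = 1 + amplitude * S / max|S|` over the unit in-plane disk, with
#'     `S = tilt_x*u + tilt_y*v + quad*(u^2 + v^2 - 1)`.}
#' }
#' All fields are strictly positive, low-frequency by construction (no
#' spectral component with period below 8 voxels), and constant along the
#' longitudinal axis.
#'
#' @param kind `"GLOBAL_RING"`, `"LOCAL_RADIAL"` or `"SMOOTH_POLY"`.
#' @param amplitude peak fractional deviation of the field from 1; must be
#'   < 1 (the field may not touch 0).  For `GLOBAL_RING` the amplitude is
#'   derived from the ring levels and this argument is ignored.
#' @param ring list with `inner_radius`, `transition_width` (mm),
#'   `inner_level`, `outer_level` (GLOBAL_RING only).  The defaults
#'   (inner level 0.75 over a water body) produce about -250 HU of
#'   soft-tissue shading, the magnitude seen clinically in uncorrected
#'   pelvis CBCT.
#' @param coefficients kind-specific shape parameters: for
#'   `LOCAL_RADIAL`, `theta0_deg` (lobe orientation) and `modulation`
#'   (relative first-harmonic depth); for `SMOOTH_POLY`, the `tilt_x`,
#'   `tilt_y` and `quad` weights of the polynomial above.
#' @return an object of class `shading_model`.
#' @export
shading_model <- function(kind = c("GLOBAL_RING", "LOCAL_RADIAL",
                                   "SMOOTH_POLY"),
                          amplitude = 0.25,
                          ring = list(inner_radius = 90,
                                      transition_width = 40,
                                      inner_level = 0.75,
                                      outer_level = 1.0),
                          coefficients = NULL) {
  kind <- match.arg(kind)
  if (kind == "GLOBAL_RING") {
    for (f in c("inner_radius", "transition_width", "inner_level",
                "outer_level"))
      if (is.null(ring[[f]])) stop("ring needs field ", f, call. = FALSE)
    amplitude <- max(abs(ring$inner_level - 1), abs(ring$outer_level - 1))
    if (ring$inner_level <= 0 || ring$outer_level <= 0)
      stop("ring levels must be positive", call. = FALSE)
  }
  if (amplitude >= 1)
    stop("amplitude must be < 1 (the field would touch 0)", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (is.null(coefficients))
    coefficients <- switch(kind,
      LOCAL_RADIAL = list(theta0_deg = 30, modulation = 0.3),
      SMOOTH_POLY = list(tilt_x = 0.15, tilt_y = 0.1, quad = 1.0),
      NULL)
  structure(list(kind = kind, amplitude = amplitude, ring = ring,
                 coefficients = coefficients),
            class = "shading_model")
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Generate a ground-truth bias field
#'
#' Evaluates a [shading_model()] on the geometry of a volume.  The field
#' is identical in every transverse slice and strictly positive.
#'
#' @param model a [shading_model()].
#' @param grid a [ct_volume()] or a list with `grid_shape`/`dims` and
#'   `spacing` supplying the geometry.
#' @return a `bias_field` (see [bias_field()]) with provenance `"TRUTH"`.
#' @export
make_bias_field <- function(model, grid) {
  if (!inherits(model, "shading_model"))
    stop("expected a `shading_model`", call. = FALSE)
  if (inherits(grid, "ct_volume")) {
    d <- dim(grid$values); spacing <- grid$spacing
  } else {
    d <- as.integer(grid$grid_shape %||% grid$dims)
    spacing <- as.numeric(grid$spacing)
  }
  pc <- plane_coords(d, spacing)
  r <- sqrt(pc$x^2 + pc$y^2)
  half_extent <- min((d[1:2] - 1) / 2 * spacing[1:2])
  slice <- switch(model$kind,
    GLOBAL_RING = {
      rg <- model$ring
      lvl <- rg$inner_level +
        (rg$outer_level - rg$inner_level) *
          smoothstep((r - rg$inner_radius) / rg$transition_width)
      lvl
    },
    LOCAL_RADIAL = {
      co <- model$coefficients
      theta <- atan2(pc$y, pc$x) - co$theta0_deg * pi / 180
      radial <- 1 - smoothstep(r / half_extent)   # 1 at center, 0 at edge
      # radius-weighted modulation keeps the field smooth at the center
      lobe <- radial * (1 + co$modulation * pmin(r / half_extent, 1) *
                          cos(theta))
      1 - model$amplitude * lobe
    },
    SMOOTH_POLY = {
      co <- model$coefficients
      u <- pc$x / half_extent
      v <- pc$y / half_extent
      s <- co$tilt_x * u + co$tilt_y * v + co$quad * (u^2 + v^2 - 1)
      smax <- max(abs(s[u^2 + v^2 <= 1]))
      if (smax == 0) matrix(1, d[1], d[2]) else
        1 + model$amplitude * s / smax
    })
  values <- array(slice, dim = d)
  bias_field(values, provenance = "TRUTH")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a multiplicative shading field to a ground-truth volume
#'
#' The forward model: the shaded volume equals the truth multiplied by the
#' bias field in the relative-attenuation domain, converted back to HU,
#' plus additive Gaussian noise in HU.  With `noise_sigma = 0` the
#' operation is exactly invertible given the field.
#'
#' @param truth a [ct_volume()] in HU.
#' @param bias a `bias_field` with the same grid.
#' @param noise_sigma additive noise standard deviation in HU.
#' @param seed integer seed for the noise.
#' @return a [ct_volume()] in HU.
#' @export
apply_shading <- function(truth, bias, noise_sigma = 0, seed = 1L) {
  stop_unit(truth, "HU")
  if (!inherits(bias, "bias_field"))
    stop("expected a `bias_field`", call. = FALSE)
  if (!identical(dim(truth$values), dim(bias$values)))
    stop("truth and bias field shapes differ", call. = FALSE)
  rel <- hu_to_rel_mu(truth)
  rel$values <- rel$values * bias$values
  out <- rel_mu_to_hu(rel)
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    out$values <- out$values +
      array(stats::rnorm(length(out$values), sd = noise_sigma),
            dim = dim(out$values))
    out <- ct_volume(out$values, unit = "HU", spacing = out$spacing)
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Read a phantom + shading simulation specification from JSON
#'
#' The file is a JSON object with two members, `phantom` and `shading`,
#' whose keys mirror [phantom_spec()] and [shading_model()].
#'
#' @param path file path.
#' @return list with `phantom` and `shading`.
#' @export
read_sim_spec <- function(path) {
  if (!file.exists(path)) stop("spec file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  phantom <- if (is.null(raw$phantom)) phantom_spec() else
    do.call(phantom_spec, raw$phantom)
  shading <- if (is.null(raw$shading)) shading_model() else
    do.call(shading_model, raw$shading)
  list(phantom = phantom, shading = shading)
}
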