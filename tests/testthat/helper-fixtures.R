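# Shared fixture builders.  Everything is generated in code; no binary
# fixtures are stored.

# small all-in-one phantom: water body with bone, gas and contrast inserts
small_phantom_spec <- function(grid = c(96L, 96L, 8L), noise_sigma = 0,
                               inserts = NULL, seed = 1L) {
  if (is.null(inserts))
    inserts <- list(
      list(shape = "ellipse", hu = 300, center = c(60, 0),
           semi_axes = c(18, 18)),
      list(shape = "ellipse", hu = -600, center = c(-60, 20),
           semi_axes = c(15, 15)),
      list(shape = "ellipse", hu = 50, center = c(0, -55),
           semi_axes = c(12, 12)))
  phantom_spec(grid_shape = grid, spacing = rep(350 / grid[1], 3),
               body = list(semi_axes = c(150, 110), hu = 0),
               inserts = inserts, noise_sigma = noise_sigma, seed = seed)
}

# a fast config for small-grid tests (coarser polar grid; the published
# 600 x 360 operating point is exercised in the acceptance suite)
fast_config <- function(...) {
  correction_config(n_radial = 200L, n_angular = 180L, ...)
}

pop_sd_of <- function(x) sqrt(mean((x - mean(x))^2))

# 2D disk slice in HU: value inside radius, air outside
disk_slice <- function(n = 96L, radius = 30, value = 0,
                       center = (n - 1) / 2 * c(1, 1)) {
  x <- matrix(0:(n - 1), n, n)
  y <- t(x)
  r <- sqrt((x - center[1])^2 + (y - center[2])^2)
  ifelse(r <= radius, value, -1000)
}

# build a polar_slice object directly (bypassing interpolation) for
# operations that act on the polar grid
make_polar <- function(values, valid = NULL, radial_step = 1,
                       angular_step = 360 / ncol(values),
                       unit = "REL_MU", center = c(0, 0)) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(values), ncol(values))
  structure(list(values = values, valid = valid, center_xy = center,
                 radial_step = radial_step, angular_step = angular_step,
                 unit = unit),
            class = "polar_slice")
}

# tiny volume with prescribed per-ROI means: a flat `background` with one
# constant block per ROI; rois are placed on a 1D raster along x
roi_mean_volume <- function(means, sds = rep(0, length(means)),
                            block = 4L, nz = 4L, seed = 1L) {
  n <- length(means)
  nx <- max(8L, n * block)
  vals <- array(0, dim = c(nx, 8L, nz))
  set.seed(seed)
  rois <- vector("list", n)
  for (i in seq_len(n)) {
    x0 <- (i - 1L) * block
    blockvals <- rep(means[i], block * block * nz)
    if (sds[i] > 0) {
      # exact population sd: alternate +/- sd around the mean
      half <- length(blockvals) / 2
      blockvals <- means[i] + sds[i] * rep(c(1, -1), half)
    }
    vals[(x0 + 1):(x0 + block), 1:block, ] <- blockvals
    rois[[i]] <- roi_box(paste0("roi", i), c(x0, 0, 0),
                         c(x0 + block, block, nz))
  }
  list(volume = ct_volume(vals, unit = "HU", spacing = c(1, 1, 1)),
       rois = rois)
}
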