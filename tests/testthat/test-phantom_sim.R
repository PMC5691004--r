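test_that("a body-only phantom is water inside and air outside", {
  spec <- phantom_spec(grid_shape = c(64L, 64L, 4L), spacing = rep(2, 3),
                       body = list(semi_axes = c(50, 40), hu = 0),
                       inserts = list())
  ph <- make_phantom(spec)
  expect_true(all(ph$truth$values[ph$labels == 1] == 0))
  expect_true(all(ph$truth$values[ph$labels == 0] == -1000))
  expect_setequal(unique(as.vector(ph$labels)), c(0L, 1L))
})

test_that("insert labels mark exactly the insert voxels", {
  spec <- phantom_spec(grid_shape = c(64L, 64L, 4L), spacing = rep(2, 3),
                       body = list(semi_axes = c(55, 50), hu = 0),
                       inserts = list(list(shape = "ellipse", hu = 300,
                                           center = c(20, 0),
                                           semi_axes = c(10, 10))))
  ph <- make_phantom(spec)
  expect_identical(ph$labels == 2, ph$truth$values == 300)
  expect_gt(sum(ph$labels == 2), 0)
})

test_that("phantom construction rejects bad inserts", {
  expect_error(phantom_spec(inserts = list(
    list(shape = "ellipse", hu = 300, center = c(145, 0),
         semi_axes = c(20, 20)))), "outside the body")
  expect_error(phantom_spec(inserts = list(
    list(shape = "ellipse", hu = -200, center = c(0, 0),
         semi_axes = c(10, 10)))), "insert HU")
  expect_error(phantom_spec(body = list(semi_axes = c(400, 110), hu = 0)),
               "fit")
})

test_that("simulation is deterministic given the seed", {
  spec <- small_phantom_spec(grid = c(32L, 32L, 4L), noise_sigma = 15,
                             inserts = list())
  ph <- make_phantom(spec)
  bias <- make_bias_field(shading_model("LOCAL_RADIAL"), ph$truth)
  a <- apply_shading(ph$truth, bias, spec$noise_sigma, seed = 11L)
  b <- apply_shading(ph$truth, bias, spec$noise_sigma, seed = 11L)
  expect_identical(a$values, b$values)
  c_ <- apply_shading(ph$truth, bias, spec$noise_sigma, seed = 12L)
  expect_false(identical(a$values, c_$values))
})

test_that("zero-amplitude shading models give an identity field", {
  grid <- list(grid_shape = c(32L, 32L, 2L), spacing = c(2, 2, 2))
  for (kind in c("LOCAL_RADIAL", "SMOOTH_POLY")) {
    b <- make_bias_field(shading_model(kind, amplitude = 0), grid)
    expect_equal(max(abs(b$values - 1)), 0, label = kind)
  }
  ring0 <- shading_model("GLOBAL_RING",
                         ring = list(inner_radius = 20, transition_width = 10,
                                     inner_level = 1, outer_level = 1))
  expect_equal(max(abs(make_bias_field(ring0, grid)$values - 1)), 0)
})

test_that("the ring field ramps monotonically between its levels", {
  grid <- list(grid_shape = c(64L, 64L, 1L), spacing = c(2, 2, 2))
  model <- shading_model("GLOBAL_RING",
                         ring = list(inner_radius = 20, transition_width = 24,
                                     inner_level = 0.7, outer_level = 1.0))
  b <- make_bias_field(model, grid)$values[, , 1]
  x <- (0:63 - 31.5) * 2
  r <- sqrt(outer(x^2, x^2, "+"))
  expect_true(all(abs(b[r < 19] - 0.7) < 1e-12))
  expect_true(all(abs(b[r > 45] - 1.0) < 1e-12))
  mid <- b[r > 21 & r < 43]
  expect_true(all(mid > 0.7 & mid < 1.0))
  # monotone in r along the +x axis
  profile <- b[33:64, 33]
  expect_true(all(diff(profile) >= -1e-12))
})

test_that("SMOOTH_POLY matches direct polynomial evaluation", {
  grid <- list(grid_shape = c(40L, 30L, 3L), spacing = c(1.5, 1.5, 3))
  co <- list(tilt_x = 0.4, tilt_y = -0.2, quad = 0.3)
  model <- shading_model("SMOOTH_POLY", amplitude = 0.2, coefficients = co)
  b <- make_bias_field(model, grid)
  # independent direct evaluation at random voxels
  half <- min((c(40, 30) - 1) / 2 * 1.5)
  u_at <- function(i) ((i - (40 + 1) / 2) * 1.5) / half
  v_at <- function(j) ((j - (30 + 1) / 2) * 1.5) / half
  s_at <- function(i, j)
    co$tilt_x * u_at(i) + co$tilt_y * v_at(j) +
      co$quad * (u_at(i)^2 + v_at(j)^2 - 1)
  ii <- seq_len(40); jj <- seq_len(30)
  s_all <- outer(ii, jj, Vectorize(s_at))
  disk <- outer(u_at(ii)^2, v_at(jj)^2, "+") <= 1
  smax <- max(abs(s_all[disk]))
  set.seed(3)
  for (k in 1:10) {
    i <- sample(40, 1); j <- sample(30, 1); z <- sample(3, 1)
    expect_lt(abs(b$values[i, j, z] - (1 + 0.2 * s_at(i, j) / smax)), 1e-12)
  }
})

test_that("shading model amplitude >= 1 is rejected", {
  expect_error(shading_model("LOCAL_RADIAL", amplitude = 1), "amplitude")
  expect_error(shading_model("GLOBAL_RING",
                             ring = list(inner_radius = 10,
                                         transition_width = 5,
                                         inner_level = -0.1,
                                         outer_level = 1)), "positive")
})

test_that("shading application is the REL_MU product and inverts exactly", {
  spec <- small_phantom_spec(grid = c(48L, 48L, 4L), inserts = list())
  ph <- make_phantom(spec)
  ident <- bias_field(array(1, dim = dim(ph$truth$values)), "TRUTH")
  out <- apply_shading(ph$truth, ident, noise_sigma = 0)
  expect_lt(max(abs(out$values - ph$truth$values)), 1e-9)

  flat <- bias_field(array(0.8, dim = dim(ph$truth$values)), "TRUTH")
  shaded <- apply_shading(ph$truth, flat, noise_sigma = 0)
  expect_lt(max(abs(shaded$values[ph$labels == 1] - (-200))), 1e-9)

  bias <- make_bias_field(shading_model("SMOOTH_POLY", amplitude = 0.3),
                          ph$truth)
  shaded <- apply_shading(ph$truth, bias, noise_sigma = 0)
  # algebraic inversion oracle: truth = shaded / bias in REL_MU
  rec <- hu_to_rel_mu(shaded)
  rec$values <- rec$values / bias$values
  rec <- rel_mu_to_hu(rec)
  expect_lt(max(abs(rec$values - ph$truth$values)), 1e-9)
})

test_that("generated fields are low-frequency: bounded discrete gradient", {
  grid <- list(grid_shape = c(96L, 96L, 2L), spacing = rep(350 / 96, 3))
  for (kind in c("LOCAL_RADIAL", "SMOOTH_POLY")) {
    model <- shading_model(kind, amplitude = 0.3)
    b <- make_bias_field(model, grid)$values[, , 1]
    g <- max(abs(diff(b)), abs(t(diff(t(b)))))
    expect_lt(g, 0.3 / 4)
  }
  # ring: bounded outside the declared transition band
  model <- shading_model("GLOBAL_RING")
  b <- make_bias_field(model, grid)$values[, , 1]
  x <- (0:95 - 47.5) * 350 / 96
  r <- sqrt(outer(x^2, x^2, "+"))
  rg <- model$ring
  outside <- r < rg$inner_radius - 5 |
    r > rg$inner_radius + rg$transition_width + 5
  gx <- abs(diff(b)); gx_out <- gx[outside[-1, ] & outside[-96, ]]
  expect_lt(max(gx_out), model$amplitude / 4)
})

test_that("simulation specs load from JSON", {
  path <- file.path(withr::local_tempdir(), "sim.json")
  writeLines('{
    "phantom": {"grid_shape": [32, 32, 2], "spacing": [2, 2, 2],
                "body": {"semi_axes": [25, 20], "hu": 0},
                "noise_sigma": 5, "seed": 3},
    "shading": {"kind": "LOCAL_RADIAL", "amplitude": 0.2}
  }', path)
  sim <- read_sim_spec(path)
  expect_identical(sim$phantom$grid_shape, c(32L, 32L, 2L))
  expect_identical(sim$shading$kind, "LOCAL_RADIAL")
  expect_equal(sim$shading$amplitude, 0.2)
})
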