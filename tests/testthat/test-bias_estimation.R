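test_that("angular median handles constants, full circles, and exclusions", {
  # constant field -> constant
  p <- make_polar(matrix(3.3, 10, 36))
  expect_true(all(angular_median(p, 80)$values == 3.3))

  # full-circle width: the plain median of all 360 values, 180.5 here
  vals <- matrix(rep(1:360, each = 5), 5, 360, byrow = FALSE)
  p <- make_polar(vals)
  am <- angular_median(p, 360)
  expect_true(all(am$values == 180.5))

  # invalid bins are excluded from the window
  vals <- matrix(c(1, 2, 3, 1000), 1, 4)
  valid <- matrix(c(TRUE, TRUE, TRUE, FALSE), 1, 4)
  p <- make_polar(vals, valid, angular_step = 90)
  am <- angular_median(p, 360)
  expect_true(all(am$values == 2))

  # a bin with no valid value in its window becomes invalid
  p_all_bad <- make_polar(matrix(1, 4, 8), matrix(FALSE, 4, 8))
  am2 <- angular_median(p_all_bad, 90)
  expect_false(any(am2$valid))
})

test_that("angular median equals a brute-force circular median", {
  set.seed(21)
  vals <- matrix(stats::rnorm(30 * 36), 30, 36)
  valid <- matrix(stats::runif(30 * 36) > 0.15, 30, 36)
  p <- make_polar(vals, valid, angular_step = 10)
  width_deg <- 90                        # 9 bins -> half window 4
  am <- angular_median(p, width_deg)
  half <- (9 %/% 2)
  for (r in c(1, 13, 30)) {
    for (a in c(1, 7, 36)) {
      win <- ((a - 1 + (-half:half)) %% 36) + 1
      wv <- vals[r, win][valid[r, win]]
      if (length(wv) == 0) {
        expect_false(am$valid[r, a])
      } else {
        expect_equal(am$values[r, a], stats::median(wv))
      }
    }
  }
})

test_that("polynomial fitting is exact, mean-reducing, and solver-correct", {
  x <- seq(-1, 1, length.out = 50)
  cubic <- 2 - x + 0.5 * x^2 + 3 * x^3
  f <- fit_polynomial_1d(cubic, order = 3)
  expect_false(f$degenerate)
  expect_lt(max(abs(f$fitted - cubic)), 1e-9)

  # order 0: the mean of the valid points
  set.seed(8)
  y <- stats::rnorm(40)
  valid <- rep(c(TRUE, FALSE), 20)
  f0 <- fit_polynomial_1d(y, valid, 0)
  expect_equal(f0$fitted[1], mean(y[valid]))

  # order-8 fit equals the explicit normal-equations solution
  y2 <- 1 + 0.3 * x[seq_len(50)]^3 + 0.2 * sin(4 * x)
  f8 <- fit_polynomial_1d(y2, order = 8)
  V <- outer(x, 0:8, "^")
  beta <- solve(t(V) %*% V, t(V) %*% y2)
  expect_lt(max(abs(f8$fitted - as.vector(V %*% beta))), 1e-6)
})

test_that("degenerate profiles fall back to the valid median", {
  y <- c(5, 7, NA, NA, NA)
  f <- fit_polynomial_1d(y, c(TRUE, TRUE, FALSE, FALSE, FALSE), 3)
  expect_true(f$degenerate)
  expect_true(all(f$fitted == 6))
  f_none <- fit_polynomial_1d(rep(NA_real_, 4), rep(FALSE, 4), 1)
  expect_true(f_none$degenerate)
  expect_true(all(is.na(f_none$fitted)))
})

test_that("a uniform water body yields an identity bias", {
  p <- make_polar(matrix(1, 120, 90), angular_step = 4)
  est <- estimate_slice_bias(p, fast_config())
  expect_false(est$empty)
  expect_lt(max(abs(est$bias - 1)), 1e-6)
  # slice with no valid bin: identity bias, flagged empty
  p0 <- make_polar(matrix(1, 120, 90), matrix(FALSE, 120, 90))
  est0 <- estimate_slice_bias(p0, fast_config())
  expect_true(est0$empty)
  expect_true(all(est0$bias == 1))
})

test_that("separable smooth fields are recovered within 2% RMS", {
  nr <- 150; na <- 120
  r <- seq(0, 1, length.out = nr)
  th <- ((seq_len(na) - 1) + 0.5) * (360 / na) * pi / 180
  f <- 1 - 0.25 * (3 * r^2 - 2 * r^3)           # cubic in r
  g <- 1 + 0.15 * cos(th - 0.4)                  # one-period harmonic
  field <- outer(f, g)
  p <- make_polar(field, angular_step = 360 / na)
  est <- estimate_slice_bias(p, correction_config())
  rel <- (est$bias - field) / field
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("flagged high-intensity wedges cannot perturb the bias", {
  nr <- 120; na <- 90
  r <- seq(0, 1, length.out = nr)
  field <- matrix(1 - 0.2 * r^2, nr, na)
  p_clean <- make_polar(field, angular_step = 4)
  est_clean <- estimate_slice_bias(p_clean, fast_config())
  contaminated <- field
  contaminated[40:60, 10:20] <- 50               # bright wedge
  valid <- matrix(TRUE, nr, na)
  valid[40:60, 10:20] <- FALSE                   # ... but flagged
  p_bad <- make_polar(contaminated, valid)
  est_bad <- estimate_slice_bias(p_bad, fast_config())
  expect_lt(max(abs(est_bad$bias - est_clean$bias)), 1e-6)
})

test_that("bias estimation is scale-equivariant", {
  nr <- 100; na <- 72
  r <- seq(0, 1, length.out = nr)
  field <- outer(1 - 0.2 * r^3, 1 + 0.1 * cos(2 * pi * (1:na) / na))
  p <- make_polar(field, angular_step = 5)
  est1 <- estimate_slice_bias(p, fast_config())
  p$values <- 1.4 * p$values
  est2 <- estimate_slice_bias(p, fast_config())
  expect_lt(max(abs(est2$bias - 1.4 * est1$bias)), 1e-9)
})

test_that("3D median filtering: identity, despiking, brute-force oracle", {
  const <- array(2.5, dim = c(7, 7, 5))
  expect_identical(smooth_bias_3d(const)$values, const)
  spike <- const
  spike[4, 4, 3] <- 4.9
  sm <- smooth_bias_3d(spike)
  expect_identical(sm$values, const)

  set.seed(13)
  a <- array(stats::runif(7 * 7 * 7, 0.5, 2), dim = c(7, 7, 7))
  sm <- smooth_bias_3d(a, c(3, 3, 3), clamp_lo = 0.01, clamp_hi = 10)
  for (k in 1:10) {
    i <- sample(2:6, 1); j <- sample(2:6, 1); z <- sample(2:6, 1)
    neigh <- a[(i - 1):(i + 1), (j - 1):(j + 1), (z - 1):(z + 1)]
    expect_equal(sm$values[i, j, z], sort(neigh)[14])
  }
  expect_error(smooth_bias_3d(a, c(2, 3, 3)), "odd")
})

test_that("the bias field container enforces positivity", {
  expect_error(bias_field(array(c(1, 0, 1, 1), c(1, 2, 2))), "positive")
  b <- bias_field(array(1, c(2, 2, 2)), "COMBINED")
  expect_identical(b$provenance, "COMBINED")
})

test_that("ring precorrection follows the inner/band/outer rule", {
  # uniform cylinder with a pure ring bias: the precorrection alone should
  # flatten the shading up to a constant
  spec <- small_phantom_spec(grid = c(96L, 96L, 4L), inserts = list())
  ph <- make_phantom(spec)
  model <- shading_model("GLOBAL_RING",
                         ring = list(inner_radius = 60,
                                     transition_width = 30,
                                     inner_level = 0.75, outer_level = 1))
  bias <- make_bias_field(model, ph$truth)
  shaded <- apply_shading(ph$truth, bias, noise_sigma = 0)
  cfg <- fast_config()
  pre <- precorrect_global_radial(hu_to_rel_mu(shaded), cfg)
  relt <- hu_to_rel_mu(ph$truth)
  body <- ph$labels == 1
  resid <- pre$volume$values[body] / relt$values[body]
  # residual shading is (nearly) uniform: the ring structure is gone
  expect_lt(pop_sd_of(resid) / mean(resid), 0.02)
  # and the uncorrected shading was anything but uniform
  shading0 <- hu_to_rel_mu(shaded)$values[body] / relt$values[body]
  expect_gt(pop_sd_of(shading0) / mean(shading0), 0.10)
  # bias normalization: inner-region level is 1
  ctr_bias <- pre$bias$values[48, 48, 2]
  expect_lt(abs(ctr_bias - 1), 1e-6)
})

test_that("precorrection is the identity on ring-free slices", {
  spec <- small_phantom_spec(grid = c(96L, 96L, 2L), inserts = list())
  ph <- make_phantom(spec)
  pre <- precorrect_global_radial(hu_to_rel_mu(ph$truth), fast_config())
  expect_true(all(pre$bias$values == 1))
  expect_equal(pre$volume$values, hu_to_rel_mu(ph$truth)$values)
})
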