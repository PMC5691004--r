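test_that("polar resampling reproduces constants exactly", {
  s <- matrix(52, 64, 64)
  p <- to_polar(s, c(31.5, 31.5), 200L, 180L, unit = "HU")
  expect_lt(max(abs(p$values[p$valid] - 52)), 1e-9)
  # out-of-grid samples take air and are invalid
  expect_true(all(p$values[!p$valid] == -1000))
  expect_gt(sum(!p$valid), 0)
  # and back: a constant polar field maps to a constant slice
  p$values[] <- 7
  back <- from_polar(p, c(64L, 64L))
  expect_lt(max(abs(back - 7)), 1e-9)
})

test_that("a centered disk is constant along every polar row inside", {
  s <- disk_slice(n = 96L, radius = 30, value = 100)
  s[s == -1000] <- 0                    # milder edge, value 100 vs 0
  p <- to_polar(s, c(47.5, 47.5), 300L, 180L, unit = "HU")
  inner_rows <- which((seq_len(300) - 1) * p$radial_step < 27)
  expect_lt(max(abs(p$values[inner_rows, ] - 100)), 1e-6)
})

test_that("polar samples match analytic evaluation of a smooth Gaussian", {
  n <- 96L
  x <- matrix(0:(n - 1), n, n); y <- t(x)
  g <- 500 * exp(-((x - 40)^2 + (y - 55)^2) / (2 * 15^2))
  ctr <- c(47.5, 47.5)
  p <- to_polar(g, ctr, 300L, 240L, unit = "HU")
  set.seed(5)
  for (k in 1:20) {
    i <- sample(180, 1) + 10            # radial bins safely inside
    j <- sample(240, 1)
    r <- (i - 1) * p$radial_step
    th <- ((j - 1) + 0.5) * p$angular_step * pi / 180
    gx <- ctr[1] + r * cos(th); gy <- ctr[2] + r * sin(th)
    if (gx < 1 || gx > n - 2 || gy < 1 || gy > n - 2) next
    analytic <- 500 * exp(-((gx - 40)^2 + (gy - 55)^2) / (2 * 15^2))
    expect_lt(abs(p$values[i, j] - analytic), 1e-3 * 500)
  }
})

test_that("polar -> Cartesian round trip is faithful on band-limited fields", {
  n <- 96L
  x <- matrix(0:(n - 1), n, n); y <- t(x)
  f <- 100 * sin(x / 14) + 80 * cos(y / 17) + 0.3 * x
  ctr <- c(47.5, 47.5)
  p <- to_polar(f, ctr, 400L, 360L, unit = "HU")
  back <- from_polar(p, c(n, n))
  r <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  sel <- r < 40                          # body-like support
  dyn <- diff(range(f))
  expect_lt(max(abs(back[sel] - f[sel])), 0.005 * dyn)
  # mean preservation within 1%
  expect_lt(abs(mean(back[sel]) - mean(f[sel])), 0.01 * abs(mean(f[sel])) +
              0.001 * dyn)
})

test_that("a radial-only polar field maps back radially symmetric", {
  p <- to_polar(matrix(0, 64, 64), c(31.5, 31.5), 200L, 180L, unit = "HU")
  rr <- (seq_len(200) - 1) * p$radial_step
  p$values <- matrix(1 + 0.01 * rr, 200, 180)   # f(r) only
  back <- from_polar(p, c(64L, 64L))
  x <- matrix(0:63, 64, 64); y <- t(x)
  r <- sqrt((x - 31.5)^2 + (y - 31.5)^2)
  # the linear-in-r field is reproduced analytically at every radius
  sel <- r < 25
  expect_lt(max(abs(back[sel] - (1 + 0.01 * r[sel]))), 1e-6)
})

test_that("air boundary lands on the body edge for disks and ellipses", {
  s <- disk_slice(n = 96L, radius = 30, value = 0)
  p <- to_polar(s, c(47.5, 47.5), 300L, 180L, unit = "HU")
  p <- detect_air_boundary(p)
  expect_true(all(abs(p$boundary * p$radial_step - 30) <= 1.5))
  # beyond-boundary bins are invalid
  a <- 90
  expect_false(any(p$valid[(p$boundary[a] + 3):300, a]))

  # ellipse: boundary follows the analytic polar radius of the ellipse
  n <- 128L
  x <- matrix(0:(n - 1), n, n); y <- t(x)
  ctr <- (n - 1) / 2
  ell <- ifelse(((x - ctr) / 45)^2 + ((y - ctr) / 30)^2 <= 1, 0, -1000)
  pe <- to_polar(ell, c(ctr, ctr), 400L, 180L, unit = "HU")
  pe <- detect_air_boundary(pe)
  th <- ((seq_len(180) - 1) + 0.5) * pe$angular_step * pi / 180
  r_analytic <- 1 / sqrt((cos(th) / 45)^2 + (sin(th) / 30)^2)
  r_detected <- pe$boundary * pe$radial_step
  expect_lt(max(abs(r_detected - r_analytic)), 1.5)  # within ~1 voxel

  # all-air slice: every angle invalid
  pa <- to_polar(matrix(-1000, 64, 64), c(31.5, 31.5), 200L, 90L,
                 unit = "HU")
  pa <- detect_air_boundary(pa)
  expect_false(any(pa$valid))
  expect_true(all(pa$boundary == 0L))
})

test_that("boundary detection is invariant to adding a constant", {
  s <- disk_slice(n = 96L, radius = 30, value = 0)
  p1 <- detect_air_boundary(to_polar(s, c(47.5, 47.5), 300L, 180L, "HU"))
  p2 <- detect_air_boundary(to_polar(s + 77, c(47.5, 47.5), 300L, 180L,
                                     "HU"))
  expect_identical(p1$boundary, p2$boundary)
})

test_that("rotating the slice by whole bins permutes polar columns", {
  n <- 97L                               # odd: exact center voxel
  x <- matrix(0:(n - 1), n, n); y <- t(x)
  ctr <- (n - 1) / 2
  f <- 100 * exp(-((x - 60)^2 + (y - 48)^2) / (2 * 12^2))
  # rotate +90 degrees about the center in the (x, y) frame:
  # (x, y) -> (-y, x), realized exactly on the grid by array ops
  f90 <- t(f)[, n:1]
  p <- to_polar(f, c(ctr, ctr), 200L, 120L, unit = "REL_MU")
  p90 <- to_polar(f90, c(ctr, ctr), 200L, 120L, unit = "REL_MU")
  shift <- 90 / p$angular_step           # 30 columns for 3-degree bins
  rotated_cols <- ((seq_len(120) - 1 + shift) %% 120) + 1
  inner <- 1:120                         # all radii inside for this field
  expect_lt(max(abs(p90$values[inner, ] - p$values[inner, rotated_cols])),
            1e-6 * 100)
})
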