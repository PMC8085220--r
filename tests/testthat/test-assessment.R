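spatial_with_grid <- function(m, grid) {
  a <- array(m, c(grid$nx, grid$ny, 1))
  attr(a, "grid") <- grid
  a
}

test_that("longitudinal profiles integrate the central slice", {
  grid <- fov_grid(101, 101, 1, 3)
  img <- spatial_with_grid(matrix(1, 101, 101), grid)
  prof <- longitudinal_profile(img, grid)          # 30 mm -> 10 rows
  expect_true(all(prof$intensity == 10))
  expect_equal(nrow(prof), 101)
  # single hot voxel on the beam axis -> single-bin spike
  m <- matrix(0, 101, 101)
  m[40, 51] <- 5
  prof2 <- longitudinal_profile(spatial_with_grid(m, grid), grid)
  expect_equal(sum(prof2$intensity > 0), 1)
  expect_equal(prof2$position[prof2$intensity > 0], axis_x <- (40 - 51) * 3)
  # degenerate width: exactly the central row
  prof3 <- longitudinal_profile(spatial_with_grid(m, grid), grid,
                                slice_width = 3)
  expect_equal(prof3$intensity, m[, 51])
  expect_warning(longitudinal_profile(img, grid, slice_width = 1e4),
                 "clipped")
})

test_that("range metrics match the hand-interpolated example", {
  prof <- data.frame(position = seq(-13.5, 13.5, by = 3),
                     intensity = c(0, 1, 2, 4, 8, 10, 7, 3, 1, 0))
  rm <- range_metrics(prof)
  expect_equal(rm$max_pos, 1.5)
  expect_equal(rm$r80, 3.5)
  expect_equal(rm$r50, 6.0)
  expect_true(rm$max_pos <= rm$r80 && rm$r80 <= rm$r50)
  # symmetric triangle peaking at zero
  tri <- data.frame(position = seq(-9, 9, by = 3),
                    intensity = c(1, 2, 3, 4, 3, 2, 1))
  rmt <- range_metrics(tri)
  expect_equal(rmt$max_pos, 0)
  expect_equal(rmt$r50, 6)   # half maximum on the linear falling edge
  # monotone increasing: no distal fall-off
  mono <- data.frame(position = seq(0, 15, by = 3),
                     intensity = 1:6)
  expect_error(range_metrics(mono), class = "pg_undefined")
})

test_that("R80 follows the distal fall-off past proximal fluctuations", {
  # a proximal spike must not drag the crossing away from the distal edge
  prof <- data.frame(position = seq(0, 33, by = 3),
                     intensity = c(2, 10, 4, 6, 8, 9, 9.5, 9, 5, 2, 1, 0.5))
  rm <- range_metrics(prof)
  expect_gt(rm$r80, 18)   # distal crossing, not the spike at position 3
})

test_that("transverse FWHM is interpolated on both flanks", {
  grid <- fov_grid(7, 7, 1, 3)
  v <- c(0, 2, 6, 10, 6, 2, 0)
  m <- matrix(rep(v, each = 7), 7, 7)   # y-profile v, constant in x
  expect_equal(transverse_fwhm(m, grid), 7.5, tolerance = 1e-9)
  # single-voxel spike reports one voxel width
  spike <- matrix(0, 7, 7)
  spike[4, 4] <- 1
  expect_equal(transverse_fwhm(spike, grid), 3, tolerance = 1e-9)
  # widening the transverse distribution widens the FWHM
  grid2 <- fov_grid(21, 21, 1, 3)
  yc <- seq(-30, 30, by = 3)
  narrow <- matrix(rep(dnorm(yc, 0, 5), each = 21), 21, 21)
  wide <- matrix(rep(dnorm(yc, 0, 10), each = 21), 21, 21)
  expect_gt(transverse_fwhm(wide, grid2), transverse_fwhm(narrow, grid2))
})

test_that("CNR follows its definition and edge cases", {
  grid <- fov_grid(101, 101, 1, 3)
  set.seed(8)
  m <- matrix(2, 101, 101)
  xc <- (seq_len(101) - 51) * 3
  outside <- outer(abs(xc) > 75, rep(TRUE, 101), "&") |
    outer(rep(TRUE, 101), abs(xc) > 30, "&")
  m[outside] <- 2 + rep(c(-1, 1), length.out = sum(outside))
  m[51, 51] <- 10
  got <- cnr(m, grid)
  expect_equal(got, 8, tolerance = 0.01)
  # adding a constant leaves the contrast unchanged
  expect_equal(cnr(m + 5, grid), got, tolerance = 1e-9)
  expect_error(cnr(matrix(1, 101, 101), grid), class = "pg_undefined")
})

test_that("the spectral peak fit recovers an exact Gaussian", {
  e <- seq(3.8, 5.0, by = 0.1)
  y <- 7 * exp(-(e - 4.4)^2 / (2 * 0.3^2)) + 0.5
  fit <- fit_spectral_peak(setNames(y, e))
  expect_equal(fit$mean, 4.4, tolerance = 1e-6)
  expect_equal(fit$sigma, 0.3, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_error(fit_spectral_peak(setNames(rep(2, length(e)), e)),
               class = "pg_undefined")
})

test_that("range shifts difference the chosen feature", {
  a <- structure(list(max_pos = -35.7, r80 = -29.9, r50 = -23.4),
                 class = "pg_range_metrics")
  b <- structure(list(max_pos = -30.7, r80 = -24.9, r50 = -18.4),
                 class = "pg_range_metrics")
  expect_equal(estimate_shift(a, a), 0)
  expect_equal(estimate_shift(b, a), 5)         # reference R80 at -29.9 mm
  expect_equal(estimate_shift(a, b), -estimate_shift(b, a))
  expect_equal(estimate_shift(b, a, "max_pos"), 5)
  bad <- structure(list(max_pos = 1, r80 = NA_real_, r50 = 2),
                   class = "pg_range_metrics")
  expect_error(estimate_shift(bad, a), class = "pg_undefined")
})

test_that("metrics shift with whole-voxel translations and ignore scale", {
  grid <- fov_grid(41, 41, 1, 3)
  xc <- (seq_len(41) - 21) * 3
  base <- pmax(0, dnorm(xc, -12, 9))
  m <- matrix(rep(base, times = 41), 41, 41)
  rm0 <- range_metrics(longitudinal_profile(spatial_with_grid(m, grid), grid))
  mshift <- matrix(0, 41, 41)
  mshift[3:41, ] <- m[1:39, ]   # +2 voxels along the beam
  rm2 <- range_metrics(longitudinal_profile(spatial_with_grid(mshift, grid),
                                            grid))
  expect_equal(rm2$max_pos - rm0$max_pos, 6)
  expect_equal(rm2$r80 - rm0$r80, 6, tolerance = 1e-9)
  expect_equal(rm2$r50 - rm0$r50, 6, tolerance = 1e-9)
  rms <- range_metrics(longitudinal_profile(spatial_with_grid(17 * m, grid),
                                            grid))
  expect_equal(rms$r80, rm0$r80, tolerance = 1e-12)
})
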