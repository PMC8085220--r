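test_that("ray tracing yields exact chords through the grid", {
  grid <- fov_grid(101, 101, 1, 3)
  rt <- ray_trace(c(-160, 0, 0), c(1, 0, 0), grid)
  expect_equal(nrow(rt), 101)
  expect_true(all(abs(rt$length - 3) < 1e-9))
  # 45-degree diagonal across a single 3 mm voxel
  g1 <- fov_grid(1, 1, 1, 3)
  rt2 <- ray_trace(c(-3, -3, 0), c(1, 1, 0) / sqrt(2), g1)
  expect_equal(nrow(rt2), 1)
  expect_equal(rt2$length, 3 * sqrt(2), tolerance = 1e-9)
  # miss
  rt3 <- ray_trace(c(0, 500, 0), c(0, 1, 0), grid)
  expect_equal(nrow(rt3), 0)
  expect_error(ray_trace(c(0, 0, 0), c(1, 1, 0), grid))  # not unit
})

test_that("a noiseless event backprojects positive weight at its source", {
  ev <- point_source_events(1, pos = c(-30, 0, 0), seed = 4)
  grid <- fov_grid(41, 41, 1, 3, energy_min = 3.0, energy_max = 6.0)
  row <- backproject_event(ev, grid, n_rays = 720, p_peak = 1, e_res = 0)
  xc <- axis_centers <- seq(-60, 60, by = 3)
  vT <- which(xc == -30) + 41 * (which(xc == 0) - 1)
  b44 <- which(abs(grid$energy_centers - 4.4) < 1e-9)
  neigh <- vT + c(-42, -41, -40, -1, 0, 1, 40, 41, 42)
  w <- row$weight[row$bin == b44 & row$voxel %in% neigh]
  expect_gt(sum(w), 0)
})

test_that("kinematically impossible candidate energies contribute nothing", {
  # deposit close to E0: only bins with a valid cone survive
  ev <- point_source_events(1, seed = 5)
  ev$E1 <- 3.0
  ev$E2 <- 0.5
  grid <- fov_grid(21, 21, 1, 3, energy_min = 3.0, energy_max = 6.0)
  row <- backproject_event(ev, grid, n_rays = 90, p_peak = 0)
  ec <- grid$energy_centers
  valid <- !is.na(suppressWarnings(
    ifelse(ec > ev$E1 + 0.05, cone_cosine(ev$E1, pmax(ec, ev$E1 + 0.06)), NA)))
  bad_bins <- which(!valid)
  expect_false(any(row$bin %in% bad_bins))
  expect_true(any(row$weight > 0))
})

test_that("row mass scales linearly with the number of rays", {
  ev <- point_source_events(1, seed = 6)
  grid <- fov_grid(41, 41, 1, 3, energy_min = 3.0, energy_max = 6.0)
  r1 <- backproject_event(ev, grid, n_rays = 1440, p_peak = 0)
  r2 <- backproject_event(ev, grid, n_rays = 2880, p_peak = 0)
  m1 <- tapply(r1$weight, r1$bin, sum)
  m2 <- tapply(r2$weight, r2$bin, sum)
  shared <- intersect(names(m1), names(m2))
  big <- shared[m1[shared] > 0.1 * max(m1)]
  ratio <- as.numeric(m2[big]) / as.numeric(m1[big])
  expect_equal(ratio, rep(2, length(ratio)), tolerance = 0.01)
})

test_that("backprojected weights agree with brute-force cone sampling", {
  ev <- point_source_events(1, pos = c(-6, 0, 0), seed = 8)
  grid <- fov_grid(21, 21, 1, 3, energy_min = 4.2, energy_max = 4.6)
  A <- backproject_events(ev, grid, n_rays = 36, p_peak = 0, n_sub = 1)
  oracle <- brute_force_backproject(ev, grid, n_rays = 36, ds = 0.01)
  nv <- 21 * 21
  for (k in seq_along(grid$energy_centers)) {
    j <- nv * (k - 1) + seq_len(nv)
    tot <- sum(A[1, j])
    tot_oracle <- sum(oracle[j])
    if (tot_oracle > 1e-6) {
      expect_equal(tot, tot_oracle, tolerance = 0.02)
    }
  }
})

test_that("the MLEM update has the expected fixed points", {
  # identical uniform rows: a uniform image stays uniform
  nj <- 18
  A <- Matrix::Matrix(1, nrow = 2, ncol = nj, sparse = TRUE)
  lam <- mlem_iterate(rep(1, nj), A, rep(1, nj))
  expect_true(all(abs(lam - lam[1]) < 1e-12))
  # single event touching one voxel: everything concentrates there
  A1 <- Matrix::sparseMatrix(i = 1, j = 5, x = 2.5, dims = c(1, nj))
  lam1 <- mlem_iterate(rep(1, nj), A1, rep(1, nj))
  expect_equal(lam1[5], 1)
  expect_true(all(lam1[-5] == 0))
  # scale invariance: multiplying all weights leaves the update unchanged
  ev <- point_source_events(40, seed = 12)
  grid <- fov_grid(21, 21, 1, 3, energy_min = 4.0, energy_max = 5.0)
  A2 <- backproject_events(ev, grid, n_rays = 90)
  nj2 <- ncol(A2)
  l1 <- mlem_iterate(rep(1, nj2), A2, rep(1, nj2))
  l2 <- mlem_iterate(rep(1, nj2), 7 * A2, rep(1, nj2))
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("the list-mode log-likelihood is non-decreasing without the filter", {
  ev <- point_source_events(50, seed = 13)
  grid <- fov_grid(21, 21, 1, 3, energy_min = 4.0, energy_max = 5.0)
  img <- reconstruct(ev, grid, iterations = 10, n_rays = 90,
                     use_filter = FALSE, p_peak = 1, e_res = 0)
  expect_equal(length(img$loglik), 10)
  expect_true(all(diff(img$loglik) > -1e-6 * abs(img$loglik[-1])))
  expect_true(all(img$values >= 0))
})

test_that("the 4D median filter behaves like a median filter", {
  arr <- array(2, c(5, 5, 1, 4))
  expect_equal(median_filter_4d(arr), arr)
  # isolated impulse in the interior is removed
  imp <- array(0, c(5, 5, 1, 4))
  imp[3, 3, 1, 2] <- 100
  out <- median_filter_4d(imp)
  expect_equal(max(out), 0)
  # max never grows
  set.seed(2)
  noisy <- array(runif(5 * 5 * 1 * 4), c(5, 5, 1, 4))
  expect_lte(max(median_filter_4d(noisy)), max(noisy))
  expect_error(median_filter_4d(noisy, size = c(2, 3, 1, 3)))
})

test_that("reconstruction is deterministic and respects iteration count", {
  ev <- point_source_events(30, seed = 14)
  grid <- fov_grid(21, 21, 1, 3, energy_min = 4.0, energy_max = 5.0)
  img0 <- reconstruct(ev, grid, iterations = 0, n_rays = 45)
  expect_true(all(img0$values == 1))
  a <- reconstruct(ev, grid, iterations = 3, n_rays = 45)
  b <- reconstruct(ev, grid, iterations = 3, n_rays = 45)
  expect_identical(a$values, b$values)
  expect_error(reconstruct(ev[0, ], grid), "empty")
})

test_that("translating events and grid together leaves the image unchanged", {
  ev <- point_source_events(25, seed = 15)
  shift <- c(6, -9, 0)
  ev2 <- ev
  for (i in 1:3) {
    cols1 <- c("x1", "y1", "z1")[i]
    cols2 <- c("x2", "y2", "z2")[i]
    ev2[[cols1]] <- ev2[[cols1]] + shift[i]
    ev2[[cols2]] <- ev2[[cols2]] + shift[i]
  }
  ev2$truth_x <- ev2$truth_x + shift[1]
  g1 <- fov_grid(15, 15, 1, 3, energy_min = 4.0, energy_max = 5.0,
                 center = c(-30, 0, 0))
  g2 <- fov_grid(15, 15, 1, 3, energy_min = 4.0, energy_max = 5.0,
                 center = c(-30, 0, 0) + shift)
  i1 <- reconstruct(ev, g1, iterations = 4, n_rays = 60, use_filter = FALSE)
  i2 <- reconstruct(ev2, g2, iterations = 4, n_rays = 60, use_filter = FALSE)
  expect_equal(i1$values, i2$values, tolerance = 1e-9)
})

test_that("energy integration and the recovered spectrum conserve totals", {
  ev <- point_source_events(40, seed = 16)
  grid <- fov_grid(21, 21, 1, 3, energy_min = 4.0, energy_max = 5.0)
  img <- reconstruct(ev, grid, iterations = 5, n_rays = 60)
  total <- sum(img$values)
  full <- integrate_energy(img, 4.0, 5.0)
  expect_equal(sum(full), total, tolerance = 1e-9)
  spec <- recovered_spectrum(img)
  expect_equal(sum(spec), total, tolerance = 1e-9)
  # the 4.3-4.5 MeV window selects exactly 3 bins of the default axis
  g92 <- fov_grid()
  expect_equal(sum(g92$energy_centers >= 4.3 - 1e-9 &
                     g92$energy_centers <= 4.5 + 1e-9), 3)
  one <- integrate_energy(img, 4.4, 4.4)
  b44 <- which(abs(grid$energy_centers - 4.4) < 1e-9)
  expect_equal(sum(one), sum(img$values[, , , b44]), tolerance = 1e-12)
  expect_error(integrate_energy(img, 9.0, 9.1))
})

test_that("sensitivity maps have the documented structure", {
  grid <- fov_grid(11, 11, 1, 3, energy_min = 4.0, energy_max = 5.0)
  geom <- camera_geometry()
  uni <- sensitivity_map(geom, grid, method = "uniform")
  expect_true(all(uni$s == 1))
  mc <- sensitivity_map(geom, grid, method = "montecarlo",
                        n_samples = 400, seed = 2)
  expect_true(all(mc$s > 0))
  # x-reflection symmetry of the geometry within Monte-Carlo tolerance
  v <- matrix(mc$values[, 1], 11, 11)
  expect_equal(mean(v[1:5, ]), mean(v[11:7, ]), tolerance = 0.1)
  # larger stand-off reduces the mean sensitivity (solid angle)
  far <- sensitivity_map(camera_geometry(scatterer_standoff = 250), grid,
                         method = "montecarlo", n_samples = 400, seed = 2)
  expect_lt(mean(far$s), mean(mc$s))
  # flood sensitivity is strictly positive and reproducible by seed
  fl1 <- sensitivity_map(geom, grid, method = "flood", seed = 3,
                         flood_events = 4000, n_rays = 45)
  fl2 <- sensitivity_map(geom, grid, method = "flood", seed = 3,
                         flood_events = 4000, n_rays = 45)
  expect_true(all(fl1$s > 0))
  expect_identical(fl1$s, fl2$s)
})
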