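test_that("scattered photon energy follows the Compton formula", {
  expect_equal(scattered_photon_energy(4.439, 1), 4.439)
  expect_equal(scattered_photon_energy(4.439, -1), 0.24159, tolerance = 1e-4)
  # backscatter limit approaches mec2 / 2 for large E0
  expect_equal(scattered_photon_energy(1e6, -1), 0.511 / 2, tolerance = 1e-4)
  expect_error(scattered_photon_energy(-1, 0))
  expect_error(scattered_photon_energy(1, 1.5))
})

test_that("cone cosine matches direct evaluation and flags invalid pairs", {
  expect_equal(cone_cosine(1.0, 4.439), 0.9665, tolerance = 1e-4)
  e1max <- max_compton_transfer(4.439)
  expect_equal(cone_cosine(e1max, 4.439), -1, tolerance = 1e-9)
  # beyond the Compton edge: kinematically invalid, value-level NA
  expect_true(is.na(cone_cosine(4.300, 4.439)))
  expect_error(cone_cosine(5, 4.439))
  expect_error(cone_cosine(0, 4.439))
})

test_that("maximum Compton transfer matches the closed form", {
  expect_equal(max_compton_transfer(4.439), 4.19741, tolerance = 1e-5)
  expect_equal(max_compton_transfer(0.511), 0.511 * 2 / 3, tolerance = 1e-9)
  E0 <- c(0.2, 1, 4.439, 10)
  e1max <- max_compton_transfer(E0)
  expect_true(all(e1max > 0 & e1max < E0))
})

test_that("energy transfer and cone angle are mutually inverse", {
  set.seed(11)
  E0 <- runif(200, 0.3, 9)
  ct <- runif(200, -1, 1)
  E1 <- E0 - scattered_photon_energy(E0, ct)
  valid <- E1 > 1e-9 & E1 < E0
  expect_equal(cone_cosine(E1[valid], E0[valid]), ct[valid],
               tolerance = 1e-9)
  # monotone: at fixed E0, the cone closes as the deposit grows
  e1 <- seq(0.1, max_compton_transfer(4.439) - 1e-6, length.out = 50)
  expect_true(all(diff(cone_cosine(e1, 4.439)) < 0))
})

test_that("the scattering-angle sampler reproduces the Klein-Nishina law", {
  set.seed(42)
  x <- sample_scatter_cosine(4.439, n = 1e5)
  ks <- suppressWarnings(stats::ks.test(x, kn_cdf_fun(4.439)))
  expect_gt(ks$p.value, 0.01)
  # Thomson limit: symmetric distribution in cos(theta)
  set.seed(42)
  y <- sample_scatter_cosine(1e-4, n = 2e4)
  expect_lt(abs(mean(y)), 0.02)
  # determinism under a fixed seed
  set.seed(7); a <- sample_scatter_cosine(2.0, n = 100)
  set.seed(7); b <- sample_scatter_cosine(2.0, n = 100)
  expect_identical(a, b)
})
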