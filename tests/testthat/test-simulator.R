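test_that("emission sampling honors the spectral mixture", {
  src <- source_model(lines = data.frame(energy = 4.439, weight = 1),
                      continuum_weight = 0)
  set.seed(1)
  em <- sample_emission(src, 2000)
  expect_true(all(em$E0 == 4.439))
  # degenerate fall-off: nothing beyond the peak
  src0 <- source_model(fall_sigma = 0)
  set.seed(1)
  em0 <- sample_emission(src0, 5000)
  expect_true(all(em0$x <= src0$entrance_x + src0$peak_depth + 1e-9))
})

test_that("a rigid source shift translates the sampled depths", {
  set.seed(3)
  a <- sample_emission(source_model(), 1e5)
  b <- sample_emission(source_model(shift = 3), 1e5)
  expect_equal(mean(b$x) - mean(a$x), 3, tolerance = 0.3)
  expect_equal(unname(quantile(b$x, 0.9) - quantile(a$x, 0.9)), 3,
               tolerance = 0.3)
})

test_that("sampled depths match the closed-form longitudinal profile", {
  src <- source_model()
  set.seed(9)
  em <- sample_emission(src, 1e5)
  lo <- src$entrance_x
  hi <- src$entrance_x + src$peak_depth + 4 * src$fall_sigma
  brk <- seq(lo, hi, length.out = 26)
  counts <- table(cut(em$x, brk))
  xs <- seq(lo, hi, length.out = 4001)
  dens <- emission_density(src, xs)
  cdf <- c(0, cumsum((dens[-1] + dens[-4001]) / 2) * diff(xs)[1])
  p <- diff(approx(xs, cdf, xout = brk)$y)
  gof <- suppressWarnings(stats::chisq.test(as.numeric(counts),
                                            p = p, rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("unblurred signal events conserve energy and satisfy the cone identity", {
  set.seed(21)
  geom <- camera_geometry(p_photopeak = 1)
  em <- sample_emission(source_model(), 20000)
  ev <- simulate_signal_events(em, geom, blur = FALSE)
  expect_gt(nrow(ev), 100)
  expect_equal(ev$E1 + ev$E2, ev$truth_E0, tolerance = 1e-12)
  u <- cbind(ev$x1 - ev$x2, ev$y1 - ev$y2, ev$z1 - ev$z2)
  u <- u / sqrt(rowSums(u^2))
  d <- cbind(ev$truth_x - ev$x1, ev$truth_y - ev$y1, ev$truth_z - ev$z1)
  d <- d / sqrt(rowSums(d^2))
  ct <- cone_cosine(ev$E1, ev$truth_E0)
  resid <- abs(acos(pmin(pmax(rowSums(u * d), -1), 1)) -
                 acos(pmin(pmax(ct, -1), 1)))
  expect_lt(max(resid), 1e-6)
  # positions inside the crystal volumes
  expect_true(all(abs(ev$x1) <= geom$scatterer_size[1] / 2 + 1e-9))
  expect_true(all(ev$y1 >= geom$scatterer_standoff - 1e-9))
})

test_that("wrong-order events break the cone identity", {
  set.seed(22)
  geom <- camera_geometry(p_photopeak = 1)
  ev <- simulate_background_events("wrong_order", geom, source_model(),
                                   n = 400, blur = FALSE)
  u <- cbind(ev$x1 - ev$x2, ev$y1 - ev$y2, ev$z1 - ev$z2)
  u <- u / sqrt(rowSums(u^2))
  d <- cbind(ev$truth_x - ev$x1, ev$truth_y - ev$y1, ev$truth_z - ev$z1)
  d <- d / sqrt(rowSums(d^2))
  ct <- suppressWarnings(
    ifelse(ev$E1 < ev$truth_E0 - 1e-9,
           1 - 0.511 * (1 / (ev$truth_E0 - ev$E1) - 1 / ev$truth_E0),
           NA_real_))
  resid <- abs(acos(pmin(pmax(rowSums(u * d), -1), 1)) -
                 acos(pmin(pmax(ct, -1), 1)))
  broken <- is.na(resid) | resid > 1e-3
  expect_gte(mean(broken), 0.95)
})

test_that("background kinds have their stated energy signatures", {
  set.seed(23)
  geom <- camera_geometry()
  src <- source_model()
  pair <- simulate_background_events("pair_annihilation", geom, src,
                                     n = 200, blur = FALSE)
  expect_true(all(pair$E2 == 0.511))
  expect_true(all(pair$truth_E0 - 1.022 - pair$E1 < 1e-9))
  expect_error(simulate_background_events("gamma_burst", geom, src))
  for (kind in c("random_coincidence", "neutron_like")) {
    ev <- simulate_background_events(kind, geom, src, n = 50)
    expect_equal(nrow(ev), 50)
    expect_true(all(ev$label == "background"))
    expect_true(all(ev$bg_kind == kind))
  }
})

test_that("the combined-energy threshold keeps the boundary and preserves records", {
  ev <- data.frame(x1 = 0, y1 = 150, z1 = 0, E1 = c(0.2, 0.375, 1.1),
                   x2 = 0, y2 = 205, z2 = 0, E2 = c(0.3, 0.375, 1.1))
  kept <- apply_energy_threshold(ev, 0.75)
  expect_equal(nrow(kept), 2)           # 0.75 boundary kept
  expect_equal(kept$E1, c(0.375, 1.1))  # order and values untouched
  expect_equal(nrow(apply_energy_threshold(ev, 0)), 3)
  none <- apply_energy_threshold(ev, 10)
  expect_equal(nrow(none), 0)
  expect_error(apply_energy_threshold(ev, -1))
})

test_that("generated datasets have exact class counts and reproduce bit-for-bit", {
  ds <- generate_dataset(1000, seed = 314)
  expect_equal(nrow(ds), 1000)
  expect_equal(sum(ds$label == "signal"), 76)  # round(1000 * 0.076)
  all_sig <- generate_dataset(200, signal_fraction = 1, seed = 314)
  expect_true(all(all_sig$label == "signal"))
  expect_error(generate_dataset(100, bg_fractions = c(pair_annihilation = 0.5,
                                                      wrong_order = 0.2)))
  a <- generate_dataset(400, seed = 99)
  b <- generate_dataset(400, seed = 99)
  expect_identical(a, b)
  # thresholding holds in the generated set
  expect_true(all(ds$E1 + ds$E2 >= 0.75))
})
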