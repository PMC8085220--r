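# Shared fixtures and independent oracles used across the test files.

# Numeric CDF of the Klein-Nishina angular density (trapezoidal
# integration), independent of the rejection sampler it checks.
kn_cdf_fun <- function(E0, n_grid = 4001) {
  ct <- seq(-1, 1, length.out = n_grid)
  f <- klein_nishina(E0, ct)
  h <- ct[2] - ct[1]
  cdf <- c(0, cumsum((f[-1] + f[-n_grid]) / 2) * h)
  cdf <- cdf / cdf[n_grid]
  approxfun(ct, cdf, yleft = 0, yright = 1)
}

# Noiseless full-absorption coincidences from a point source.
point_source_events <- function(n, pos = c(-36, 0, 0), E0 = 4.439,
                                seed = 1, standoff = 50) {
  set.seed(seed)
  geom <- camera_geometry(p_photopeak = 1, scatterer_standoff = standoff)
  em <- data.frame(x = pos[1], y = pos[2], z = pos[3], E0 = E0)
  em <- em[rep(1, 40 * n), ]
  ev <- simulate_signal_events(em, geom, blur = FALSE)
  stopifnot(nrow(ev) >= n)
  ev[seq_len(n), ]
}

# Brute-force cone backprojection oracle: the same cone parameters and
# per-cone weights as the production code, but integrated by dense point
# stepping along each ray instead of exact voxel-chord traversal.
brute_force_backproject <- function(event, grid, n_rays = 36, ds = 0.02,
                                    p_peak = 0, t_max = 400) {
  mec2 <- 0.511
  apex <- c(event$x1, event$y1, event$z1)
  u <- apex - c(event$x2, event$y2, event$z2)
  u <- u / sqrt(sum(u^2))
  e <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- c(u[2] * e[3] - u[3] * e[2], u[3] * e[1] - u[1] * e[3],
         u[1] * e[2] - u[2] * e[1])
  a <- a / sqrt(sum(a^2))
  b <- c(u[2] * a[3] - u[3] * a[2], u[3] * a[1] - u[1] * a[3],
         u[1] * a[2] - u[2] * a[1])
  corner <- grid$center - c(grid$nx, grid$ny, grid$nz) * grid$voxel / 2
  dims <- c(grid$nx, grid$ny, grid$nz)
  nv <- prod(dims)
  ec <- grid$energy_centers
  out <- numeric(nv * length(ec))
  ts <- seq(ds / 2, t_max, by = ds)
  for (k in seq_along(ec)) {
    E0 <- ec[k]
    if (E0 < event$E1 + 0.05) next
    ct <- 1 - mec2 * (1 / (E0 - event$E1) - 1 / E0)
    if (is.na(ct) || ct < -1) next
    st <- sqrt(max(0, 1 - ct^2))
    fac <- st * klein_nishina(E0, ct)
    for (r in seq_len(n_rays)) {
      phi <- 2 * pi * (r - 0.5) / n_rays
      d <- ct * u + st * (cos(phi) * a + sin(phi) * b)
      px <- apex[1] + d[1] * ts
      py <- apex[2] + d[2] * ts
      pz <- apex[3] + d[3] * ts
      ix <- floor((px - corner[1]) / grid$voxel)
      iy <- floor((py - corner[2]) / grid$voxel)
      iz <- floor((pz - corner[3]) / grid$voxel)
      ok <- ix >= 0 & ix < dims[1] & iy >= 0 & iy < dims[2] &
        iz >= 0 & iz < dims[3]
      if (!any(ok)) next
      j <- (ix + dims[1] * (iy + dims[2] * iz))[ok] + 1 + nv * (k - 1)
      tab <- table(j)
      out[as.integer(names(tab))] <- out[as.integer(names(tab))] +
        as.numeric(tab) * ds * fac
    }
  }
  out
}
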