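# Profiles, distal fall-off metrics (max / R80 / R50), transverse FWHM,
# contrast-to-noise ratio, spectral peak fit and range-shift estimation.

.spatial_matrix <- function(image, grid = NULL) {
  if (inherits(image, "pg_image"))
    stop("pass a spatial image (see integrate_energy()), not a 4D image")
  g <- if (is.null(grid)) attr(image, "grid") else grid
  if (is.null(g)) stop("grid metadata required")
  m <- image
  if (length(dim(m)) == 3) m <- apply(m, c(1, 2), sum)  # collapse z
  list(m = as.matrix(m), grid = g)
}

#' Longitudinal emission profile along the beam
#'
#' Integrates the spatial image over a slice of width `slice_width`
#' (default 3 cm, chosen to include the beam lateral spread) in the y
#' direction, centered on the beam axis, giving one intensity per x
#' voxel. With the default 3 mm voxels this sums the 10 y-rows nearest
#' the axis.
#'
#' @param image spatial image (from [integrate_energy()]) or matrix.
#' @param grid a [fov_grid()]; taken from the image attribute if absent.
#' @param slice_width transverse integration width, mm.
#' @return data.frame of class `pg_profile` with columns `position` (x
#'   voxel centers, mm) and `intensity`.
#' @export
longitudinal_profile <- function(image, grid = NULL, slice_width = 30) {
  sm <- .spatial_matrix(image, grid)
  g <- sm$grid
  stopifnot(slice_width > 0)
  nrow_band <- max(1L, as.integer(round(slice_width / g$voxel)))
  if (nrow_band > g$ny) {
    warning("slice wider than the grid; clipped to the full grid")
    nrow_band <- g$ny
  }
  yc <- axis_centers(g, "y")
  sel <- order(abs(yc), -yc)[seq_len(nrow_band)]
  prof <- if (length(sel) == 1) sm$m[, sel] else rowSums(sm$m[, sel, drop = FALSE])
  structure(data.frame(position = axis_centers(g, "x"), intensity = prof),
            class = c("pg_profile", "data.frame"), pitch = g$voxel)
}

# Interpolated crossing of height h on the distal falling edge: the last
# downward crossing of h at/after index k0. Taking the most distal
# crossing makes the estimate track the distal fall-off even when
# statistical fluctuations produce local peaks before the end of range.
.falling_crossing <- function(pos, val, k0, h, pitch) {
  out <- NA_real_
  for (k in k0:(length(val) - 1)) {
    if (val[k] >= h && val[k + 1] < h) {
      out <- pos[k] + (val[k] - h) / (val[k] - val[k + 1]) * pitch
    }
  }
  out
}

#' Range metrics from a longitudinal profile
#'
#' The peak position is the center of the maximum voxel (first
#' occurrence on ties, i.e. the most proximal). R80 and R50 are located
#' on the falling edge after the maximum by linear interpolation between
#' the voxels immediately above and below 80% and 50% of the peak
#' height. If the profile never falls below a threshold after the
#' maximum, that metric is undefined and a `pg_undefined` condition is
#' signalled.
#'
#' @param profile a `pg_profile` (or data.frame with `position`,
#'   `intensity` at constant pitch).
#' @return list of class `pg_range_metrics` with `max_pos`, `r80`, `r50`
#'   (mm along the beam axis).
#' @export
range_metrics <- function(profile) {
  pos <- profile$position
  val <- profile$intensity
  if (length(val) < 2 || max(val) <= 0)
    pg_undefined("profile has no positive maximum")
  pitch <- attr(profile, "pitch")
  if (is.null(pitch)) pitch <- diff(pos[1:2])
  imax <- which.max(val)
  vmax <- val[imax]
  if (imax == length(val))
    pg_undefined("profile is monotone increasing: no distal fall-off")
  r80 <- .falling_crossing(pos, val, imax, 0.8 * vmax, pitch)
  r50 <- .falling_crossing(pos, val, imax, 0.5 * vmax, pitch)
  if (is.na(r80) || is.na(r50))
    pg_undefined("profile never falls below the threshold after the maximum")
  structure(list(max_pos = pos[imax], r80 = r80, r50 = r50),
            class = "pg_range_metrics")
}

#' @export
print.pg_range_metrics <- function(x, ...) {
  cat(sprintf("max %.1f mm | R80 %.1f mm | R50 %.1f mm\n",
              x$max_pos, x$r80, x$r50))
  invisible(x)
}

#' Transverse FWHM of the beam image
#'
#' Builds the transverse (y) profile by summing `band_voxels` x-columns
#' centered at the image maximum, then measures the full width at half
#' maximum with linear interpolation on both flanks. When a flank never
#' crosses half maximum inside the grid, the crossing is clamped to the
#' half-voxel edge, so a single-voxel spike reports one voxel width.
#'
#' @param image spatial image or matrix.
#' @param grid a [fov_grid()].
#' @param band_voxels number of x columns in the band (default 10).
#' @return FWHM in mm.
#' @export
transverse_fwhm <- function(image, grid = NULL, band_voxels = 10) {
  sm <- .spatial_matrix(image, grid)
  g <- sm$grid
  if (max(sm$m) <= 0) pg_undefined("image has no positive maximum")
  idx <- arrayInd(which.max(sm$m), dim(sm$m))
  ix <- idx[1]
  lo <- max(1L, ix - as.integer(floor((band_voxels - 1) / 2)))
  hi <- min(g$nx, lo + band_voxels - 1L)
  lo <- max(1L, hi - band_voxels + 1L)
  prof <- rowSums(t(sm$m[lo:hi, , drop = FALSE]))
  pos <- axis_centers(g, "y")
  pk <- which.max(prof)
  half <- prof[pk] / 2
  pitch <- g$voxel

  right <- NA_real_
  if (pk < length(prof)) {
    for (k in pk:(length(prof) - 1)) {
      if (prof[k] >= half && prof[k + 1] < half) {
        right <- pos[k] + (prof[k] - half) / (prof[k] - prof[k + 1]) * pitch
        break
      }
    }
  }
  if (is.na(right)) right <- pos[length(prof)] + pitch / 2

  left <- NA_real_
  if (pk > 1) {
    for (k in pk:2) {
      if (prof[k] >= half && prof[k - 1] < half) {
        left <- pos[k] - (prof[k] - half) / (prof[k] - prof[k - 1]) * pitch
        break
      }
    }
  }
  if (is.na(left)) left <- pos[1] - pitch / 2

  right - left
}

#' Contrast-to-noise ratio
#'
#' `CNR = |S - mu| / sigma`, where `S` is the intensity at the peak and
#' `mu`, `sigma` are the mean and standard deviation of the background:
#' all voxels outside a centered exclusion rectangle of `roi[1]` mm along
#' the beam and `roi[2]` mm perpendicular to it (defaults 150 x 60 mm,
#' excluding the lateral spread of the reconstructed activity).
#'
#' @param image spatial image or matrix.
#' @param grid a [fov_grid()].
#' @param peak optional peak intensity `S`; defaults to the image maximum.
#' @param roi exclusion rectangle `c(along_beam, perpendicular)`, mm.
#' @return CNR (dimensionless). Signals `pg_undefined` when the
#'   background is empty or has zero standard deviation.
#' @export
cnr <- function(image, grid = NULL, peak = NULL, roi = c(150, 60)) {
  sm <- .spatial_matrix(image, grid)
  g <- sm$grid
  xc <- axis_centers(g, "x")
  yc <- axis_centers(g, "y")
  outside <- outer(abs(xc - g$center[1]) > roi[1] / 2,
                   rep(TRUE, g$ny), "&") |
             outer(rep(TRUE, g$nx), abs(yc - g$center[2]) > roi[2] / 2, "&")
  bg <- sm$m[outside]
  if (length(bg) < 2) pg_undefined("background region is empty")
  sdev <- sd(bg)
  if (sdev == 0) pg_undefined("background has zero standard deviation")
  S <- if (is.null(peak)) max(sm$m) else peak
  abs(S - mean(bg)) / sdev
}

#' Gaussian fit of the recovered spectral peak
#'
#' Least-squares fit of `A * exp(-(E - mean)^2 / (2 sigma^2)) + c` to the
#' recovered spectrum over `window` (default 3.8-5.0 MeV, bracketing the
#' 4.439 MeV line), via Levenberg-Marquardt.
#'
#' @param spectrum named vector from [recovered_spectrum()], or a
#'   data.frame with columns `energy` and `intensity`.
#' @param window fit window `c(lo, hi)`, MeV.
#' @return list with `mean`, `sigma` (MeV) and `r2`.
#' @export
fit_spectral_peak <- function(spectrum, window = c(3.8, 5.0)) {
  if (is.data.frame(spectrum)) {
    e <- spectrum$energy
    y <- spectrum$intensity
  } else {
    e <- as.numeric(names(spectrum))
    y <- as.numeric(spectrum)
  }
  sel <- e >= window[1] - 1e-9 & e <= window[2] + 1e-9
  if (sum(sel) < 4) stop("need at least 4 bins inside the fit window")
  e <- e[sel]; y <- y[sel]
  if (sd(y) == 0) pg_undefined("flat spectrum in the fit window")
  st <- list(A = max(y) - min(y),
             mean = e[which.max(y)],
             sigma = max(diff(range(e)) / 6, 0.05),
             c0 = min(y))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-(e - mean)^2 / (2 * sigma^2)) + c0,
                      start = st,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) {
      stop("spectral peak fit did not converge: ", conditionMessage(err))
    })
  cf <- coef(fit)
  ss_res <- sum((y - predict(fit))^2)
  ss_tot <- sum((y - mean(y))^2)
  list(mean = unname(cf["mean"]), sigma = abs(unname(cf["sigma"])),
       r2 = 1 - ss_res / ss_tot)
}

#' Range shift between two acquisitions
#'
#' Difference of a range feature between a test and a reference
#' reconstruction: `feature(test) - feature(ref)`, in mm. Positive values
#' mean the test range is deeper along the beam.
#'
#' @param metrics_test,metrics_ref [range_metrics()] results.
#' @param feature one of `"r80"` (default, the most robust indicator),
#'   `"r50"`, `"max_pos"`.
#' @return shift in mm.
#' @export
estimate_shift <- function(metrics_test, metrics_ref, feature = "r80") {
  feature <- match.arg(feature, c("r80", "r50", "max_pos"))
  a <- metrics_test[[feature]]
  b <- metrics_ref[[feature]]
  if (is.null(a) || is.null(b) || is.na(a) || is.na(b))
    pg_undefined(paste0("feature '", feature, "' undefined on an input"))
  a - b
}
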