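#' Prompt-gamma source model
#'
#' Parametric model of the prompt-gamma emission produced by a proton beam
#' stopping in a thick target: a longitudinal emission profile along the
#' beam (+x) and a spectral line/continuum mixture.
#'
#' The longitudinal profile is a monotone build-up from the target
#' entrance to the emission peak -- relative intensity
#' `rise_base + (1 - rise_base) (u / peak_depth)^rise_power` at depth `u`
#' -- followed by a Gaussian distal fall-off of scale `fall_sigma`. The
#' default quadratic build-up from a low entrance level concentrates the
#' emission near the end of range, giving the pronounced peak-to-entrance
#' contrast that makes the distal fall-off measurable. The default peak depth of 133.5 mm is
#' the calculated Bragg-peak depth of a 150 MeV proton beam in PMMA.
#' The default entrance position places the emission peak and its
#' distal fall-off comfortably inside even a reduced 41-voxel (123 mm)
#' field of view; only the faint proximal part of the build-up lies
#' outside it.
#' `shift` translates the whole profile rigidly along the beam, emulating
#' a target displacement. Transversally the emission follows the beam spot,
#' a Gaussian of `spot_fwhm` (default 7 mm FWHM) in y and z.
#'
#' The spectrum is a mixture of discrete lines and an exponential
#' continuum. Defaults: the 4.439 MeV carbon de-excitation line (dominant
#' for a PMMA target), the 6.129 MeV oxygen line, the 2.223 MeV line from
#' neutron capture on hydrogen, and a decaying continuum truncated to
#' `continuum_range`. Line weights plus `continuum_weight` must sum to 1.
#'
#' @param peak_depth depth of the emission peak from the entrance, mm.
#' @param entrance_x target entrance surface position on the beam axis, mm.
#' @param rise_base relative emission intensity at the entrance (0..1).
#' @param rise_power exponent of the monotone build-up (1 = linear).
#' @param fall_sigma Gaussian distal fall-off scale, mm.
#' @param lines data.frame with columns `energy` (MeV) and `weight`.
#' @param continuum_weight mixture weight of the continuum component.
#' @param continuum_rate exponential decay rate of the continuum, 1/MeV.
#' @param continuum_range truncation range of the continuum, MeV.
#' @param spot_fwhm transverse beam spot FWHM, mm.
#' @param shift rigid longitudinal translation of the profile, mm.
#' @return an object of class `pg_source`.
#' @export
source_model <- function(peak_depth = 133.5,
                         entrance_x = -100,
                         rise_base = 0.05,
                         rise_power = 3,
                         fall_sigma = 6,
                         lines = data.frame(
                           energy = c(4.439, 6.129, 2.223),
                           weight = c(0.45, 0.10, 0.15)
                         ),
                         continuum_weight = 0.30,
                         continuum_rate = 0.8,
                         continuum_range = c(0.8, 9.9),
                         spot_fwhm = 7,
                         shift = 0) {
  stopifnot(
    peak_depth > 0, fall_sigma >= 0, rise_base >= 0, rise_base <= 1,
    rise_power > 0,
    is.data.frame(lines), all(c("energy", "weight") %in% names(lines)),
    all(lines$energy > 0), all(lines$weight >= 0),
    continuum_weight >= 0, continuum_rate > 0,
    length(continuum_range) == 2, continuum_range[1] < continuum_range[2],
    spot_fwhm > 0
  )
  wsum <- sum(lines$weight) + continuum_weight
  if (abs(wsum - 1) > 1e-8)
    stop("line weights plus continuum_weight must sum to 1 (got ", wsum, ")")
  structure(list(
    peak_depth = peak_depth, entrance_x = entrance_x,
    rise_base = rise_base, rise_power = rise_power,
    fall_sigma = fall_sigma,
    lines = lines, continuum_weight = continuum_weight,
    continuum_rate = continuum_rate, continuum_range = continuum_range,
    spot_fwhm = spot_fwhm, shift = shift
  ), class = "pg_source")
}

#' Longitudinal emission density of a source model
#'
#' Relative (peak-normalized) emission intensity at beam-axis positions
#' `x`, including the rigid `shift`. Used for goodness-of-fit checks of
#' the sampler and for plotting.
#'
#' @param source a [source_model()].
#' @param x positions along the beam axis, mm.
#' @return relative intensities (peak = 1).
#' @export
emission_density <- function(source, x) {
  u <- x - source$entrance_x - source$shift
  L <- source$peak_depth
  b <- source$rise_base
  d <- numeric(length(u))
  rise <- u >= 0 & u <= L
  d[rise] <- b + (1 - b) * (u[rise] / L)^source$rise_power
  fall <- u > L
  if (source$fall_sigma > 0) {
    d[fall] <- exp(-(u[fall] - L)^2 / (2 * source$fall_sigma^2))
  }
  d
}

#' Sample prompt-gamma emissions
#'
#' Draws emission points from the longitudinal profile (with the
#' transverse beam-spot Gaussian in y and z) and emission energies from
#' the line/continuum mixture, independently.
#'
#' @param source a [source_model()].
#' @param n number of emissions to draw.
#' @return data.frame with columns `x, y, z` (mm) and `E0` (MeV).
#' @export
sample_emission <- function(source, n) {
  L <- source$peak_depth
  b <- source$rise_base
  pw <- source$rise_power
  s <- source$fall_sigma
  # component areas of the longitudinal density
  a_rise <- L * (b + (1 - b) / (pw + 1))
  a_fall <- s * sqrt(pi / 2)
  p_rise <- a_rise / (a_rise + a_fall)

  in_rise <- runif(n) < p_rise
  u <- numeric(n)
  nr <- sum(in_rise)
  if (nr) {
    # rejection sampling of the build-up density b + (1-b)(t/L)^pw
    todo <- which(in_rise)
    while (length(todo)) {
      cand <- runif(length(todo), 0, L)
      keep <- runif(length(todo)) < (b + (1 - b) * (cand / L)^pw)
      u[todo[keep]] <- cand[keep]
      todo <- todo[!keep]
    }
  }
  nf <- n - nr
  if (nf) u[!in_rise] <- L + abs(rnorm(nf)) * s

  x <- source$entrance_x + source$shift + u
  sigma_spot <- source$spot_fwhm / 2.3548200450309493
  y <- rnorm(n, 0, sigma_spot)
  z <- rnorm(n, 0, sigma_spot)

  # spectral mixture
  wts <- c(source$lines$weight, source$continuum_weight)
  comp <- sample.int(length(wts), n, replace = TRUE, prob = wts)
  E0 <- numeric(n)
  nline <- nrow(source$lines)
  for (k in seq_len(nline)) {
    E0[comp == k] <- source$lines$energy[k]
  }
  cont <- comp == nline + 1
  nc <- sum(cont)
  if (nc) {
    lo <- source$continuum_range[1]
    hi <- source$continuum_range[2]
    r <- source$continuum_rate
    uu <- runif(nc)
    E0[cont] <- lo - log(1 - uu * (1 - exp(-r * (hi - lo)))) / r
  }
  data.frame(x = x, y = y, z = z, E0 = E0)
}
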