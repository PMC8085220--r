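#' Two-plane Compton camera geometry
#'
#' Describes the scatterer/absorber pair relative to the beam. Coordinate
#' convention: the beam runs along +x through the origin, the detector
#' planes sit on the +y side of the beam with their faces perpendicular to
#' y, and z is the out-of-plane axis. Units are mm throughout.
#'
#' Plane sizes are given as `c(width_x, height_z, thickness_y)`; the
#' defaults are the active volumes of the two crystals used for coincidence
#' imaging (25.8 x 25.8 x 5.0 mm scatterer, 36.0 x 32.4 x 10.0 mm
#' absorber). `scatterer_standoff` is the distance from the beam axis to
#' the scatterer front face; `plane_gap` the distance from the scatterer
#' back face to the absorber front face. The two distances are
#' configurable because they depend on the experimental arrangement.
#'
#' The detector response model has three knobs: `energy_resolution` is the
#' fractional FWHM at `resolution_ref_energy` (default 5% at 0.511 MeV)
#' scaling as 1/sqrt(E); `position_sigma` is the in-plane (x, z)
#' localization blur; `p_photopeak` is the probability that the absorber
#' records the full scattered-photon energy rather than a partial deposit.
#' `coincidence_window_ns` is retained as metadata only (timing is not
#' simulated).
#'
#' @param scatterer_size,absorber_size extents `c(x, z, y-thickness)`, mm.
#' @param scatterer_standoff beam axis to scatterer front face, mm.
#' @param plane_gap scatterer back face to absorber front face, mm.
#' @param energy_resolution fractional FWHM at the reference energy.
#' @param resolution_ref_energy reference energy for the resolution, MeV.
#' @param position_sigma in-plane position blur (1 sigma), mm.
#' @param p_photopeak probability of full absorption in the absorber.
#' @param coincidence_window_ns coincidence time window, ns (metadata).
#' @param center_x,center_z camera center in the beam frame, mm.
#' @return an object of class `pg_geometry`.
#' @export
camera_geometry <- function(scatterer_size = c(25.8, 25.8, 5.0),
                            absorber_size = c(36.0, 32.4, 10.0),
                            scatterer_standoff = 150,
                            plane_gap = 50,
                            energy_resolution = 0.05,
                            resolution_ref_energy = 0.511,
                            position_sigma = 2,
                            p_photopeak = 0.5,
                            coincidence_window_ns = 50,
                            center_x = 0,
                            center_z = 0) {
  stopifnot(
    length(scatterer_size) == 3, all(scatterer_size > 0),
    length(absorber_size) == 3, all(absorber_size > 0),
    scatterer_standoff > 0, plane_gap > 0,
    energy_resolution >= 0, resolution_ref_energy > 0,
    position_sigma >= 0, p_photopeak >= 0, p_photopeak <= 1,
    coincidence_window_ns > 0
  )
  structure(list(
    scatterer_size = as.numeric(scatterer_size),
    absorber_size = as.numeric(absorber_size),
    scatterer_standoff = scatterer_standoff,
    plane_gap = plane_gap,
    energy_resolution = energy_resolution,
    resolution_ref_energy = resolution_ref_energy,
    position_sigma = position_sigma,
    p_photopeak = p_photopeak,
    coincidence_window_ns = coincidence_window_ns,
    center_x = center_x,
    center_z = center_z
  ), class = "pg_geometry")
}

# y-interval occupied by each plane
.scat_y <- function(g) g$scatterer_standoff + c(0, g$scatterer_size[3])
.abs_y <- function(g) {
  y0 <- g$scatterer_standoff + g$scatterer_size[3] + g$plane_gap
  y0 + c(0, g$absorber_size[3])
}

# 1-sigma energy blur at energy E (MeV): fractional FWHM scales as 1/sqrt(E)
.energy_sigma <- function(g, E) {
  g$energy_resolution * sqrt(g$resolution_ref_energy * E) / 2.3548200450309493
}

#' @export
print.pg_geometry <- function(x, ...) {
  cat("Two-plane Compton camera geometry (mm)\n")
  cat(sprintf("  scatterer %s at y = [%.1f, %.1f]\n",
              paste(x$scatterer_size, collapse = " x "),
              .scat_y(x)[1], .scat_y(x)[2]))
  cat(sprintf("  absorber  %s at y = [%.1f, %.1f]\n",
              paste(x$absorber_size, collapse = " x "),
              .abs_y(x)[1], .abs_y(x)[2]))
  cat(sprintf("  energy resolution %.1f%% FWHM at %.3f MeV, position sigma %.1f mm\n",
              100 * x$energy_resolution, x$resolution_ref_energy,
              x$position_sigma))
  invisible(x)
}
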