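#' Four-dimensional (space x energy) field-of-view grid
#'
#' Spatial grid of `nx x ny x nz` isotropic voxels centered on `center`,
#' plus a spectral axis of equally spaced energy-bin centers. The default
#' grid is 101 x 101 x 1 voxels of 3 mm with 92 bins of 0.1 MeV whose
#' centers run from 0.8 to 9.9 MeV inclusive (both endpoints are centers;
#' each bin spans center +/- 0.05 MeV).
#'
#' @param nx,ny,nz voxel counts per axis.
#' @param voxel isotropic voxel size, mm.
#' @param energy_min,energy_max first and last bin centers, MeV.
#' @param energy_step bin width, MeV.
#' @param center spatial grid center `c(x, y, z)`, mm.
#' @return an object of class `pg_grid`.
#' @examples
#' length(fov_grid()$energy_centers) # 92
#' @export
fov_grid <- function(nx = 101, ny = 101, nz = 1, voxel = 3,
                     energy_min = 0.8, energy_max = 9.9, energy_step = 0.1,
                     center = c(0, 0, 0)) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, voxel > 0,
            energy_step > 0, energy_max >= energy_min,
            length(center) == 3)
  nbins <- as.integer(round((energy_max - energy_min) / energy_step)) + 1L
  if (abs(energy_min + (nbins - 1) * energy_step - energy_max) > 1e-9)
    stop("energy range is not an integer number of bins")
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
    voxel = voxel,
    energy_centers = energy_min + energy_step * (seq_len(nbins) - 1),
    energy_step = energy_step,
    center = as.numeric(center)
  ), class = "pg_grid")
}

n_spatial <- function(grid) grid$nx * grid$ny * grid$nz
n_bins <- function(grid) length(grid$energy_centers)

grid_corner <- function(grid) {
  grid$center - c(grid$nx, grid$ny, grid$nz) * grid$voxel / 2
}

axis_centers <- function(grid, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  n <- switch(axis, x = grid$nx, y = grid$ny, z = grid$nz)
  k <- switch(axis, x = 1, y = 2, z = 3)
  grid_corner(grid)[k] + (seq_len(n) - 0.5) * grid$voxel
}

#' @export
print.pg_grid <- function(x, ...) {
  cat(sprintf("FoV grid: %d x %d x %d voxels of %g mm, %d energy bins of %g MeV (%g..%g)\n",
              x$nx, x$ny, x$nz, x$voxel, n_bins(x), x$energy_step,
              x$energy_centers[1], x$energy_centers[n_bins(x)]))
  invisible(x)
}
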