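# Pipeline configuration: a nested list with geometry / source / mixture /
# selector / reconstruction / assessment blocks, overridable from a YAML
# file, plus a stable fingerprint recorded in every output artifact.

#' Default pipeline configuration
#'
#' Every simulator, selector, reconstruction and assessment default in
#' one serializable list; [read_pipeline_config()] merges a YAML file
#' over it.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    geometry = list(
      scatterer_size = c(25.8, 25.8, 5.0),
      absorber_size = c(36.0, 32.4, 10.0),
      scatterer_standoff = 150, plane_gap = 50,
      energy_resolution = 0.05, resolution_ref_energy = 0.511,
      position_sigma = 2, p_photopeak = 0.5,
      coincidence_window_ns = 50, center_x = 0, center_z = 0
    ),
    source = list(
      peak_depth = 133.5, entrance_x = -100, rise_base = 0.05,
      rise_power = 3,
      fall_sigma = 6,
      line_energies = c(4.439, 6.129, 2.223),
      line_weights = c(0.45, 0.10, 0.15),
      continuum_weight = 0.30, continuum_rate = 0.8,
      continuum_range = c(0.8, 9.9), spot_fwhm = 7, shift = 0
    ),
    mixture = list(
      signal_fraction = 0.076,
      background = list(pair_annihilation = 0.65, wrong_order = 0.25,
                        random_coincidence = 0.05, neutron_like = 0.05)
    ),
    simulate = list(n_events = 50000, n_train = 30000, emin = 0.75),
    selector = list(hidden = c(80, 40), dropout = 0.25, lr = 1e-3,
                    batch_size = 256, epochs = 100, patience = 10,
                    standardize = FALSE),
    recon = list(nx = 101, ny = 101, nz = 1, voxel = 3,
                 energy_min = 0.8, energy_max = 9.9, energy_step = 0.1,
                 iterations = 50, n_rays = 180, use_filter = TRUE,
                 filter_size = c(3, 3, 1, 3),
                 sensitivity = "montecarlo", max_events = NA),
    assess = list(energy_window = c(4.3, 4.5), slice_width = 30,
                  fwhm_band = 10, cnr_roi = c(150, 60),
                  peak_window = c(3.8, 5.0)),
    seed = 1
  )
}

.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' Loads a YAML file and merges it recursively over [default_config()];
#' any subset of keys may be overridden.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  .merge_config(default_config(), yaml::read_yaml(path))
}

#' Configuration fingerprint
#'
#' Deterministic 8-hex-digit polynomial hash of the canonical JSON
#' serialization of a configuration list. A fingerprint for artifact
#' provenance, not a cryptographic digest.
#'
#' @param config any serializable list.
#' @return 8-character hex string.
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", as.integer(h))
}

# Fan a single global seed out to per-stage seeds so stages can be rerun
# in isolation: stage_seed(seed, k) = (seed * 7919 + k) mod (2^31 - 1).
stage_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k) %% 2147483647)
}

.build_geometry <- function(cfg) do.call(camera_geometry, cfg)

.build_source <- function(cfg) {
  source_model(
    peak_depth = cfg$peak_depth, entrance_x = cfg$entrance_x,
    rise_base = cfg$rise_base, rise_power = cfg$rise_power,
    fall_sigma = cfg$fall_sigma,
    lines = data.frame(energy = unlist(cfg$line_energies),
                       weight = unlist(cfg$line_weights)),
    continuum_weight = cfg$continuum_weight,
    continuum_rate = cfg$continuum_rate,
    continuum_range = unlist(cfg$continuum_range),
    spot_fwhm = cfg$spot_fwhm, shift = cfg$shift
  )
}

.build_grid <- function(cfg) {
  fov_grid(cfg$nx, cfg$ny, cfg$nz, cfg$voxel, cfg$energy_min,
           cfg$energy_max, cfg$energy_step)
}
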