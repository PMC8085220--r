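# Parametric coincidence-event simulator. It replaces full particle
# transport with a forward model that preserves the properties the
# downstream stages rely on: exact Compton kinematics in the scatterer
# (so unblurred signal events satisfy the cone-containment identity the
# reconstructor exploits), a realistic longitudinal emission profile, and
# background classes with the energy signatures the selector must learn
# to reject.

.cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Rotate unit rows of v by angle acos(cos_t) with uniform-azimuth phi.
.rotate_dirs <- function(v, cos_t, phi) {
  pick <- abs(v[, 1]) < 0.9
  e <- cbind(as.numeric(pick), as.numeric(!pick), 0)
  a <- .cross3(v, e)
  a <- a / sqrt(rowSums(a^2))
  b <- .cross3(v, a)
  st <- sqrt(pmax(0, 1 - cos_t^2))
  v * cos_t + (a * cos(phi) + b * sin(phi)) * st
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Uniform point inside the scatterer / absorber volume.
.uniform_in_scatterer <- function(g, n) {
  cbind(runif(n, g$center_x - g$scatterer_size[1] / 2,
              g$center_x + g$scatterer_size[1] / 2),
        .scat_y(g)[1] + runif(n, 0, g$scatterer_size[3]),
        runif(n, g$center_z - g$scatterer_size[2] / 2,
              g$center_z + g$scatterer_size[2] / 2))
}

.uniform_in_absorber <- function(g, n) {
  cbind(runif(n, g$center_x - g$absorber_size[1] / 2,
              g$center_x + g$absorber_size[1] / 2),
        .abs_y(g)[1] + runif(n, 0, g$absorber_size[3]),
        runif(n, g$center_z - g$absorber_size[2] / 2,
              g$center_z + g$absorber_size[2] / 2))
}

# Interaction point of a particle travelling from `from` (n x 3) into a
# plane volume: entry point uniform on the front face, depth uniform
# along the incoming ray. Keeps background deposits geometrically
# correlated with the beam, as beam-induced background is in reality.
.aimed_point <- function(g, from, plane = c("scatterer", "absorber")) {
  plane <- match.arg(plane)
  n <- nrow(from)
  if (plane == "scatterer") {
    half <- g$scatterer_size / 2
    y0 <- .scat_y(g)[1]
    thick <- g$scatterer_size[3]
  } else {
    half <- g$absorber_size / 2
    y0 <- .abs_y(g)[1]
    thick <- g$absorber_size[3]
  }
  fx <- runif(n, g$center_x - half[1], g$center_x + half[1])
  fz <- runif(n, g$center_z - half[2], g$center_z + half[2])
  entry <- cbind(fx, y0, fz)
  d <- entry - from
  d <- d / pmax(d[, 2], 1e-9)  # scale so unit step in y
  entry + d * runif(n, 0, thick)
}

# Measurement blur: Gaussian energy resolution and in-plane position blur,
# positions clamped back into the crystal volumes, energies floored at
# 1 keV to keep every record physical.
.blur_events <- function(ev, g) {
  n <- nrow(ev)
  ev$E1 <- pmax(ev$E1 + rnorm(n, 0, .energy_sigma(g, ev$E1)), 1e-3)
  ev$E2 <- pmax(ev$E2 + rnorm(n, 0, .energy_sigma(g, ev$E2)), 1e-3)
  ps <- g$position_sigma
  if (ps > 0) {
    ev$x1 <- .clamp(ev$x1 + rnorm(n, 0, ps),
                    g$center_x - g$scatterer_size[1] / 2,
                    g$center_x + g$scatterer_size[1] / 2)
    ev$z1 <- .clamp(ev$z1 + rnorm(n, 0, ps),
                    g$center_z - g$scatterer_size[2] / 2,
                    g$center_z + g$scatterer_size[2] / 2)
    ev$x2 <- .clamp(ev$x2 + rnorm(n, 0, ps),
                    g$center_x - g$absorber_size[1] / 2,
                    g$center_x + g$absorber_size[1] / 2)
    ev$z2 <- .clamp(ev$z2 + rnorm(n, 0, ps),
                    g$center_z - g$absorber_size[2] / 2,
                    g$center_z + g$absorber_size[2] / 2)
  }
  ev
}

.event_frame <- function(p1, E1, p2, E2, label, truth_E0, truth_xyz, bg_kind) {
  data.frame(
    x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3], E1 = E1,
    x2 = p2[, 1], y2 = p2[, 2], z2 = p2[, 3], E2 = E2,
    label = label,
    truth_E0 = truth_E0,
    truth_x = truth_xyz[, 1], truth_y = truth_xyz[, 2],
    truth_z = truth_xyz[, 3],
    bg_kind = bg_kind,
    stringsAsFactors = FALSE
  )
}

#' Simulate signal coincidence events from given emissions
#'
#' For each emission, the photon is importance-directed towards the
#' scatterer aperture (a point uniform on the crystal face, interaction
#' depth uniform through the crystal), Compton-scatters with a
#' Klein-Nishina angle, and the scattered ray is propagated to the
#' absorber plane. Rays that miss the absorber are geometric misses and
#' are dropped. The absorber records the full scattered energy with
#' probability `p_photopeak` (geometry parameter), otherwise a partial
#' deposit. With `blur = FALSE` the records are exact: `E1 + E2 = E0`
#' when the photopeak branch is taken, and the Compton cone built from
#' `(E1, pos1, pos2)` at the true `E0` contains the emission point.
#'
#' @param emissions data.frame from [sample_emission()] (columns x, y, z, E0).
#' @param geometry a [camera_geometry()].
#' @param blur apply the detector resolution model (default TRUE).
#' @return event data.frame (one row per detected coincidence, possibly
#'   fewer rows than `emissions`), labeled `"signal"` with truth columns.
#' @export
simulate_signal_events <- function(emissions, geometry, blur = TRUE) {
  g <- geometry
  n <- nrow(emissions)
  if (n == 0) return(.event_frame(matrix(0, 0, 3), numeric(0),
                                  matrix(0, 0, 3), numeric(0),
                                  character(0), numeric(0),
                                  matrix(0, 0, 3), character(0)))
  p1 <- .uniform_in_scatterer(g, n)
  em <- cbind(emissions$x, emissions$y, emissions$z)
  v <- p1 - em
  rr <- sqrt(rowSums(v^2))
  v <- v / rr
  # solid-angle acceptance: a surface patch at distance r and incidence
  # cosine dy/r subtends a flux proportional to cos(alpha)/r^2. Rejection
  # normalized per emission by its closest approach to the face keeps the
  # bound below 1 everywhere and the accepted points distributed as
  # physical flux through the face.
  cos_alpha <- pmax(v[, 2], 0)
  dx_face <- pmax(abs(em[, 1] - g$center_x) - g$scatterer_size[1] / 2, 0)
  dz_face <- pmax(abs(em[, 3] - g$center_z) - g$scatterer_size[2] / 2, 0)
  r_close <- sqrt(dx_face^2 + (g$scatterer_standoff - em[, 2])^2 + dz_face^2)
  acc <- runif(n) < cos_alpha * (r_close / rr)^2
  ct <- sample_scatter_cosine(emissions$E0)
  Ep <- scattered_photon_energy(emissions$E0, ct)
  E1 <- emissions$E0 - Ep
  w <- .rotate_dirs(v, ct, runif(n, 0, 2 * pi))

  ya <- .abs_y(g)[1]
  ok <- w[, 2] > 1e-9
  tt <- ifelse(ok, (ya - p1[, 2]) / w[, 2], NA_real_)
  qx <- p1[, 1] + w[, 1] * tt
  qz <- p1[, 3] + w[, 3] * tt
  ok <- ok &
    abs(qx - g$center_x) <= g$absorber_size[1] / 2 &
    abs(qz - g$center_z) <= g$absorber_size[2] / 2
  ok[is.na(ok)] <- FALSE

  # deposit point uniform along the ray's chord inside the absorber box,
  # so pos2 stays exactly on the scattered ray (no clamping): the
  # unblurred record then satisfies the cone-containment identity
  exit_t <- function(p, d, lo, hi) {
    ifelse(d > 1e-12, (hi - p) / d, ifelse(d < -1e-12, (lo - p) / d, Inf))
  }
  t_exit <- pmin(
    (ya + g$absorber_size[3] - p1[, 2]) / w[, 2],
    exit_t(p1[, 1], w[, 1], g$center_x - g$absorber_size[1] / 2,
           g$center_x + g$absorber_size[1] / 2),
    exit_t(p1[, 3], w[, 3], g$center_z - g$absorber_size[2] / 2,
           g$center_z + g$absorber_size[2] / 2)
  )
  t2 <- tt + runif(n) * pmax(t_exit - tt, 0)
  p2 <- p1 + w * t2

  full <- runif(n) < g$p_photopeak
  E2 <- ifelse(full, Ep, Ep * runif(n, 0.1, 0.9))

  # E1 = 0 occurs only at exactly forward scatter; drop such events as
  # undetectable rather than recording a zero deposit
  ok <- ok & acc & E1 > 1e-9
  ev <- .event_frame(p1[ok, , drop = FALSE], E1[ok], p2[ok, , drop = FALSE],
                     E2[ok], "signal", emissions$E0[ok],
                     em[ok, , drop = FALSE], NA_character_)
  if (blur) ev <- .blur_events(ev, g)
  ev
}

#' Simulate a single signal event
#'
#' Scalar wrapper around [simulate_signal_events()] for one emission;
#' returns `NULL` on a geometric miss (a normal outcome, not an error).
#'
#' @param emission list or one-row data.frame with `x, y, z, E0`.
#' @param geometry a [camera_geometry()].
#' @param blur apply the detector resolution model.
#' @return one-row event data.frame, or `NULL` if the scattered photon
#'   misses the absorber.
#' @export
simulate_signal_event <- function(emission, geometry, blur = TRUE) {
  ev <- simulate_signal_events(as.data.frame(as.list(emission)), geometry,
                               blur = blur)
  if (nrow(ev) == 0) NULL else ev
}

.bg_kinds <- c("pair_annihilation", "wrong_order", "random_coincidence",
               "neutron_like")

#' Simulate background coincidence events
#'
#' Generates `n` events of one background class:
#' \describe{
#'   \item{pair_annihilation}{a prompt gamma pair-produces in the
#'     scatterer (deposit `E0 - 1.022` MeV) and one 0.511 MeV
#'     annihilation photon is absorbed in the absorber.}
#'   \item{wrong_order}{a signal event whose plane energies are swapped
#'     in the record, emulating a time-order misassignment; the recorded
#'     cone no longer points back at the emission.}
#'   \item{random_coincidence}{two unrelated emissions: a Compton deposit
#'     in the scatterer from one and an arbitrary partial deposit in the
#'     absorber from the other.}
#'   \item{neutron_like}{uncorrelated broad (exponential) deposits in
#'     both planes, emulating neutron-induced background.}
#' }
#'
#' @param kind one of `r paste0('"', paste(pgcc:::.bg_kinds, collapse='", "'), '"')`.
#' @param geometry a [camera_geometry()].
#' @param source a [source_model()] (emission sampling for photon-derived
#'   classes).
#' @param n number of events.
#' @param blur apply the detector resolution model.
#' @return event data.frame labeled `"background"` with `bg_kind` recorded.
#' @export
simulate_background_events <- function(kind, geometry, source, n = 1,
                                       blur = TRUE) {
  if (!kind %in% .bg_kinds)
    stop("unknown background kind: ", kind)
  g <- geometry

  if (kind == "pair_annihilation") {
    em <- sample_emission(source, n)
    # pair production needs E0 > 2 mec2; redraw the energy for soft photons
    for (i in 1:50) {
      low <- em$E0 <= 1.022 + 1e-6
      if (!any(low)) break
      em$E0[low] <- sample_emission(source, sum(low))$E0
    }
    em$E0[em$E0 <= 1.022 + 1e-6] <- 4.439
    emm <- cbind(em$x, em$y, em$z)
    p1 <- .aimed_point(g, emm, "scatterer")
    # annihilation photon emitted at the conversion point
    p2 <- .aimed_point(g, p1, "absorber")
    ev <- .event_frame(p1, em$E0 - 1.022, p2, rep(0.511, n), "background",
                       em$E0, emm, kind)
  } else if (kind == "wrong_order") {
    ev <- NULL
    while (is.null(ev) || nrow(ev) < n) {
      em <- sample_emission(source, max(2 * n, 100))
      batch <- simulate_signal_events(em, g, blur = FALSE)
      ev <- rbind(ev, batch)
    }
    ev <- ev[seq_len(n), ]
    tmp <- ev$E1
    ev$E1 <- ev$E2
    ev$E2 <- tmp
    ev$label <- "background"
    ev$bg_kind <- kind
  } else if (kind == "random_coincidence") {
    # two unrelated beam emissions detected within the coincidence
    # window, one deposit per plane
    em_a <- sample_emission(source, n)
    em_b <- sample_emission(source, n)
    p1 <- .aimed_point(g, cbind(em_a$x, em_a$y, em_a$z), "scatterer")
    ct <- sample_scatter_cosine(em_a$E0)
    E1 <- em_a$E0 - scattered_photon_energy(em_a$E0, ct)
    p2 <- .aimed_point(g, cbind(em_b$x, em_b$y, em_b$z), "absorber")
    E2 <- em_b$E0 * runif(n, 0.2, 1)
    ev <- .event_frame(p1, pmax(E1, 1e-3), p2, E2, "background",
                       NA_real_, cbind(NA_real_, NA_real_, NA_real_)[rep(1, n), , drop = FALSE],
                       kind)
  } else { # neutron_like
    # beam-produced neutrons reach the planes from the target region
    # with broad, uncorrelated deposits
    em_a <- sample_emission(source, n)
    em_b <- sample_emission(source, n)
    p1 <- .aimed_point(g, cbind(em_a$x, em_a$y, em_a$z), "scatterer")
    p2 <- .aimed_point(g, cbind(em_b$x, em_b$y, em_b$z), "absorber")
    E1 <- pmin(0.05 + rexp(n, 1 / 1.5), 9.9)
    E2 <- pmin(0.05 + rexp(n, 1 / 1.5), 9.9)
    ev <- .event_frame(p1, E1, p2, E2, "background", NA_real_,
                       cbind(NA_real_, NA_real_, NA_real_)[rep(1, n), , drop = FALSE],
                       kind)
  }
  if (blur) ev <- .blur_events(ev, g)
  ev
}

#' @rdname simulate_background_events
#' @export
simulate_background_event <- function(kind, geometry, source, blur = TRUE) {
  simulate_background_events(kind, geometry, source, n = 1, blur = blur)
}

#' Apply the combined-energy acquisition threshold
#'
#' Retains exactly the events whose combined deposited energy
#' `E1 + E2` is at least `emin` (boundary kept), preserving order and all
#' fields. The default 0.75 MeV reproduces the 750 keV low-energy
#' threshold applied before event selection.
#'
#' @param events event data.frame.
#' @param emin threshold on `E1 + E2`, MeV.
#' @return the retained subset, order preserved.
#' @export
apply_energy_threshold <- function(events, emin = 0.75) {
  if (!is.numeric(emin) || length(emin) != 1 || is.na(emin) || emin < 0)
    stop("emin must be a single non-negative number")
  keep <- events$E1 + events$E2 >= emin
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Largest-remainder apportionment of n among fractions (sums to n exactly).
.largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Generate a labeled coincidence dataset
#'
#' Produces exactly `n_events` post-threshold events with exact class
#' counts `round(n_events * fraction)` by largest-remainder rounding:
#' `signal_fraction` of signal events (default 7.6%, the signal
#' prevalence among coincidences in the training study) and the remainder
#' split among background kinds by `bg_fractions`. Events of each class
#' are simulated until the quota of threshold-passing events is reached,
#' then the classes are interleaved by a seeded shuffle. Bit-for-bit
#' reproducible from `(configuration, seed)`.
#'
#' @param n_events number of events after thresholding.
#' @param signal_fraction fraction of true signal events.
#' @param bg_fractions named fractions over background kinds (sum to 1).
#' @param geometry a [camera_geometry()].
#' @param source a [source_model()].
#' @param emin combined-energy threshold, MeV (see
#'   [apply_energy_threshold()]).
#' @param blur apply the detector resolution model.
#' @param seed integer seed; when non-NULL, `set.seed(seed)` is called.
#' @return event data.frame with attributes `config` (generation
#'   parameters) and `seed`.
#' @export
generate_dataset <- function(n_events,
                             signal_fraction = 0.076,
                             bg_fractions = c(pair_annihilation = 0.65,
                                              wrong_order = 0.25,
                                              random_coincidence = 0.05,
                                              neutron_like = 0.05),
                             geometry = camera_geometry(),
                             source = source_model(),
                             emin = 0.75,
                             blur = TRUE,
                             seed = NULL) {
  stopifnot(n_events >= 1, signal_fraction >= 0, signal_fraction <= 1)
  if (is.null(names(bg_fractions)) || !all(names(bg_fractions) %in% .bg_kinds))
    stop("bg_fractions must be named with known background kinds")
  if (abs(sum(bg_fractions) - 1) > 1e-8 && signal_fraction < 1)
    stop("bg_fractions must sum to 1")
  if (!is.null(seed)) set.seed(seed)

  fractions <- c(signal = signal_fraction,
                 (1 - signal_fraction) * bg_fractions)
  counts <- .largest_remainder(n_events, fractions)
  names(counts) <- names(fractions)

  take <- function(gen, k) {
    out <- NULL
    while (is.null(out) || nrow(out) < k) {
      batch <- apply_energy_threshold(gen(max(2 * k, 200)), emin)
      out <- rbind(out, batch)
    }
    out[seq_len(k), , drop = FALSE]
  }

  pieces <- list()
  if (counts["signal"] > 0) {
    pieces$signal <- take(function(m) {
      simulate_signal_events(sample_emission(source, m), geometry, blur = blur)
    }, counts["signal"])
  }
  for (kind in names(bg_fractions)) {
    k <- counts[kind]
    if (k > 0) {
      pieces[[kind]] <- take(function(m) {
        simulate_background_events(kind, geometry, source, n = m, blur = blur)
      }, k)
    }
  }

  events <- do.call(rbind, pieces)
  events <- events[sample.int(nrow(events)), , drop = FALSE]
  rownames(events) <- NULL
  attr(events, "config") <- list(
    n_events = n_events, signal_fraction = signal_fraction,
    bg_fractions = as.list(bg_fractions), emin = emin, blur = blur,
    geometry = unclass(geometry), source = unclass(source)
  )
  attr(events, "seed") <- seed
  events
}
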