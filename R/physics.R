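# Closed-form Compton kinematics and Klein-Nishina scattering. These are
# shared by the simulator (forward sampling) and the reconstructor
# (candidate-energy cone angles).

#' Scattered photon energy after a Compton interaction
#'
#' For an incident photon of energy `E0` scattering through an angle with
#' cosine `cos_theta`, the scattered photon carries
#' \deqn{E' = \frac{E_0}{1 + (E_0/m_ec^2)(1 - \cos\theta)}}
#' with \eqn{m_ec^2 = 0.511} MeV.
#'
#' @param E0 incident photon energy, MeV (> 0).
#' @param cos_theta cosine of the scattering angle, in \[-1, 1\].
#' @return scattered photon energy E', MeV; `E' = E0` iff `cos_theta = 1`.
#' @examples
#' scattered_photon_energy(4.439, -1) # backscatter, ~0.2416 MeV
#' @export
scattered_photon_energy <- function(E0, cos_theta) {
  if (any(!is.finite(E0)) || any(E0 <= 0))
    stop("E0 must be positive and finite")
  if (any(!is.finite(cos_theta)) || any(cos_theta < -1) || any(cos_theta > 1))
    stop("cos_theta must lie in [-1, 1]")
  E0 / (1 + (E0 / .mec2) * (1 - cos_theta))
}

#' Compton cone angle cosine from deposited and assumed total energy
#'
#' Inverts the Compton formula: an event that deposited `E1` in the first
#' interaction of a photon of (assumed) energy `E0` constrains the incoming
#' direction to a cone of half-angle theta with
#' \deqn{\cos\theta = 1 - m_ec^2\left(\frac{1}{E_0-E_1} - \frac{1}{E_0}\right).}
#' Energy transfers beyond the Compton edge make the right-hand side fall
#' below -1; that candidate energy is kinematically impossible and the
#' function returns `NA` (a value-level outcome, not an error, because the
#' spectral backprojector probes many candidate energies per event and most
#' are expected to fail).
#'
#' @param E1 energy deposited in the first interaction, MeV (0 < E1 < E0).
#' @param E0 assumed initial photon energy, MeV.
#' @return cosine of the cone half-angle in \[-1, 1\], or `NA_real_` when
#'   the pair is kinematically invalid.
#' @export
cone_cosine <- function(E1, E0) {
  if (any(!is.finite(E1)) || any(!is.finite(E0)) || any(E1 <= 0) || any(E1 >= E0))
    stop("require 0 < E1 < E0")
  ct <- 1 - .mec2 * (1 / (E0 - E1) - 1 / E0)
  ct[ct < -1] <- NA_real_
  ct
}

#' Maximum Compton energy transfer (Compton edge)
#'
#' The largest energy a photon of energy `E0` can deposit in a single
#' Compton scatter, attained at backscatter:
#' `E1max = E0 - E0 / (1 + 2 E0 / mec2)`.
#'
#' @param E0 photon energy, MeV (> 0).
#' @return maximum single-scatter energy transfer, MeV.
#' @export
max_compton_transfer <- function(E0) {
  if (any(!is.finite(E0)) || any(E0 <= 0))
    stop("E0 must be positive and finite")
  E0 - E0 / (1 + 2 * E0 / .mec2)
}

#' Klein-Nishina angular density (unnormalized)
#'
#' Differential cross-section in `cos_theta`, up to a constant factor:
#' with \eqn{\epsilon = E'/E_0}, the density is
#' \eqn{\epsilon^2(\epsilon + 1/\epsilon - \sin^2\theta)}. Used as the
#' target density of [sample_scatter_cosine()] and as the oracle in its
#' tests. Bounded above by 2 for every `E0`.
#'
#' @param E0 photon energy, MeV.
#' @param cos_theta cosine(s) of the scattering angle.
#' @return unnormalized density values.
#' @export
klein_nishina <- function(E0, cos_theta) {
  eps <- 1 / (1 + (E0 / .mec2) * (1 - cos_theta))
  eps^2 * (eps + 1 / eps - (1 - cos_theta^2))
}

#' Draw Compton scattering angle cosines from the Klein-Nishina density
#'
#' Rejection sampling with a uniform proposal on \[-1, 1\] and the exact
#' envelope bound 2 (the density maximum, attained at forward scatter).
#' Deterministic given the R random-number state.
#'
#' @param E0 photon energy, MeV; scalar or vector (one draw per element).
#' @param n number of draws when `E0` is scalar.
#' @return vector of sampled `cos_theta` values.
#' @export
sample_scatter_cosine <- function(E0, n = length(E0)) {
  if (any(!is.finite(E0)) || any(E0 <= 0))
    stop("E0 must be positive and finite")
  if (length(E0) == 1) E0 <- rep(E0, n)
  if (length(E0) != n) stop("length(E0) must be 1 or n")
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    ct <- runif(length(todo), -1, 1)
    u <- runif(length(todo), 0, 2)
    ok <- u <= klein_nishina(E0[todo], ct)
    out[todo[ok]] <- ct[ok]
    todo <- todo[!ok]
  }
  out
}
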