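#' Donor fluorescence quantum yield
#'
#' The quantum yield of the donor fluorophore is the product of its radiative
#' (fluorescence) decay rate and its measured excited-state lifetime,
#' \eqn{\phi_D = k_F \cdot \tau_L}. Lifetimes of maleimide-conjugated dyes
#' depend on the local protein environment, so \code{tau_L} is typically
#' measured per labelling site (e.g. by TCSPC).
#'
#' @param k_F Radiative decay rate in ns^-1 (> 0).
#' @param tau_L Fluorescence lifetime in ns (> 0).
#' @return Dimensionless quantum yield in (0, 1].
#' @examples
#' quantum_yield(0.239, 2.6)
#' @export
quantum_yield <- function(k_F, tau_L) {
  stopifnot(is.numeric(k_F), is.numeric(tau_L), is.finite(k_F), is.finite(tau_L))
  if (k_F <= 0 || tau_L <= 0) stop("k_F and tau_L must be positive")
  phi <- k_F * tau_L
  if (any(phi > 1)) stop("k_F * tau_L exceeds 1: not a valid quantum yield")
  phi
}

#' Forster radius of a dye pair
#'
#' Computes \eqn{R_0 = 0.211 (\kappa^2 n^{-4} \phi_D J)^{1/6}} in Angstrom
#' (the 0.211 prefactor is valid for the overlap integral J expressed in
#' M^-1 cm^-1 nm^4) and returns the result in nm.
#'
#' @param k_F Donor radiative decay rate, ns^-1.
#' @param tau_L Donor fluorescence lifetime, ns.
#' @param kappa2 Orientation factor; 2/3 for freely rotating dyes.
#' @param n_refr Refractive index of the medium.
#' @param J Spectral overlap integral in M^-1 cm^-1 nm^4.
#' @return Forster radius in nm.
#' @examples
#' forster_radius(0.239, 2.6, 2 / 3, 1.34, 5.8e15) # ~6.35 nm
#' @export
forster_radius <- function(k_F, tau_L, kappa2 = 2 / 3, n_refr = 1.34,
                           J = 5.8e15) {
  stopifnot(kappa2 > 0, kappa2 <= 4, n_refr >= 1, J > 0)
  phi <- quantum_yield(k_F, tau_L)
  r0_angstrom <- 0.211 * (kappa2 * n_refr^-4 * phi * J)^(1 / 6)
  if (!is.finite(r0_angstrom)) stop("non-finite Forster radius")
  r0_angstrom / 10
}

#' Fluorophore-pair presets
#'
#' Named photophysical constants for the Cy3B / ATTO 647N pair used with the
#' two single-cysteine labelling sites of InlB321: `cy3b_T` (tail site,
#' lifetime 2.6 ns) and `cy3b_H` (head site, lifetime 2.5 ns). The derived
#' Forster radii are ~6.34 and ~6.30 nm.
#'
#' @param preset One of `"cy3b_T"`, `"cy3b_H"`, or `"custom"`.
#' @param k_F,tau_L,kappa2,n_refr,J Overrides for `"custom"` (defaults are
#'   the `cy3b_T` values).
#' @return A list of class `fluorophore_pair` with the inputs, `phi_D`, and
#'   the derived `R0` in nm.
#' @export
fluorophore_pair <- function(preset = c("cy3b_T", "cy3b_H", "custom"),
                             k_F = 0.239, tau_L = 2.6, kappa2 = 2 / 3,
                             n_refr = 1.34, J = 5.8e15) {
  preset <- match.arg(preset)
  if (preset == "cy3b_T") tau_L <- 2.6
  if (preset == "cy3b_H") tau_L <- 2.5
  out <- list(
    preset = preset, k_F = k_F, tau_L = tau_L, kappa2 = kappa2,
    n_refr = n_refr, J = J,
    phi_D = quantum_yield(k_F, tau_L),
    R0 = forster_radius(k_F, tau_L, kappa2, n_refr, J)
  )
  class(out) <- "fluorophore_pair"
  out
}

#' @export
print.fluorophore_pair <- function(x, ...) {
  cat(sprintf("Fluorophore pair '%s': phi_D = %.4f, R0 = %.3f nm\n",
              x$preset, x$phi_D, x$R0))
  invisible(x)
}

#' Convert FRET efficiency to donor-acceptor distance
#'
#' \eqn{R = R_0 (1/E - 1)^{1/6}}. Efficiencies at or outside (0, 1) cannot be
#' converted; callers handle censored "no FRET" observations explicitly (see
#' [measured_distance_set()]).
#'
#' @param E FRET efficiency, strictly inside (0, 1). Vectorized.
#' @param R0 Forster radius in nm.
#' @return Distance in nm.
#' @examples
#' efficiency_to_distance(0.84, 6.34) # ~4.8 nm
#' @export
efficiency_to_distance <- function(E, R0) {
  stopifnot(is.numeric(E), is.numeric(R0), R0 > 0)
  if (any(!is.finite(E)) || any(E <= 0) || any(E >= 1)) {
    stop("E out of range (0, 1): distance undefined (censored observation?)")
  }
  R0 * (1 / E - 1)^(1 / 6)
}

#' Convert donor-acceptor distance to FRET efficiency
#'
#' \eqn{E = 1 / (1 + (R/R_0)^6)}; exact inverse of
#' [efficiency_to_distance()].
#'
#' @param R Distance in nm (> 0). Vectorized.
#' @param R0 Forster radius in nm.
#' @return FRET efficiency in (0, 1).
#' @export
distance_to_efficiency <- function(R, R0) {
  stopifnot(is.numeric(R), is.numeric(R0), all(R > 0), R0 > 0)
  1 / (1 + (R / R0)^6)
}

#' First-order uncertainty of a FRET-derived distance
#'
#' Propagates the efficiency uncertainty and the relative uncertainty of the
#' Forster radius through the distance conversion:
#' \deqn{\sigma_R^2 = (\partial R/\partial E \cdot \sigma_E)^2 +
#'       (R \cdot \sigma_{R_0}/R_0)^2}
#' with \eqn{\partial R/\partial E = -(R_0/6)(1/E - 1)^{-5/6} E^{-2}}.
#'
#' @param E FRET efficiency in (0, 1).
#' @param sigma_E Standard deviation of E.
#' @param R0 Forster radius in nm.
#' @param rel_sigma_R0 Relative uncertainty of R0 (default 0.03, covering
#'   orientation-factor, refractive-index and overlap-integral uncertainty at
#'   the level of the community benchmark conventions).
#' @return Distance standard deviation in nm.
#' @examples
#' distance_uncertainty(0.84, 0.06, 6.34) # ~0.3 nm
#' @export
distance_uncertainty <- function(E, sigma_E, R0, rel_sigma_R0 = 0.03) {
  stopifnot(sigma_E >= 0, rel_sigma_R0 >= 0)
  if (any(E <= 0) || any(E >= 1)) stop("E at or outside bounds (0, 1)")
  R <- efficiency_to_distance(E, R0)
  dRdE <- -(R0 / 6) * (1 / E - 1)^(-5 / 6) / E^2
  sqrt((dRdE * sigma_E)^2 + (R * rel_sigma_R0)^2)
}
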