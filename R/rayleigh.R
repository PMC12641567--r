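# Rayleigh-limit conversions between charge, droplet diameter and mass.
#
# The Rayleigh limit is the maximum charge a spherical liquid droplet can
# hold before Coulomb fission. Globular particles electrosprayed from
# aqueous solution typically charge near this limit, so the limit charge of
# a water droplet of equal size is a useful proxy for particle diameter.
# The limiting diameter for charge z (in elementary units) is
#
#   d_R = 2 * (z e / (8 pi))^(2/3) * (eps0 * gamma)^(-1/3)
#
# with eps0 the permittivity of the medium and gamma the surface tension of
# water. The inverse, and the limit charge of a sphere of a given mass at
# unit density, follow algebraically.

#' Physical constants for Rayleigh-limit calculations
#'
#' @param epsilon0 permittivity of the surrounding medium in F/m.
#' @param gamma surface tension of water in N/m. The default 0.0720 N/m
#'   reproduces the canonical 165 e ~ 24.0 nm pairing for AAV-sized
#'   droplets.
#' @param e_charge elementary charge in C.
#' @param density droplet density in kg/m^3; the Rayleigh line is drawn for
#'   a water droplet, hence 1000 by default.
#' @return An object of class `rayleigh_constants`.
#' @examples
#' rayleigh_constants()
#' @export
rayleigh_constants <- function(epsilon0 = 8.8542e-12, gamma = 0.0720,
                               e_charge = 1.602177e-19, density = 1000) {
  check_scalar(epsilon0, "epsilon0", lower = 0, strict_lower = TRUE)
  check_scalar(gamma, "gamma", lower = 0, strict_lower = TRUE)
  check_scalar(e_charge, "e_charge", lower = 0, strict_lower = TRUE)
  check_scalar(density, "density", lower = 0, strict_lower = TRUE)
  structure(list(epsilon0 = epsilon0, gamma = gamma, e_charge = e_charge,
                 density = density),
            class = "rayleigh_constants")
}

#' Rayleigh-limit droplet diameter for a given charge
#'
#' Diameter of the spherical water droplet whose Rayleigh limit equals `z`.
#'
#' @param z charge in elementary units (vectorized, non-negative).
#' @param consts a [rayleigh_constants()] object.
#' @return Diameter in nm.
#' @examples
#' diameter_from_charge(165)  # ~24.0 nm
#' diameter_from_charge(170)  # ~24.5 nm
#' @export
diameter_from_charge <- function(z, consts = rayleigh_constants()) {
  stopifnot(inherits(consts, "rayleigh_constants"))
  if (any(!is.finite(z)) || any(z < 0)) {
    stop_invalid("charge 'z' must be non-negative")
  }
  2 * (z * consts$e_charge / (8 * pi))^(2 / 3) *
    (consts$epsilon0 * consts$gamma)^(-1 / 3) * 1e9
}

#' Rayleigh-limit charge for a given droplet diameter
#'
#' Exact algebraic inverse of [diameter_from_charge()]; returns a real
#' (non-integer) charge.
#'
#' @param d diameter in nm (vectorized, non-negative).
#' @param consts a [rayleigh_constants()] object.
#' @return Charge in elementary units.
#' @examples
#' charge_from_diameter(24.5)  # ~170 e
#' @export
charge_from_diameter <- function(d, consts = rayleigh_constants()) {
  stopifnot(inherits(consts, "rayleigh_constants"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_invalid("diameter 'd' must be non-negative")
  }
  r <- d * 1e-9 / 2
  8 * pi * sqrt(consts$epsilon0 * consts$gamma * r^3) / consts$e_charge
}

#' Rayleigh-limit charge as a function of particle mass
#'
#' Converts mass to the radius of a sphere of the configured density, then
#' returns that sphere's Rayleigh limit. This is the "Rayleigh line"
#' overlaid on two-dimensional mass/charge histograms; fragment ions whose
#' charge tracks this line are diagnostic of capsid disassembly.
#'
#' @param m mass in Da (vectorized, non-negative).
#' @param consts a [rayleigh_constants()] object.
#' @return Charge in elementary units (z scales as sqrt(m)).
#' @examples
#' rayleigh_charge_for_mass(4.93e6)  # ~175 e
#' @export
rayleigh_charge_for_mass <- function(m, consts = rayleigh_constants()) {
  stopifnot(inherits(consts, "rayleigh_constants"))
  if (any(!is.finite(m)) || any(m < 0)) {
    stop_invalid("mass 'm' must be non-negative")
  }
  m_kg <- m * .DA_TO_KG
  r <- (3 * m_kg / (4 * pi * consts$density))^(1 / 3)
  8 * pi * sqrt(consts$epsilon0 * consts$gamma * r^3) / consts$e_charge
}
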