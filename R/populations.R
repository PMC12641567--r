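# Population classification and derived quantities.
#
# Measured ions are assigned to mechanistic populations using mass windows
# around the expected species masses and the position of each ion's charge
# relative to the Rayleigh line. The gates mirror what a practitioner
# reads off a 2D mass/charge histogram: intact full capsids sit in a
# narrow mass window at high charge; disassembly fragments form a
# sub-capsid mass continuum whose charge tracks the Rayleigh limit; dimers
# sit at twice the capsid mass; aggregates carry excess protein mass above
# the intact capsid.

#' Classification gates
#'
#' @param full_mass_window relative half-width of the intact-capsid mass
#'   window (default 0.05, i.e. +/-5%).
#' @param empty_mass_window relative half-width of the empty-capsid mass
#'   window.
#' @param dimer_mass_window relative half-width of the dimer mass window
#'   (around twice the full mass).
#' @param rayleigh_band interval of charge / Rayleigh-limit-charge ratios
#'   accepted for fragments (default `c(0.80, 1.02)`).
#' @param fragment_mass_max_frac fragments must fall below this fraction
#'   of the full mass (default 0.93, excluding the intact distribution's
#'   low-mass tail).
#' @param aggregate_min_excess_da minimum mass excess above the full
#'   capsid for the aggregate gate, in Da.
#' @return An object of class `population_gates`.
#' @export
population_gates <- function(full_mass_window = 0.05,
                             empty_mass_window = 0.05,
                             dimer_mass_window = 0.05,
                             rayleigh_band = c(0.80, 1.02),
                             fragment_mass_max_frac = 0.93,
                             aggregate_min_excess_da = 2.5e5) {
  check_scalar(full_mass_window, "full_mass_window", lower = 0,
               strict_lower = TRUE)
  check_scalar(empty_mass_window, "empty_mass_window", lower = 0,
               strict_lower = TRUE)
  check_scalar(dimer_mass_window, "dimer_mass_window", lower = 0,
               strict_lower = TRUE)
  if (length(rayleigh_band) != 2L || any(!is.finite(rayleigh_band)) ||
      rayleigh_band[1] <= 0 || rayleigh_band[2] > 1.1 ||
      rayleigh_band[1] >= rayleigh_band[2]) {
    stop_invalid("'rayleigh_band' must be an increasing interval within (0, 1.1]")
  }
  check_scalar(fragment_mass_max_frac, "fragment_mass_max_frac", lower = 0,
               upper = 1, strict_lower = TRUE)
  check_scalar(aggregate_min_excess_da, "aggregate_min_excess_da", lower = 0)
  structure(list(full_mass_window = full_mass_window,
                 empty_mass_window = empty_mass_window,
                 dimer_mass_window = dimer_mass_window,
                 rayleigh_band = rayleigh_band,
                 fragment_mass_max_frac = fragment_mass_max_frac,
                 aggregate_min_excess_da = aggregate_min_excess_da),
            class = "population_gates")
}

#' Classify measured ions into mechanistic populations
#'
#' Labels each ion as `DIMER`, `INTACT_FULL`, `EMPTY`, `AGGREGATE`,
#' `FRAGMENT` or `UNASSIGNED`, applying the gates in that precedence
#' order. `FRAGMENT` requires both a mass below
#' `fragment_mass_max_frac * full_mass` and a charge within the Rayleigh
#' band for the ion's mass; `EMPTY` is only assigned when an empty-capsid
#' mass is provided.
#'
#' @param measurements data.frame with `mass_da` and `charge_e`.
#' @param full_mass_da expected intact full-capsid mass in Da (or a
#'   [capsid_species()]).
#' @param empty_mass_da expected empty-capsid mass in Da, a
#'   [capsid_species()], or `NULL` to disable the EMPTY gate.
#' @param gates a [population_gates()].
#' @param consts [rayleigh_constants()] for the Rayleigh band.
#' @return Character vector of labels, one per row (deterministic and
#'   permutation-invariant for fixed gates).
#' @export
classify_ions <- function(measurements, full_mass_da,
                          empty_mass_da = NULL,
                          gates = population_gates(),
                          consts = rayleigh_constants()) {
  stopifnot(inherits(gates, "population_gates"))
  if (inherits(full_mass_da, "capsid_species")) {
    full_mass_da <- species_mass(full_mass_da)
  }
  if (inherits(empty_mass_da, "capsid_species")) {
    empty_mass_da <- species_mass(empty_mass_da)
  }
  check_scalar(full_mass_da, "full_mass_da", lower = 0, strict_lower = TRUE)
  m <- measurements$mass_da
  z <- measurements$charge_e
  if (is.null(m) || is.null(z)) {
    stop_invalid("measurements must have 'mass_da' and 'charge_e' columns")
  }
  n <- length(m)
  if (n == 0L) return(character(0))
  labels <- rep("UNASSIGNED", n)
  in_window <- function(x, center, rel) {
    abs(x - center) <= rel * center
  }
  zr <- rayleigh_charge_for_mass(pmax(m, 0), consts)
  ratio <- ifelse(zr > 0, z / zr, Inf)
  is_dimer <- in_window(m, 2 * full_mass_da, gates$dimer_mass_window)
  is_full <- in_window(m, full_mass_da, gates$full_mass_window)
  is_empty <- if (!is.null(empty_mass_da)) {
    in_window(m, empty_mass_da, gates$empty_mass_window)
  } else rep(FALSE, n)
  is_agg <- m > full_mass_da + gates$aggregate_min_excess_da
  is_frag <- m < gates$fragment_mass_max_frac * full_mass_da &
    ratio >= gates$rayleigh_band[1] & ratio <= gates$rayleigh_band[2]
  labels[is_frag] <- "FRAGMENT"
  labels[is_agg] <- "AGGREGATE"
  labels[is_empty] <- "EMPTY"
  labels[is_full] <- "INTACT_FULL"
  labels[is_dimer] <- "DIMER"
  labels
}

#' Population abundance fractions
#'
#' @param labels character vector of classification labels (non-empty).
#' @return Named numeric vector of fractions summing to 1.
#' @export
population_fractions <- function(labels) {
  if (!length(labels)) stop_invalid("'labels' must be non-empty")
  tab <- table(labels)
  fr <- as.numeric(tab) / length(labels)
  names(fr) <- names(tab)
  fr
}

#' Number of bound ligands from a mass increment
#'
#' `round((mass - base_mass) / ligand_da)`; negative estimates clamp to 0
#' with attribute `clamped = TRUE`.
#'
#' @param mass_da measured complex mass in Da (vectorized).
#' @param base_mass_da unliganded species mass in Da.
#' @param ligand_da ligand mass in Da (> 0), e.g. 3.4e4 for a ~34 kDa
#'   nuclease.
#' @return Integer vector of bound-ligand counts.
#' @examples
#' estimate_bound_count(5.10e6, 4.60e6, 3.4e4)  # 15
#' @export
estimate_bound_count <- function(mass_da, base_mass_da, ligand_da) {
  check_scalar(base_mass_da, "base_mass_da", lower = 0)
  check_scalar(ligand_da, "ligand_da", lower = 0, strict_lower = TRUE)
  raw <- round((mass_da - base_mass_da) / ligand_da)
  clamped <- raw < 0
  out <- as.integer(pmax(raw, 0))
  if (any(clamped)) attr(out, "clamped") <- TRUE
  out
}

#' Charge trend versus number of bound ligands
#'
#' Ordinary least squares of measured charge on the estimated bound-ligand
#' count. A negative slope quantifies the structural compaction that
#' accompanies ligand binding.
#'
#' @param measurements data.frame with `mass_da` and `charge_e`.
#' @param base_mass_da unliganded species mass in Da.
#' @param ligand_da ligand mass in Da.
#' @return List with `slope_e_per_ligand`, `intercept_e`, `n`.
#' @export
charge_vs_bound_slope <- function(measurements, base_mass_da, ligand_da) {
  nb <- estimate_bound_count(measurements$mass_da, base_mass_da, ligand_da)
  z <- measurements$charge_e
  if (length(unique(nb)) < 2L) {
    stop_invalid("need at least 2 distinct bound counts for a trend")
  }
  fit <- stats::lm.fit(cbind(1, as.numeric(nb)), z)
  list(slope_e_per_ligand = unname(fit$coefficients[2]),
       intercept_e = unname(fit$coefficients[1]),
       n = length(z))
}
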