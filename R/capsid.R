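# Capsid mass accounting: VP stoichiometry and additive species masses.
#
# An AAV capsid is built from 60 copies of three viral proteins (VP1, VP2,
# VP3) at an average stoichiometry near 1:1:10, plus an optional
# single-stranded DNA cargo, buffer-salt adducts, and bound ligands such as
# nuclease enzymes. All mass contributions are additive.

#' VP subunit masses
#'
#' Container for the masses of the three AAV capsid proteins. Defaults are
#' the rounded literature values for AAV9: VP1 83.5 kDa, VP2 68.6 kDa,
#' VP3 62.0 kDa.
#'
#' @param vp1_da,vp2_da,vp3_da subunit masses in Da; all strictly positive.
#' @return An object of class `vp_masses`.
#' @examples
#' vp_masses()
#' @export
vp_masses <- function(vp1_da = 83500, vp2_da = 68600, vp3_da = 62000) {
  check_scalar(vp1_da, "vp1_da", lower = 0, strict_lower = TRUE)
  check_scalar(vp2_da, "vp2_da", lower = 0, strict_lower = TRUE)
  check_scalar(vp3_da, "vp3_da", lower = 0, strict_lower = TRUE)
  structure(list(vp1_da = vp1_da, vp2_da = vp2_da, vp3_da = vp3_da),
            class = "vp_masses")
}

#' Define a capsid species
#'
#' A molecular species whose mass is fully determined by its composition:
#' VP subunit counts, DNA cargo, aggregate buffer-adduct mass, bound
#' ligands, and a multiplicity (1 for a monomeric capsid, 2 for a dimer).
#'
#' For canonical capsids `sum(vp_counts)` equals `60 * multiplicity`; the
#' constraint is deliberately not enforced so that fragment species (capsids
#' that have lost constituent proteins) can be represented.
#'
#' @param vp_counts integer vector `c(n1, n2, n3)` of VP1/VP2/VP3 copies.
#' @param cargo_da DNA cargo mass in Da (per capsid unit; doubled in a dimer).
#' @param adduct_da aggregate nonvolatile-salt adduct mass in Da. Adduction
#'   is modeled as a single lump sum because only aggregate shifts are
#'   observable in the mass histogram.
#' @param n_ligand number of bound ligand copies.
#' @param ligand_da mass of one ligand in Da.
#' @param multiplicity 1 = monomer, 2 = dimer, ...
#' @param label free-text population tag.
#' @return An object of class `capsid_species`.
#' @examples
#' capsid_species(c(5, 5, 50), cargo_da = 1.05e6, label = "AAV9_CMV_GFP")
#' @export
capsid_species <- function(vp_counts, cargo_da = 0, adduct_da = 0,
                           n_ligand = 0, ligand_da = 0, multiplicity = 1,
                           label = "") {
  if (length(vp_counts) != 3L || any(!is.finite(vp_counts)) ||
      any(vp_counts < 0) || any(vp_counts != round(vp_counts))) {
    stop_invalid("'vp_counts' must be three non-negative integers")
  }
  check_scalar(cargo_da, "cargo_da", lower = 0)
  check_scalar(adduct_da, "adduct_da", lower = 0)
  n_ligand <- check_count(n_ligand, "n_ligand")
  check_scalar(ligand_da, "ligand_da", lower = 0)
  multiplicity <- check_count(multiplicity, "multiplicity", lower = 1L)
  structure(list(vp_counts = as.integer(vp_counts), cargo_da = cargo_da,
                 adduct_da = adduct_da, n_ligand = n_ligand,
                 ligand_da = ligand_da, multiplicity = multiplicity,
                 label = as.character(label)),
            class = "capsid_species")
}

#' @export
print.capsid_species <- function(x, ...) {
  cat(sprintf("<capsid_species> %s\n", if (nzchar(x$label)) x$label else "(unnamed)"))
  cat(sprintf("  VP1:VP2:VP3 = %d:%d:%d  multiplicity = %d\n",
              x$vp_counts[1], x$vp_counts[2], x$vp_counts[3], x$multiplicity))
  cat(sprintf("  cargo %.4g Da, adducts %.4g Da, %d x %.4g Da ligand\n",
              x$cargo_da, x$adduct_da, x$n_ligand, x$ligand_da))
  cat(sprintf("  mass = %.6g Da (%.3f MDa)\n", species_mass(x),
              species_mass(x) / 1e6))
  invisible(x)
}

#' Integer VP counts from a stoichiometry ratio
#'
#' Apportions `total_subunits` among VP1/VP2/VP3 proportionally to `ratio`
#' using largest-remainder rounding, so counts always sum exactly to
#' `total_subunits`. Remainder ties are broken toward VP3 (then VP2), the
#' majority subunit.
#'
#' @param total_subunits positive integer, e.g. 60 for an AAV capsid.
#' @param ratio three non-negative weights, e.g. `c(1, 1, 10)`; must not be
#'   all zero.
#' @return Integer vector of length 3 summing to `total_subunits`.
#' @examples
#' vp_counts_from_ratio(60, c(1, 1, 10))  # 5 5 50
#' vp_counts_from_ratio(60, c(0, 0, 1))   # VP3-only virus-like particle
#' @export
vp_counts_from_ratio <- function(total_subunits, ratio) {
  total_subunits <- check_count(total_subunits, "total_subunits", lower = 1L)
  if (length(ratio) != 3L || any(!is.finite(ratio)) || any(ratio < 0)) {
    stop_invalid("'ratio' must be three non-negative finite weights")
  }
  if (sum(ratio) == 0) stop_invalid("'ratio' must not be all zero")
  quota <- total_subunits * ratio / sum(ratio)
  counts <- floor(quota)
  short <- total_subunits - sum(counts)
  if (short > 0) {
    # rank remainders descending; ties go to the higher VP index (VP3 first)
    ord <- order(quota - counts, seq_len(3L), decreasing = TRUE)
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Sample a VP stoichiometry
#'
#' Multinomial draw of VP1/VP2/VP3 counts, modeling the virion-to-virion
#' variability of capsid composition around the average stoichiometry.
#'
#' @param total_subunits positive integer number of subunits.
#' @param probs probability triple summing to 1 (tolerance 1e-9).
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return Integer vector of length 3 summing to `total_subunits`.
#' @examples
#' sample_stoichiometry(60, c(1, 1, 10) / 12, seed = 1)
#' @export
sample_stoichiometry <- function(total_subunits, probs, seed = NULL) {
  total_subunits <- check_count(total_subunits, "total_subunits", lower = 1L)
  if (length(probs) != 3L || any(!is.finite(probs))) {
    stop_invalid("'probs' must be three finite probabilities")
  }
  if (any(probs < 0)) stop_invalid("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) {
    stop_invalid("'probs' must sum to 1 (got %.12g)", sum(probs))
  }
  with_seed(seed, as.integer(drop(stats::rmultinom(1, total_subunits, probs))))
}

#' Deterministic mass of a capsid species
#'
#' Total mass in Da:
#' `multiplicity * (sum(vp_counts * vp_masses) + cargo_da) + adduct_da +
#' n_ligand * ligand_da`.
#'
#' @param species a [capsid_species()].
#' @param vp a [vp_masses()] object; defaults to the AAV9 subunit masses.
#' @return Mass in Da.
#' @examples
#' species_mass(capsid_species(c(5, 5, 50), cargo_da = 1.05e6)) / 1e6  # 4.91 MDa
#' @export
species_mass <- function(species, vp = vp_masses()) {
  stopifnot(inherits(species, "capsid_species"), inherits(vp, "vp_masses"))
  protein <- sum(species$vp_counts * c(vp$vp1_da, vp$vp2_da, vp$vp3_da))
  species$multiplicity * (protein + species$cargo_da) +
    species$adduct_da + species$n_ligand * species$ligand_da
}

#' Built-in capsid species registry
#'
#' Named reference species used throughout the package:
#' \describe{
#'   \item{AAV9_CMV_GFP}{wild-type AAV9 (5:5:50) with a 1.05 MDa CMV-GFP
#'     cargo; calculated mass 4.91 MDa.}
#'   \item{VLP_CAG_GFP}{VP3-only virus-like particle (0:0:60) with a
#'     0.84 MDa CAG-GFP cargo.}
#'   \item{AAV9_CAG_GFP}{wild-type AAV9 with the 0.84 MDa CAG-GFP cargo.}
#'   \item{AAV9_empty}{wild-type AAV9 capsid without cargo (~3.9 MDa).}
#' }
#'
#' @param name species name; omit to get the full named list.
#' @return A [capsid_species()] or a named list of them.
#' @examples
#' species_mass(species_registry("AAV9_CMV_GFP"))
#' @export
species_registry <- function(name = NULL) {
  reg <- list(
    AAV9_CMV_GFP = capsid_species(c(5, 5, 50), cargo_da = 1.05e6,
                                  label = "AAV9_CMV_GFP"),
    VLP_CAG_GFP  = capsid_species(c(0, 0, 60), cargo_da = 0.84e6,
                                  label = "VLP_CAG_GFP"),
    AAV9_CAG_GFP = capsid_species(c(5, 5, 50), cargo_da = 0.84e6,
                                  label = "AAV9_CAG_GFP"),
    AAV9_empty   = capsid_species(c(5, 5, 50), cargo_da = 0,
                                  label = "AAV9_empty")
  )
  if (is.null(name)) return(reg)
  if (!name %in% names(reg)) {
    stop_invalid("unknown species '%s'; available: %s", name,
                 paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}
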