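# Scenario presets and ground-truth ion ensembles.
#
# A scenario describes a mixture of particle populations, each with a mass
# model and a charge model, emulating the ion ensembles seen in CDMS
# experiments on AAV preparations: intact capsids with one or more charge
# conformers, salt-adducted species, Rayleigh-limited fragment continua
# from capsid disassembly, dimers, aggregates, and nuclease-bound capsids.
#
# Mass models: gaussian(mean, sd); uniform(lo, hi); offset_uniform(base +
# U(lo, hi)); ligand(base + n * ligand_da with n ~ discrete uniform).
# Charge models: gmm (Gaussian mixture over conformer centroids);
# rayleigh_band (charge = Rayleigh limit of the drawn mass times
# U(lo, hi)); linear_ligand (intercept + slope * n_bound + noise).

mass_model <- function(kind, ...) c(list(kind = kind), list(...))
charge_model <- function(kind, ...) c(list(kind = kind), list(...))

component <- function(label, weight, mass, charge) {
  list(label = label, weight = weight, mass = mass, charge = charge)
}

# Preset builders. Intact-species "true" masses are the centroids observed
# for the corresponding buffer conditions (simulator ground truth), and the
# conformer charge centroids are the fitted values for those conditions;
# component weights and widths are package defaults (see the methods
# vignette) since only centroids are reported.
.presets <- list(
  aa_neutral = function() {
    list(
      full_mass_da = 4.93e6,
      components = list(
        intact = component("INTACT_FULL", 1,
          mass_model("gaussian", mean = 4.93e6, sd = 5e4),
          charge_model("gmm", centroids = c(165, 150), sds = c(4, 5),
                       weights = c(0.85, 0.15)))
      ))
  },
  pbs_neutral = function() {
    list(
      full_mass_da = 5.31e6,  # 4.93 MDa + 0.38 MDa salt adducts
      components = list(
        intact = component("INTACT_FULL", 1,
          mass_model("gaussian", mean = 5.31e6, sd = 1e5),
          charge_model("gmm",
                       centroids = c(171, 159, 147, 137, 128, 117, 102),
                       sds = rep(4, 7), weights = rep(1 / 7, 7)))
      ))
  },
  vlp_pbs = function() {
    list(
      full_mass_da = 4.93e6,  # 4.51 MDa VLP + 0.42 MDa salt adducts
      components = list(
        intact = component("INTACT_FULL", 1,
          mass_model("gaussian", mean = 4.93e6, sd = 1e5),
          charge_model("gmm", centroids = c(167, 148, 131, 120, 102),
                       sds = rep(4, 5), weights = rep(1 / 5, 5)))
      ))
  },
  pbs_ph4_37c = function() {
    list(
      full_mass_da = 5.27e6,
      components = list(
        intact = component("INTACT_FULL", 1,
          mass_model("gaussian", mean = 5.27e6, sd = 1e5),
          charge_model("gmm", centroids = c(166, 159, 145, 133, 120, 108),
                       sds = rep(4, 6), weights = rep(1 / 6, 6)))
      ))
  },
  aa_ph4_37c = function() {
    full <- 5.22e6
    list(
      full_mass_da = full,
      empty_mass_da = 3.9e6,
      components = list(
        intact = component("INTACT_FULL", 0.65,
          mass_model("gaussian", mean = full, sd = 5e4),
          charge_model("gmm", centroids = c(165, 150), sds = c(4, 5),
                       weights = c(0.8, 0.2))),
        fragment = component("FRAGMENT", 0.25,
          mass_model("uniform", lo = 1e6, hi = 0.90 * full),
          charge_model("rayleigh_band", lo = 0.85, hi = 1.00)),
        aggregate = component("AGGREGATE", 0.05,
          mass_model("offset_uniform", base = full, lo = 3e5, hi = 1.5e6),
          charge_model("gmm", centroids = 165, sds = 5, weights = 1)),
        dimer = component("DIMER", 0.05,
          mass_model("gaussian", mean = 2 * full, sd = 0.02 * 2 * full),
          charge_model("rayleigh_band", lo = 0.98, hi = 1.06))
      ))
  },
  freeze_thaw = function(degraded_weight = 0.16) {
    check_scalar(degraded_weight, "degraded_weight", lower = 0, upper = 1)
    full <- 4.6e6
    comps <- list(
      intact = component("INTACT_FULL", 1 - degraded_weight,
        mass_model("gaussian", mean = full, sd = 6e4),
        charge_model("gmm", centroids = 160, sds = 4, weights = 1)))
    if (degraded_weight > 0) {
      comps$fragment <- component("FRAGMENT", 0.75 * degraded_weight,
        mass_model("uniform", lo = 1e6, hi = 0.90 * full),
        charge_model("rayleigh_band", lo = 0.85, hi = 1.00))
      comps$aggregate <- component("AGGREGATE", 0.25 * degraded_weight,
        mass_model("offset_uniform", base = full, lo = 3e5, hi = 1.5e6),
        charge_model("gmm", centroids = 160, sds = 5, weights = 1))
    }
    list(full_mass_da = full, empty_mass_da = full - 0.84e6,
         components = comps)
  },
  nuclease = function() {
    full <- 4.6e6
    list(
      full_mass_da = full,
      ligand_da = 3.4e4,
      components = list(
        bound = component("INTACT_FULL", 0.97,
          mass_model("ligand", base = full, ligand_da = 3.4e4,
                     n_min = 0, n_max = 20),
          # endpoints: 0 bound -> ~160 e, 15 bound -> ~120 e
          charge_model("linear_ligand", intercept = 160,
                       slope = -40 / 15, sd = 3)),
        offtrend = component("OFFTREND", 0.03,
          mass_model("gaussian", mean = 5.0e6, sd = 5e4),
          charge_model("gmm", centroids = 100, sds = 3, weights = 1))
      ))
  }
)

#' List available scenario presets
#'
#' @return Character vector of preset names accepted by [build_scenario()].
#' @export
scenario_presets <- function() names(.presets)

#' Build a scenario configuration from a preset
#'
#' Resolves a named preset into a fully specified scenario: a weighted
#' mixture of populations, each with a mass model and a charge model.
#' Presets cover neutral-pH ammonium acetate and PBS conditions, the
#' VP3-only particle in PBS, acidified 37 degree incubations in both
#' buffers, one freeze-thaw cycle, and nuclease binding.
#'
#' @param preset_name one of [scenario_presets()].
#' @param overrides named list of overrides. Names matching a preset
#'   parameter (e.g. `degraded_weight` for `"freeze_thaw"`) are passed to
#'   the preset builder; other names are dot-separated key paths into the
#'   resolved scenario, e.g. `"components.intact.weight"`.
#' @return An object of class `scenario_config` with elements
#'   `name`, `components`, `full_mass_da` and (where meaningful)
#'   `empty_mass_da` and `ligand_da`.
#' @examples
#' build_scenario("aa_neutral")
#' build_scenario("freeze_thaw", list(degraded_weight = 0))
#' @export
build_scenario <- function(preset_name, overrides = list()) {
  if (!is.character(preset_name) || length(preset_name) != 1L ||
      !preset_name %in% names(.presets)) {
    stop_invalid("unknown preset '%s'; valid presets: %s",
                 as.character(preset_name)[1],
                 paste(names(.presets), collapse = ", "))
  }
  builder <- .presets[[preset_name]]
  formal_names <- names(formals(builder))
  is_param <- names(overrides) %in% formal_names
  sc <- do.call(builder, overrides[is_param])
  for (key in names(overrides)[!is_param]) {
    sc <- assign_key_path(sc, strsplit(key, ".", fixed = TRUE)[[1]],
                          overrides[[key]], key)
  }
  sc$name <- preset_name
  w <- vapply(sc$components, `[[`, numeric(1), "weight")
  if (any(w < 0) || sum(w) <= 0) {
    stop_invalid("component weights must be non-negative and not all zero")
  }
  sc$components <- lapply(sc$components, function(cp) {
    cp$weight <- cp$weight / sum(w)
    cp
  })
  structure(sc, class = "scenario_config")
}

assign_key_path <- function(x, path, value, key) {
  if (length(path) == 0L) return(value)
  if (!is.list(x) || !path[1] %in% names(x)) {
    stop_invalid("unknown override key '%s' (no element '%s')", key, path[1])
  }
  x[[path[1]]] <- assign_key_path(x[[path[1]]], path[-1], value, key)
  x
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %s (full mass %.3g MDa)\n",
              x$name, x$full_mass_da / 1e6))
  for (nm in names(x$components)) {
    cp <- x$components[[nm]]
    cat(sprintf("  %-10s w=%.3f  label=%s  mass=%s  charge=%s\n", nm,
                cp$weight, cp$label, cp$mass$kind, cp$charge$kind))
  }
  invisible(x)
}

draw_mass <- function(mm, n) {
  switch(mm$kind,
    gaussian = stats::rnorm(n, mm$mean, mm$sd),
    uniform = stats::runif(n, mm$lo, mm$hi),
    offset_uniform = mm$base + stats::runif(n, mm$lo, mm$hi),
    ligand = {
      nb <- sample(mm$n_min:mm$n_max, n, replace = TRUE)
      structure(mm$base + nb * mm$ligand_da, n_bound = nb)
    },
    stop_invalid("unknown mass model '%s'", mm$kind))
}

draw_charge <- function(cm, mass_da, n_bound, consts) {
  n <- length(mass_da)
  switch(cm$kind,
    gmm = {
      j <- sample.int(length(cm$centroids), n, replace = TRUE,
                      prob = cm$weights)
      stats::rnorm(n, cm$centroids[j], cm$sds[j])
    },
    rayleigh_band = rayleigh_charge_for_mass(mass_da, consts) *
      stats::runif(n, cm$lo, cm$hi),
    linear_ligand = cm$intercept + cm$slope * n_bound +
      stats::rnorm(n, 0, cm$sd),
    stop_invalid("unknown charge model '%s'", cm$kind))
}

#' Sample a ground-truth ion ensemble
#'
#' Draws `n_ions` ions from the scenario's population mixture: each ion
#' gets a true mass, a true charge, the oscillation frequency implied by
#' the trap calibration, and its population label.
#'
#' @param scenario a [build_scenario()] result.
#' @param n_ions number of ions to draw (> 0).
#' @param cal a [trap_calibration()].
#' @param seed integer seed; identical inputs give identical ensembles.
#' @param consts [rayleigh_constants()] used by Rayleigh-band charge models.
#' @return A data.frame with columns `ion_id`, `population`, `mass_da`,
#'   `charge_e`, `f0_hz`, `mass_loss_rate_da_per_s`, `n_bound`.
#' @examples
#' head(sample_ion_ensemble(build_scenario("aa_neutral"), 5, seed = 1))
#' @export
sample_ion_ensemble <- function(scenario, n_ions, cal = trap_calibration(),
                                seed = NULL,
                                consts = rayleigh_constants()) {
  stopifnot(inherits(scenario, "scenario_config"))
  n_ions <- check_count(n_ions, "n_ions", lower = 1L)
  with_seed(seed, {
    w <- vapply(scenario$components, `[[`, numeric(1), "weight")
    comp_idx <- sample.int(length(w), n_ions, replace = TRUE, prob = w)
    mass <- numeric(n_ions)
    charge <- numeric(n_ions)
    n_bound <- rep(NA_integer_, n_ions)
    pop <- character(n_ions)
    for (j in seq_along(scenario$components)) {
      sel <- which(comp_idx == j)
      if (!length(sel)) next
      cp <- scenario$components[[j]]
      m <- draw_mass(cp$mass, length(sel))
      nb <- attr(m, "n_bound")
      mass[sel] <- as.numeric(m)
      if (!is.null(nb)) n_bound[sel] <- nb
      charge[sel] <- draw_charge(cp$charge, mass[sel], nb, consts)
      pop[sel] <- cp$label
    }
    data.frame(ion_id = seq_len(n_ions), population = pop,
               mass_da = mass, charge_e = charge,
               f0_hz = frequency_for_ion(mass, charge, cal),
               mass_loss_rate_da_per_s = 0,
               n_bound = n_bound)
  })
}

#' Ideal measurements from a ground-truth ensemble
#'
#' Converts a ground-truth ensemble into an ion-measurement table by adding
#' the measurement uncertainty of the full trace analysis analytically
#' (per-ion charge SD and relative frequency SD), without synthesizing and
#' refitting time-domain traces. Useful for large-ensemble downstream
#' analyses (histogram decomposition, population classification) whose
#' trace-level fidelity is validated separately on smaller ensembles.
#'
#' @param ensemble a [sample_ion_ensemble()] result.
#' @param cal a [trap_calibration()].
#' @param seed integer seed.
#' @param charge_sd per-ion charge standard deviation in e (default 1.0,
#'   the full-trap precision at the default noise level).
#' @param freq_rel_sd relative standard deviation of the recovered
#'   fundamental frequency.
#' @return An ion-measurement data.frame (see [write_ion_table()] for the
#'   schema); the ground-truth `population` and `n_bound` columns are kept
#'   as extra columns.
#' @export
measurements_from_truth <- function(ensemble, cal = trap_calibration(),
                                    seed = NULL, charge_sd = 1.0,
                                    freq_rel_sd = 1e-5) {
  stopifnot(is.data.frame(ensemble))
  check_scalar(charge_sd, "charge_sd", lower = 0)
  check_scalar(freq_rel_sd, "freq_rel_sd", lower = 0)
  with_seed(seed, {
    n <- nrow(ensemble)
    f0 <- ensemble$f0_hz * (1 + stats::rnorm(n, 0, freq_rel_sd))
    z <- ensemble$charge_e + stats::rnorm(n, 0, charge_sd)
    mz <- mz_from_frequency(f0, cal)
    data.frame(ion_id = ensemble$ion_id, f0_hz = f0, mz_th = mz,
               charge_e = z, mass_da = mz * z,
               n_segments_used = NA_integer_,
               drift_hz_per_s = 0, flags = "",
               population = ensemble$population,
               n_bound = ensemble$n_bound,
               stringsAsFactors = FALSE)
  })
}
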