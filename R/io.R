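# Tables, run configuration, and the end-to-end pipeline.

.ION_TABLE_COLS <- c("ion_id", "f0_hz", "mz_th", "charge_e", "mass_da",
                     "n_segments_used", "drift_hz_per_s", "flags")
.ION_TABLE_NUMERIC <- c("ion_id", "f0_hz", "mz_th", "charge_e", "mass_da",
                        "n_segments_used", "drift_hz_per_s")

#' Write an ion-measurement table
#'
#' Comma-separated UTF-8 text with a header; numeric fields are written at
#' 12 significant digits so a write/read round trip is lossless at that
#' precision. Extra (non-schema) columns are preserved.
#'
#' @param measurements data.frame containing at least the schema columns
#'   `ion_id, f0_hz, mz_th, charge_e, mass_da, n_segments_used,
#'   drift_hz_per_s, flags`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ion_table <- function(measurements, path) {
  missing_cols <- setdiff(.ION_TABLE_COLS, names(measurements))
  if (length(missing_cols)) {
    stop_invalid("measurements are missing required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  out <- measurements
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- format_sig12(out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ion-measurement table
#'
#' Validates the schema: a missing required column raises an error naming
#' the column; a row whose numeric field does not parse raises an error
#' with its line number. Extra columns are kept as read.
#'
#' @param path CSV file written by [write_ion_table()] (or compatible).
#' @return data.frame of measurements.
#' @export
read_ion_table <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(.ION_TABLE_COLS, names(raw))
  if (length(missing_cols)) {
    stop_invalid("ion table %s is missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", "))
  }
  for (cn in names(raw)) {
    if (!cn %in% .ION_TABLE_NUMERIC) next
    vals <- suppressWarnings(as.numeric(raw[[cn]]))
    bad <- which(is.na(vals) & !(raw[[cn]] %in% c("NA", "")))
    if (length(bad)) {
      stop_invalid("malformed value '%s' in column '%s' at line %d of %s",
                   raw[[cn]][bad[1]], cn, bad[1] + 1L, path)
    }
    raw[[cn]] <- vals
  }
  raw
}

#' Build a validated run configuration
#'
#' A single key-value document (nested named list, readable from YAML via
#' [read_run_config()]) describing a full pipeline run. Unknown top-level
#' keys are rejected.
#'
#' @param scenario preset name (see [scenario_presets()]).
#' @param n_ions ensemble size.
#' @param seed integer seed controlling every random stage.
#' @param out_dir output directory.
#' @param analysis `"truth"` (analytic measurement noise on the
#'   ground-truth ensemble; fast) or `"trace"` (synthesize and refit full
#'   time-domain traces).
#' @param overrides scenario overrides passed to [build_scenario()].
#' @param calibration,acquisition,gates,rayleigh optional named lists of
#'   arguments for [trap_calibration()], [acquisition_config()],
#'   [population_gates()], [rayleigh_constants()].
#' @param mixture named list: `axis` (`"charge"`/`"mass"`), `k`
#'   (integer or `"auto"`), optional `init`.
#' @param write_traces if `TRUE` (trace mode), persist the synthetic
#'   traces with [write_trace_set()].
#' @return An object of class `run_config` with all defaults resolved.
#' @export
run_config <- function(scenario, n_ions = 1000, seed = 1,
                       out_dir = "cdms_run", analysis = c("truth", "trace"),
                       overrides = list(), calibration = list(),
                       acquisition = list(), gates = list(),
                       rayleigh = list(),
                       mixture = list(axis = "charge", k = "auto"),
                       write_traces = FALSE) {
  analysis <- match.arg(analysis)
  n_ions <- check_count(n_ions, "n_ions", lower = 1L)
  seed <- check_count(seed, "seed")
  cfg <- list(
    scenario = build_scenario(scenario, overrides),
    scenario_name = scenario,
    overrides = overrides,
    n_ions = n_ions, seed = seed, out_dir = out_dir, analysis = analysis,
    calibration = do.call(trap_calibration, calibration),
    acquisition = do.call(acquisition_config, acquisition),
    gates = do.call(population_gates, gates),
    rayleigh = do.call(rayleigh_constants, rayleigh),
    mixture = utils::modifyList(list(axis = "charge", k = "auto",
                                     init = NULL), mixture),
    write_traces = isTRUE(write_traces)
  )
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML document
#'
#' Top-level keys must be arguments of [run_config()]; anything else is
#' rejected with the list of valid keys.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  valid <- names(formals(run_config))
  unknown <- setdiff(names(doc), valid)
  if (length(unknown)) {
    stop_invalid("unknown config key(s): %s; valid keys: %s",
                 paste(unknown, collapse = ", "),
                 paste(valid, collapse = ", "))
  }
  do.call(run_config, doc)
}

#' Run the full pipeline: simulate, analyze, fit, classify
#'
#' Executes the four pipeline stages and writes all artifacts to
#' `config$out_dir`: the ground-truth table, the ion-measurement table,
#' charge and mass histograms, the fitted mixture components, per-ion
#' labels, and a YAML summary containing the seed, package version and
#' every resolved setting so the run is reproducible from the summary
#' alone. A stage failure aborts with the stage name; artifacts of
#' completed stages are left in place.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `measurements`, `labels`, `fractions`,
#'   `mixture_fit`, `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_invalid("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e))
    })
  }
  sc <- config$scenario

  truth <- stage("simulate", {
    ens <- sample_ion_ensemble(sc, config$n_ions, config$calibration,
                               seed = config$seed, consts = config$rayleigh)
    utils::write.csv(ens, file.path(config$out_dir, "ground_truth.csv"),
                     row.names = FALSE)
    ens
  })

  meas <- stage("analyze", {
    if (config$analysis == "trace") {
      traces <- lapply(seq_len(nrow(truth)), function(i) {
        synthesize_trace(truth[i, ], config$calibration,
                         config$acquisition, seed = config$seed + i)
      })
      if (config$write_traces) {
        write_trace_set(traces, file.path(config$out_dir, "traces"))
      }
      m <- analyze_trace_set(traces, config$calibration, config$acquisition)
    } else {
      m <- measurements_from_truth(truth, config$calibration,
                                   seed = config$seed + 1L)
    }
    write_ion_table(m, file.path(config$out_dir, "ion_table.csv"))
    m
  })

  mix <- stage("fit", {
    hz <- histogram1d(meas$charge_e, axis = "charge")
    hm <- histogram1d(meas$mass_da, axis = "mass")
    utils::write.csv(histogram_table(hz),
                     file.path(config$out_dir, "charge_histogram.csv"),
                     row.names = FALSE)
    utils::write.csv(histogram_table(hm),
                     file.path(config$out_dir, "mass_histogram.csv"),
                     row.names = FALSE)
    h <- if (identical(config$mixture$axis, "mass")) hm else hz
    fit <- fit_gaussian_mixture(h, k = config$mixture$k,
                                init = config$mixture$init)
    utils::write.csv(cbind(coef(fit),
                           converged = fit$converged, rss = fit$rss),
                     file.path(config$out_dir, "components.csv"),
                     row.names = FALSE)
    fit
  })

  cls <- stage("classify", {
    labels <- classify_ions(meas, sc$full_mass_da,
                            empty_mass_da = sc$empty_mass_da,
                            gates = config$gates, consts = config$rayleigh)
    out <- cbind(meas, label = labels)
    utils::write.csv(out, file.path(config$out_dir, "labels.csv"),
                     row.names = FALSE)
    labels
  })

  fractions <- population_fractions(cls)
  mass_centroid <- centroid(histogram1d(meas$mass_da, axis = "mass"))
  summary <- list(
    package_version = as.character(utils::packageVersion("cdmstrap")),
    seed = config$seed,
    scenario = config$scenario_name,
    overrides = config$overrides,
    n_ions = config$n_ions,
    n_measured = nrow(meas),
    analysis = config$analysis,
    calibration = unclass(config$calibration),
    acquisition = unclass(config$acquisition),
    gates = unclass(config$gates),
    rayleigh = unclass(config$rayleigh),
    mixture_k = mix$k,
    mixture_centroids = mix$components$centroid,
    mass_centroid_da = as.numeric(mass_centroid),
    population_fractions = as.list(fractions)
  )
  yaml::write_yaml(summary, file.path(config$out_dir, "summary.yaml"))
  invisible(list(measurements = meas, labels = cls, fractions = fractions,
                 mixture_fit = mix, summary = summary))
}
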