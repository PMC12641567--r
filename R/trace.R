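# Time-domain trace synthesis: the stand-in for the instrument.
#
# An ion oscillating in the trap induces charge on the detection tube
# during the fraction of each period it spends inside it, so the ideal
# signal is a rectangular pulse train at the ion's oscillation frequency
# with plateau height gain * charge and duty cycle d_c, on top of white
# detector noise. If the ion loses mass during the trap event its
# frequency rises consistently with m/z = C / f^2; the pulse phase is then
# the integral of the instantaneous frequency.

#' Synthesize a single-ion trap trace
#'
#' @param ion one row of a [sample_ion_ensemble()] data.frame, or any list
#'   with `mass_da`, `charge_e` and optionally `mass_loss_rate_da_per_s`.
#' @param cal a [trap_calibration()].
#' @param acq an [acquisition_config()]. The fundamental must satisfy
#'   `f0 < sample_rate / (2 * max_harmonic)` so that all fitted harmonics
#'   are alias-free.
#' @param seed integer seed for the noise and starting phase.
#' @return An object of class `cdms_trace`: list with `signal` (numeric
#'   vector), `sample_rate_hz`, `trap_ms`, and the ion's ground truth.
#' @examples
#' ion <- list(mass_da = 4.93e6, charge_e = 165)
#' tr <- synthesize_trace(ion, acq = acquisition_config(trap_ms = 25), seed = 1)
#' @export
synthesize_trace <- function(ion, cal = trap_calibration(),
                             acq = acquisition_config(), seed = NULL) {
  stopifnot(inherits(cal, "trap_calibration"),
            inherits(acq, "acquisition_config"))
  mass <- ion$mass_da
  charge <- ion$charge_e
  rate <- ion$mass_loss_rate_da_per_s
  if (is.null(rate) || is.na(rate)) rate <- 0
  check_scalar(mass, "mass_da", lower = 0, strict_lower = TRUE)
  check_scalar(charge, "charge_e", lower = 0)
  f0 <- if (charge > 0) frequency_for_ion(mass, charge, cal) else 0
  f_nyq <- acq$sample_rate_hz / (2 * acq$max_harmonic)
  t_end <- acq$trap_ms / 1000
  if (rate > 0 && rate * t_end >= mass) {
    stop_invalid("mass_loss_rate consumes the whole ion within the trap event")
  }
  f_end <- if (charge > 0) {
    frequency_for_ion(mass - rate * t_end, charge, cal)
  } else 0
  if (max(f0, f_end) >= f_nyq) {
    stop_invalid(paste0("fundamental %.0f Hz aliases fitted harmonics ",
                        "(limit %.0f Hz = sample_rate / (2 * max_harmonic))"),
                 max(f0, f_end), f_nyq)
  }
  n <- round(acq$sample_rate_hz * acq$trap_ms / 1000)
  t <- (seq_len(n) - 1) / acq$sample_rate_hz
  with_seed(seed, {
    if (charge > 0) {
      # phase in cycles: integral of f(t) = sqrt(C z / (m0 - r t))
      phase <- if (rate > 0) {
        sqrt(cal$mass_cal_c * charge) * 2 *
          (sqrt(mass) - sqrt(mass - rate * t)) / rate
      } else {
        f0 * t
      }
      phase <- phase + stats::runif(1)  # random trap-entry phase
      signal <- cal$gain * charge * ((phase %% 1) < cal$duty_cycle)
    } else {
      signal <- numeric(n)
    }
    if (cal$noise_rms > 0) {
      signal <- signal + stats::rnorm(n, 0, cal$noise_rms)
    }
    structure(list(signal = signal, sample_rate_hz = acq$sample_rate_hz,
                   trap_ms = acq$trap_ms,
                   ion = list(mass_da = mass, charge_e = charge,
                              f0_hz = f0,
                              mass_loss_rate_da_per_s = rate,
                              population = if (!is.null(ion$population))
                                as.character(ion$population) else "",
                              ion_id = if (!is.null(ion$ion_id))
                                as.integer(ion$ion_id) else NA_integer_)),
              class = "cdms_trace")
  })
}

#' @export
print.cdms_trace <- function(x, ...) {
  cat(sprintf("<cdms_trace> %d samples @ %.3g Hz (%.0f ms), true %.4g Da / %.1f e, f0 %.1f Hz\n",
              length(x$signal), x$sample_rate_hz, x$trap_ms,
              x$ion$mass_da, x$ion$charge_e, x$ion$f0_hz))
  invisible(x)
}

#' Write a set of traces to a binary container
#'
#' Stores traces in a directory as one flat file of little-endian signed
#' 16-bit samples (`traces.bin`) plus a JSON index (`index.json`) holding
#' per-ion offsets, a per-trace amplitude scale, acquisition metadata, and
#' the ground-truth fields. Samples are quantized to 16 bits after scaling
#' each trace to full range; the scale factor is stored so the read-back
#' signal is recovered in amplitude units.
#'
#' @param traces list of `cdms_trace` objects.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trace_set <- function(traces, path) {
  stopifnot(is.list(traces), length(traces) > 0)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(path, "traces.bin"), "wb")
  on.exit(close(con), add = TRUE)
  index <- vector("list", length(traces))
  offset <- 0L
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    stopifnot(inherits(tr, "cdms_trace"))
    peak <- max(abs(tr$signal), 1e-12)
    scale <- peak / 32767
    writeBin(as.integer(round(tr$signal / scale)), con, size = 2L,
             endian = "little")
    index[[i]] <- list(offset = offset, n = length(tr$signal),
                       scale = scale,
                       sample_rate_hz = tr$sample_rate_hz,
                       trap_ms = tr$trap_ms, ion = tr$ion)
    offset <- offset + length(tr$signal)
  }
  jsonlite::write_json(index, file.path(path, "index.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trace set written by [write_trace_set()]
#'
#' @param path directory containing `traces.bin` and `index.json`.
#' @return List of `cdms_trace` objects.
#' @export
read_trace_set <- function(path) {
  idx_file <- file.path(path, "index.json")
  bin_file <- file.path(path, "traces.bin")
  if (!file.exists(idx_file) || !file.exists(bin_file)) {
    stop_invalid("'%s' is not a trace-set directory", path)
  }
  index <- jsonlite::read_json(idx_file, simplifyVector = FALSE)
  con <- file(bin_file, "rb")
  on.exit(close(con), add = TRUE)
  lapply(index, function(e) {
    seek(con, where = e$offset * 2, origin = "start")
    raw16 <- readBin(con, integer(), n = e$n, size = 2L, signed = TRUE,
                     endian = "little")
    structure(list(signal = raw16 * e$scale,
                   sample_rate_hz = e$sample_rate_hz,
                   trap_ms = e$trap_ms,
                   ion = e$ion),
              class = "cdms_trace")
  })
}
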