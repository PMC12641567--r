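# Short-time Fourier transform engine: per-ion frequency, harmonic
# amplitudes, m/z, charge and mass from time-domain traces.
#
# Each trace is cut into rectangularly apodized (untapered) overlapping
# segments. In each segment the discrete spectrum locates the fundamental,
# which is then refined off-grid by maximizing the least-squares projection
# of a single tone onto the data (equivalent to the continuous-frequency
# periodogram), and the amplitudes of harmonics 1..max_harmonic are read
# out at the refined frequency with free phases. Per-ion values are robust
# (median) summaries across converged segments; a linear trend of the
# segment frequencies versus time tests for in-trap mass change.

#' Cut a trace into rectangular STFT segments
#'
#' Left-aligned windows of `segment_ms` advanced by `step_ms`; a final
#' partial window is discarded. The number of segments for a full trace is
#' `floor((trap_ms - segment_ms) / step_ms) + 1`.
#'
#' @param trace a `cdms_trace` (or list with `signal` and `sample_rate_hz`).
#' @param acq an [acquisition_config()].
#' @return List of segments, each a list with `samples` and `t_center_ms`.
#'   A trace shorter than one segment gives an empty list carrying
#'   `attr(, "flags") = "SHORT_TRAP"`.
#' @export
stft_segments <- function(trace, acq = acquisition_config()) {
  stopifnot(inherits(acq, "acquisition_config"))
  fs <- trace$sample_rate_hz
  n_seg <- round(fs * acq$segment_ms / 1000)
  n_hop <- round(fs * acq$step_ms / 1000)
  n <- length(trace$signal)
  if (n < n_seg) {
    return(structure(list(), flags = "SHORT_TRAP"))
  }
  starts <- seq.int(1L, n - n_seg + 1L, by = n_hop)
  lapply(starts, function(s0) {
    list(samples = trace$signal[s0:(s0 + n_seg - 1L)],
         t_center_ms = (s0 - 1 + n_seg / 2) / fs * 1000)
  })
}

# Concentrated least-squares objective: power of the projection of `s`
# onto a tone at frequency f (free phase). Equals the continuous-frequency
# periodogram up to scale.
tone_power <- function(s, t, f) {
  w <- 2 * pi * f * t
  sum(s * cos(w))^2 + sum(s * sin(w))^2
}

#' Fit one STFT segment
#'
#' Locates the strongest plausible fundamental in the segment's discrete
#' spectrum (guarding against picking a harmonic: if a subharmonic of the
#' strongest bin also carries energy, the lower frequency wins), refines
#' the frequency off-grid by maximizing the single-tone projection within
#' one bin of the peak, and extracts amplitudes of harmonics
#' `1..max_harmonic` at the refined frequency with free phases.
#'
#' @param segment one element of [stft_segments()].
#' @param acq an [acquisition_config()].
#' @param cal a [trap_calibration()] (carried for interface symmetry; the
#'   fit itself is calibration-free).
#' @param f_min lowest admissible fundamental in Hz.
#' @param snr_min detection threshold: the peak spectral amplitude must
#'   exceed `snr_min` times the median in-band spectral amplitude.
#' @return A list (`segment_fit`): `t_center_ms`, `f0_hz`,
#'   `harmonic_amplitudes`, `residual_rms`, `converged`.
#' @export
fit_segment <- function(segment, acq = acquisition_config(),
                        cal = trap_calibration(), f_min = 1000,
                        snr_min = 5) {
  stopifnot(inherits(acq, "acquisition_config"))
  s <- segment$samples - mean(segment$samples)
  n <- length(s)
  fs <- acq$sample_rate_hz
  df <- fs / n
  spec <- Mod(stats::fft(s))[seq_len(floor(n / 2))] * 2 / n
  freqs <- (seq_len(floor(n / 2)) - 1) * df
  # admissible fundamentals: above f_min, all harmonics below Nyquist
  band <- which(freqs >= f_min & freqs < fs / (2 * acq$max_harmonic))
  failed <- list(t_center_ms = segment$t_center_ms, f0_hz = NA_real_,
                 harmonic_amplitudes = rep(0, acq$max_harmonic),
                 residual_rms = sqrt(mean(s^2)), converged = FALSE)
  class(failed) <- "segment_fit"
  if (!length(band)) return(failed)
  floor_amp <- stats::median(spec[band])
  k_peak <- band[which.max(spec[band])]
  if (spec[k_peak] < snr_min * floor_amp) return(failed)
  # octave-error guard: prefer a subharmonic that itself carries energy
  # and whose harmonic ladder is consistent with the strongest bin
  k_fund <- k_peak
  for (d in acq$max_harmonic:2) {
    k_sub <- 1L + round((k_peak - 1L) / d)
    if (freqs[k_sub] < f_min) next
    sub_amp <- max(spec[pmax(1L, k_sub + (-1:1))])
    if (sub_amp >= snr_min * floor_amp && sub_amp >= 0.2 * spec[k_peak]) {
      k_fund <- k_sub
      break
    }
  }
  t <- (seq_len(n) - 1) / fs
  opt <- stats::optimize(function(f) tone_power(s, t, f),
                         interval = freqs[k_fund] + c(-df, df),
                         maximum = TRUE, tol = 5e-3)
  f0 <- opt$maximum
  nh <- seq_len(acq$max_harmonic)
  amps <- vapply(nh, function(k) {
    if (k * f0 >= fs / 2) return(0)
    sqrt(tone_power(s, t, k * f0)) * 2 / n
  }, numeric(1))
  res2 <- max(0, mean(s^2) - sum(amps^2) / 2)
  # magnitude debias: E[amp^2] = A^2 + 4 sigma^2 / n for a tone in white
  # noise, so subtracting the noise term removes the Rice-magnitude bias
  amps <- sqrt(pmax(amps^2 - 4 * res2 / n, 0))
  structure(list(t_center_ms = segment$t_center_ms, f0_hz = f0,
                 harmonic_amplitudes = amps,
                 residual_rms = sqrt(res2), converged = TRUE),
            class = "segment_fit")
}

#' Charge from harmonic amplitudes
#'
#' The noiseless pulse train of an ion with charge z, gain G and duty
#' cycle d has harmonic amplitudes `A_n = z * G * 2 |sin(n pi d)| / (n pi)`.
#' The charge is recovered by least squares of the observed amplitudes on
#' this pattern: `z = sum(b_n A_n) / sum(b_n^2)` with
#' `b_n = G * 2 |sin(n pi d)| / (n pi)`.
#'
#' @param harmonic_amplitudes numeric vector of amplitudes for harmonics
#'   `1..length(...)`; at least the fundamental.
#' @param cal a [trap_calibration()] providing gain and duty cycle.
#' @return Real-valued charge in elementary units (0 if all amplitudes 0).
#' @examples
#' b <- 2 * abs(sin(1:4 * pi * 0.45)) / (1:4 * pi)
#' charge_from_amplitudes(165 * b)  # 165
#' @export
charge_from_amplitudes <- function(harmonic_amplitudes,
                                   cal = trap_calibration()) {
  stopifnot(inherits(cal, "trap_calibration"))
  a <- harmonic_amplitudes
  if (!length(a) || any(!is.finite(a))) {
    stop_invalid("'harmonic_amplitudes' must be finite and non-empty")
  }
  nh <- seq_along(a)
  b <- cal$gain * 2 * abs(sin(nh * pi * cal$duty_cycle)) / (nh * pi)
  if (all(a == 0) || sum(b^2) == 0) return(0)
  sum(b * a) / sum(b^2)
}

#' Combine segment fits into a per-ion measurement
#'
#' Takes the median fundamental frequency and median harmonic amplitudes
#' over converged segments, converts them to m/z, charge and mass, and
#' tests for in-trap mass change by regressing the segment frequencies on
#' time. The drift regression uses only non-overlapping segments (every
#' `segment_ms / step_ms`-th fit) so the slope's null distribution can be
#' calibrated from the segment-to-segment frequency jitter, which would be
#' underestimated on strongly correlated overlapping windows.
#'
#' Flags: `UNSTABLE` when fewer than 80% of segments converged;
#' `MASS_CHANGE` when the absolute frequency drift exceeds 3 times the
#' jitter-derived slope standard error; `SHORT_TRAP` propagated from
#' segmentation.
#'
#' @param fits list of [fit_segment()] results.
#' @param acq an [acquisition_config()].
#' @param cal a [trap_calibration()].
#' @return A one-row data.frame (`ion_id` unset) with columns `f0_hz`,
#'   `amplitude`, `mz_th`, `charge_e`, `mass_da`, `n_segments_used`,
#'   `drift_hz_per_s`, `flags`; or `NULL` when no segment converged (the
#'   ion is dropped).
#' @export
track_ion <- function(fits, acq = acquisition_config(),
                      cal = trap_calibration()) {
  flags <- character(0)
  if (!is.null(attr(fits, "flags"))) flags <- c(flags, attr(fits, "flags"))
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(conv)) return(NULL)
  if (length(conv) < 0.8 * length(fits)) flags <- c(flags, "UNSTABLE")
  if (length(conv) == 1L && !"UNSTABLE" %in% flags) {
    flags <- c(flags, "UNSTABLE")
  }
  f0s <- vapply(conv, `[[`, numeric(1), "f0_hz")
  amp_mat <- vapply(conv, `[[`, numeric(acq$max_harmonic),
                    "harmonic_amplitudes")
  amps <- apply(matrix(amp_mat, nrow = acq$max_harmonic), 1, stats::median)
  f0 <- stats::median(f0s)
  # drift test on the non-overlapping subset
  t_s <- vapply(conv, `[[`, numeric(1), "t_center_ms") / 1000
  dec <- round(acq$segment_ms / acq$step_ms)
  keep <- seq(1L, length(conv), by = max(1L, dec))
  drift <- 0
  if (length(keep) >= 4L) {
    td <- t_s[keep]
    fd <- f0s[keep]
    fit <- stats::lm.fit(cbind(1, td), fd)
    drift <- unname(fit$coefficients[2])
    jitter_sd <- stats::sd(diff(fd)) / sqrt(2)
    slope_sd <- jitter_sd / sqrt(sum((td - mean(td))^2))
    if (is.finite(slope_sd) && slope_sd > 0 &&
        abs(drift) > 3 * slope_sd) {
      flags <- c(flags, "MASS_CHANGE")
    }
  }
  mz <- mz_from_frequency(f0, cal)
  z <- charge_from_amplitudes(amps, cal)
  data.frame(f0_hz = f0, amplitude = amps[1], mz_th = mz, charge_e = z,
             mass_da = mz * z, n_segments_used = length(conv),
             drift_hz_per_s = drift,
             flags = paste(unique(flags), collapse = "|"),
             stringsAsFactors = FALSE)
}

#' Analyze one trace end to end
#'
#' Segmentation, per-segment harmonic fitting, and per-ion tracking.
#'
#' @param trace a `cdms_trace`.
#' @param cal a [trap_calibration()].
#' @param acq an [acquisition_config()].
#' @return A one-row measurement data.frame, or `NULL` if no segment
#'   converged.
#' @export
analyze_trace <- function(trace, cal = trap_calibration(),
                          acq = acquisition_config()) {
  segs <- stft_segments(trace, acq)
  fits <- lapply(segs, fit_segment, acq = acq, cal = cal)
  attr(fits, "flags") <- attr(segs, "flags")
  track_ion(fits, acq, cal)
}

#' Analyze a list of traces into an ion table
#'
#' @param traces list of `cdms_trace` objects.
#' @param cal a [trap_calibration()].
#' @param acq an [acquisition_config()].
#' @return An ion-measurement data.frame; ions with no converged segment
#'   are dropped and reported via a message (count and ids).
#' @export
analyze_trace_set <- function(traces, cal = trap_calibration(),
                              acq = acquisition_config()) {
  rows <- vector("list", length(traces))
  dropped <- integer(0)
  for (i in seq_along(traces)) {
    m <- analyze_trace(traces[[i]], cal, acq)
    if (is.null(m)) {
      dropped <- c(dropped, i)
      next
    }
    id <- traces[[i]]$ion$ion_id
    m <- cbind(ion_id = if (!is.null(id) && !is.na(id)) id else i, m)
    pop <- traces[[i]]$ion$population
    if (!is.null(pop) && nzchar(pop)) m$population <- pop
    rows[[i]] <- m
  }
  if (length(dropped)) {
    message(sprintf("dropped %d trace(s) with no converged segment: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
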