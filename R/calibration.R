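# Trap calibration and acquisition settings.
#
# In an electrostatic linear ion trap the oscillation frequency of a
# trapped ion depends only on its m/z (for fixed trap potentials), to a
# good approximation through the power law m/z = C / f^2. The induced
# charge on the detection tube is proportional to the ion charge, with the
# ion spending a `duty_cycle` fraction of each oscillation period inside
# the tube, so the time-domain signal is a rectangular pulse train whose
# plateau height is `gain * charge`.

#' Trap calibration
#'
#' @param mass_cal_c calibration constant C in Th*Hz^2 such that
#'   m/z = C / f^2. The default 2.9879e12 puts a 4.93 MDa, 165 e ion at
#'   10.000 kHz, so all species of interest oscillate in a 5-25 kHz band
#'   well below the Nyquist limit of 1 MHz sampling.
#' @param gain detector amplitude units per elementary charge.
#' @param duty_cycle fraction of the oscillation period spent inside the
#'   detection tube, in (0, 1). The default 0.45 keeps harmonics 2-4 of the
#'   pulse train nonzero so they contribute to the harmonic fit.
#' @param noise_rms additive white-noise RMS in amplitude units. The
#'   default 250 yields a single-segment charge uncertainty of ~3.6 e and a
#'   full 500 ms trap per-ion charge SD of ~1 e, typical CDMS precision.
#' @return An object of class `trap_calibration`.
#' @examples
#' trap_calibration()
#' @export
trap_calibration <- function(mass_cal_c = 2.9879e12, gain = 1,
                             duty_cycle = 0.45, noise_rms = 250) {
  check_scalar(mass_cal_c, "mass_cal_c", lower = 0, strict_lower = TRUE)
  check_scalar(gain, "gain", lower = 0, strict_lower = TRUE)
  check_scalar(duty_cycle, "duty_cycle", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(noise_rms, "noise_rms", lower = 0)
  structure(list(mass_cal_c = mass_cal_c, gain = gain,
                 duty_cycle = duty_cycle, noise_rms = noise_rms),
            class = "trap_calibration")
}

#' Acquisition configuration
#'
#' Sampling and short-time Fourier transform (STFT) settings: 1 MHz
#' sampling, 500 ms trap events, 25 ms rectangular segments advanced in
#' 5 ms steps, harmonic fitting up to the fourth harmonic.
#'
#' @param sample_rate_hz sampling rate in Hz.
#' @param trap_ms trap event duration in ms.
#' @param segment_ms STFT segment length in ms; must not exceed `trap_ms`.
#' @param step_ms STFT hop size in ms; must not exceed `segment_ms`.
#' @param max_harmonic highest harmonic used in segment fits.
#' @return An object of class `acquisition_config`.
#' @examples
#' acquisition_config()
#' @export
acquisition_config <- function(sample_rate_hz = 1e6, trap_ms = 500,
                               segment_ms = 25, step_ms = 5,
                               max_harmonic = 4) {
  check_scalar(sample_rate_hz, "sample_rate_hz", lower = 0, strict_lower = TRUE)
  check_scalar(trap_ms, "trap_ms", lower = 0, strict_lower = TRUE)
  check_scalar(segment_ms, "segment_ms", lower = 0, upper = trap_ms,
               strict_lower = TRUE)
  check_scalar(step_ms, "step_ms", lower = 0, upper = segment_ms,
               strict_lower = TRUE)
  max_harmonic <- check_count(max_harmonic, "max_harmonic", lower = 1L)
  n_seg <- sample_rate_hz * segment_ms / 1000
  if (abs(n_seg - round(n_seg)) > 1e-9) {
    stop_invalid("segment_ms * sample_rate_hz must give an integer number of samples")
  }
  structure(list(sample_rate_hz = sample_rate_hz, trap_ms = trap_ms,
                 segment_ms = segment_ms, step_ms = step_ms,
                 max_harmonic = max_harmonic),
            class = "acquisition_config")
}

#' m/z from oscillation frequency
#'
#' Applies the trap frequency law m/z = C / f^2.
#'
#' @param f0_hz fundamental oscillation frequency in Hz (vectorized,
#'   strictly positive).
#' @param cal a [trap_calibration()].
#' @return m/z in Th.
#' @examples
#' mz_from_frequency(10000)  # 29879 Th
#' @export
mz_from_frequency <- function(f0_hz, cal = trap_calibration()) {
  stopifnot(inherits(cal, "trap_calibration"))
  if (any(!is.finite(f0_hz)) || any(f0_hz <= 0)) {
    stop_invalid("'f0_hz' must be strictly positive")
  }
  cal$mass_cal_c / f0_hz^2
}

#' Oscillation frequency of an ion of given mass and charge
#'
#' Inverse of [mz_from_frequency()]: f = sqrt(C * z / m).
#'
#' @param mass_da ion mass in Da (vectorized).
#' @param charge_e ion charge in elementary units (vectorized).
#' @param cal a [trap_calibration()].
#' @return Fundamental frequency in Hz.
#' @export
frequency_for_ion <- function(mass_da, charge_e, cal = trap_calibration()) {
  stopifnot(inherits(cal, "trap_calibration"))
  if (any(!is.finite(mass_da)) || any(mass_da <= 0) ||
      any(!is.finite(charge_e)) || any(charge_e <= 0)) {
    stop_invalid("mass and charge must be strictly positive")
  }
  sqrt(cal$mass_cal_c * charge_e / mass_da)
}
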