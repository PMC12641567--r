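# Trace synthesis: 100 ms trap events keep these tests fast; the full
# 500 ms events are exercised by the recovery tests.
acq100 <- acquisition_config(trap_ms = 100)

test_that("noiseless pulse train has the analytic DC and Fourier content", {
  cal0 <- trap_calibration(noise_rms = 0)
  ion <- list(mass_da = 4.93e6, charge_e = 165)
  tr <- synthesize_trace(ion, cal = cal0, acq = acq100, seed = 4)
  # DC level: plateau * duty cycle
  expect_equal(mean(tr$signal), 165 * 0.45, tolerance = 1e-6)
  # fundamental amplitude: 2 z sin(pi d) / pi, via independent projection
  a1 <- projection_amplitude(tr$signal, tr$sample_rate_hz, tr$ion$f0_hz)
  expect_equal(a1, 165 * 2 * sin(0.45 * pi) / pi, tolerance = 0.05 / 103.75)
  # third harmonic ratio (amplitudes are magnitudes)
  a3 <- projection_amplitude(tr$signal, tr$sample_rate_hz, 3 * tr$ion$f0_hz)
  expect_equal(a1 / a3, sin(0.45 * pi) / (abs(sin(1.35 * pi)) / 3),
               tolerance = 0.01)
})

test_that("a half duty cycle suppresses even harmonics", {
  cal <- trap_calibration(noise_rms = 0, duty_cycle = 0.5)
  # mass chosen so f0 is exactly 10 kHz (an integer number of samples per
  # period); otherwise sampling skew leaves ~1e-5 even-harmonic leakage
  mass <- cal$mass_cal_c * 165 / 1e8
  tr <- synthesize_trace(list(mass_da = mass, charge_e = 165),
                         cal = cal, acq = acq100, seed = 9)
  a1 <- projection_amplitude(tr$signal, tr$sample_rate_hz, tr$ion$f0_hz)
  a2 <- projection_amplitude(tr$signal, tr$sample_rate_hz, 2 * tr$ion$f0_hz)
  a4 <- projection_amplitude(tr$signal, tr$sample_rate_hz, 4 * tr$ion$f0_hz)
  expect_lt(a2 / a1, 1e-9)
  expect_lt(a4 / a1, 1e-9)
})

test_that("degenerate and invalid ions are handled", {
  cal0 <- trap_calibration(noise_rms = 0)
  tr <- synthesize_trace(list(mass_da = 1e6, charge_e = 0), cal = cal0,
                         acq = acq100, seed = 1)
  expect_true(all(tr$signal == 0))
  # a light, highly charged ion would alias its fitted harmonics
  expect_error(synthesize_trace(list(mass_da = 1e4, charge_e = 500),
                                acq = acq100, seed = 1),
               "aliases")
  # mass loss must not consume the ion within the event
  expect_error(synthesize_trace(list(mass_da = 1e6, charge_e = 100,
                                     mass_loss_rate_da_per_s = 2e10),
                                acq = acq100, seed = 1),
               "whole ion")
})

test_that("mass loss raises the oscillation frequency during the event", {
  cal0 <- trap_calibration(noise_rms = 0)
  ion <- list(mass_da = 5.1e6, charge_e = 160,
              mass_loss_rate_da_per_s = 3.19e5)
  tr <- synthesize_trace(ion, cal = cal0, acq = acquisition_config(), seed = 2)
  n <- length(tr$signal)
  # short windows at either end keep the within-window chirp small
  nw <- 50000L
  first <- tr$signal[1:nw]
  last <- tr$signal[(n - nw + 1):n]
  f_start <- dense_grid_f0(first, tr$sample_rate_hz)
  f_end <- dense_grid_f0(last, tr$sample_rate_hz)
  expect_gt(f_end, f_start)
  # frequency change consistent with m/z = C / f^2 at the lost mass
  m0 <- 5.1e6 - 3.19e5 * (nw / 2) / 1e6
  m1 <- 5.1e6 - 3.19e5 * (n - nw / 2) / 1e6
  expect_equal(f_end / f_start, sqrt(m0 / m1), tolerance = 2e-3)
})

test_that("trace sets round-trip through the binary container", {
  dir <- withr::local_tempdir()
  ions <- sample_ion_ensemble(build_scenario("aa_neutral"), 3, seed = 1)
  traces <- lapply(1:3, function(i) {
    synthesize_trace(ions[i, ], acq = acquisition_config(trap_ms = 25),
                     seed = i)
  })
  write_trace_set(traces, file.path(dir, "ts"))
  back <- read_trace_set(file.path(dir, "ts"))
  expect_length(back, 3)
  for (i in 1:3) {
    peak <- max(abs(traces[[i]]$signal))
    expect_lt(max(abs(back[[i]]$signal - traces[[i]]$signal)), peak / 32000)
    expect_equal(back[[i]]$ion$mass_da, traces[[i]]$ion$mass_da)
    expect_equal(back[[i]]$ion$charge_e, traces[[i]]$ion$charge_e)
  }
  expect_error(read_trace_set(file.path(dir, "nothere")), "trace-set")
})
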