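acq <- acquisition_config()
acq100 <- acquisition_config(trap_ms = 100)
cal0 <- trap_calibration(noise_rms = 0)

make_trace <- function(mass = 4.93e6, charge = 165, trap_ms = 100,
                       noise = 250, seed = 1, rate = 0) {
  synthesize_trace(list(mass_da = mass, charge_e = charge,
                        mass_loss_rate_da_per_s = rate),
                   cal = trap_calibration(noise_rms = noise),
                   acq = acquisition_config(trap_ms = trap_ms), seed = seed)
}

test_that("segmentation yields the expected window count and flags", {
  tr <- make_trace(trap_ms = 500, noise = 0)
  expect_length(stft_segments(tr, acq), 96)
  tr25 <- make_trace(trap_ms = 25, noise = 0)
  expect_length(stft_segments(tr25, acq), 1)
  # a trace truncated below one segment length carries the SHORT_TRAP flag
  tr24 <- list(signal = tr25$signal[1:24000], sample_rate_hz = 1e6,
               trap_ms = 24)
  segs <- stft_segments(tr24, acq)
  expect_length(segs, 0)
  expect_identical(attr(segs, "flags"), "SHORT_TRAP")
})

test_that("segment fits recover frequency and harmonic ratios of a clean ion", {
  tr <- make_trace(noise = 0, seed = 6)
  seg <- stft_segments(tr, acq)[[1]]
  fit <- fit_segment(seg, acq)
  expect_true(fit$converged)
  expect_lt(abs(fit$f0_hz - tr$ion$f0_hz), 0.5)
  a <- fit$harmonic_amplitudes
  expect_equal(a[1] / a[3], sin(0.45 * pi) / (abs(sin(1.35 * pi)) / 3),
               tolerance = 0.01)
})

test_that("refined frequency matches the dense-grid periodogram oracle", {
  set.seed(21)
  for (i in 1:6) {
    m <- runif(1, 2.5e6, 8e6)
    z <- runif(1, 110, 200)
    tr <- make_trace(mass = m, charge = z, trap_ms = 25, noise = 0, seed = i)
    seg <- stft_segments(tr, acq)[[1]]
    fit <- fit_segment(seg, acq)
    f_oracle <- dense_grid_f0(seg$samples, acq$sample_rate_hz)
    expect_lt(abs(fit$f0_hz - f_oracle), 0.5)
  }
})

test_that("pure noise does not converge; a two-tone segment yields the stronger tone", {
  set.seed(8)
  noise_seg <- list(samples = rnorm(25000, 0, 250), t_center_ms = 12.5)
  fit <- fit_segment(noise_seg, acq)
  expect_false(fit$converged)
  expect_true(all(fit$harmonic_amplitudes == 0))

  t <- (0:24999) / 1e6
  two <- list(samples = 80 * cos(2 * pi * 9000 * t) +
                40 * cos(2 * pi * 13700 * t), t_center_ms = 12.5)
  fit2 <- fit_segment(two, acq)
  expect_true(fit2$converged)
  expect_lt(abs(fit2$f0_hz - 9000), 1)
})

test_that("charge follows from harmonic amplitudes by model inversion", {
  cal <- trap_calibration()
  b <- cal$gain * 2 * abs(sin(1:4 * pi * cal$duty_cycle)) / (1:4 * pi)
  expect_equal(charge_from_amplitudes(165 * b, cal), 165, tolerance = 0.05 / 165)
  expect_identical(charge_from_amplitudes(rep(0, 4), cal), 0)
  # fundamental-only closed form
  a1 <- 165 * b[1]
  expect_equal(charge_from_amplitudes(a1, cal),
               a1 * pi / (cal$gain * 2 * sin(0.45 * pi)), tolerance = 1e-12)
  expect_error(charge_from_amplitudes(numeric(0)), "non-empty")
})

test_that("tracking summarizes segments and flags sparse convergence", {
  tr <- make_trace(seed = 13)
  fits <- lapply(stft_segments(tr, acq100), fit_segment, acq = acq100)
  m <- track_ion(fits, acq100)
  expect_equal(m$n_segments_used, 16)
  expect_equal(m$charge_e, 165, tolerance = 5 / 165)

  single <- track_ion(fits[1], acq100)
  expect_equal(single$n_segments_used, 1)
  expect_match(single$flags, "UNSTABLE")

  unconv <- lapply(fits, function(f) { f$converged <- FALSE; f })
  expect_null(track_ion(unconv, acq100))
})

test_that("mass change is flagged for evaporating ions and not for stable ones", {
  # evaporation at the reported aqueous-nanodrop rate is far above threshold
  for (i in 1:3) {
    tr <- make_trace(mass = 5.1e6, charge = 160, trap_ms = 500,
                     rate = 3.19e5, seed = 300 + i)
    expect_match(analyze_trace(tr, acq = acq)$flags, "MASS_CHANGE")
  }
  # constant-mass ions at default noise stay unflagged
  flags <- vapply(1:5, function(i) {
    analyze_trace(make_trace(trap_ms = 500, seed = 400 + i), acq = acq)$flags
  }, character(1))
  expect_false(any(grepl("MASS_CHANGE", flags)))
})

test_that("recovered charge is unbiased at the trace level", {
  # low-noise short traps isolate estimator bias from statistical spread
  zs <- vapply(1:40, function(i) {
    tr <- make_trace(noise = 50, seed = 500 + i)
    analyze_trace(tr, cal = trap_calibration(noise_rms = 50),
                  acq = acq100)$charge_e
  }, numeric(1))
  expect_lt(abs(mean(zs) - 165), 0.25)
})

test_that("trace-set analysis returns one measurement row per usable ion", {
  ens <- sample_ion_ensemble(build_scenario("aa_neutral"), 4, seed = 3)
  traces <- lapply(1:4, function(i) {
    synthesize_trace(ens[i, ], acq = acq100, seed = 600 + i)
  })
  tab <- analyze_trace_set(traces, acq = acq100)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("ion_id", "f0_hz", "mz_th", "charge_e", "mass_da",
                    "n_segments_used", "drift_hz_per_s", "flags")
                  %in% names(tab)))
  expect_equal(tab$mass_da, ens$mass_da, tolerance = 0.05)
  expect_equal(tab$mass_da, tab$mz_th * tab$charge_e, tolerance = 1e-12)
})
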