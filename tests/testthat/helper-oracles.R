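# Independent oracles used by the tests.

# Continuous-frequency periodogram at a single frequency, computed from
# first principles (no package internals).
periodogram_power <- function(s, fs, f) {
  t <- (seq_along(s) - 1) / fs
  Mod(sum(s * exp(-2i * pi * f * t)))^2
}

# Exhaustive dense-grid periodogram maximizer: coarse FFT-grid peak within
# `band`, then a 0.02 Hz grid over +/- 1.5 bins around it.
dense_grid_f0 <- function(s, fs, band = c(1000, fs / 8)) {
  s <- s - mean(s)
  n <- length(s)
  df <- fs / n
  spec <- Mod(stats::fft(s))[seq_len(floor(n / 2))]
  freqs <- (seq_len(floor(n / 2)) - 1) * df
  keep <- freqs >= band[1] & freqs <= band[2]
  f_coarse <- freqs[keep][which.max(spec[keep])]
  grid <- seq(f_coarse - 1.5 * df, f_coarse + 1.5 * df, by = 0.02)
  pw <- vapply(grid, function(f) periodogram_power(s, fs, f), numeric(1))
  grid[which.max(pw)]
}

# Amplitude of the tone at a known frequency, by direct projection.
projection_amplitude <- function(s, fs, f) {
  s <- s - mean(s)
  2 * sqrt(periodogram_power(s, fs, f)) / length(s)
}
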