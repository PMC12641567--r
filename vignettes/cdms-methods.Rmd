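---
title: "Models and methods behind cdmstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cdmstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdmstrap)
```

# The measurement

Charge detection mass spectrometry (CDMS) measures single ions. A
nanoelectrosprayed particle is trapped in an electrostatic linear ion trap,
where it oscillates back and forth through a cylindrical detection
electrode. Two quantities are read out of the induced-charge signal at
once:

* the oscillation frequency, which for fixed trap potentials depends only
  on m/z, and
* the induced-charge amplitude, which is proportional to the ion's charge
  z.

Their product gives the mass of that one ion, so thousands of trapped ions
yield mass and charge *histograms* rather than a congested m/z spectrum.
For megadalton, heterogeneous analytes such as adeno-associated virus
(AAV) capsids this is the difference between a usable measurement and an
uninterpretable one.

`cdmstrap` provides the full chain in one package: deterministic mass
accounting for capsid species, a synthetic single-ion signal generator
standing in for the instrument, the short-time Fourier transform (STFT)
analysis that recovers per-ion frequency, charge and mass, and the
downstream analyses (Gaussian-mixture decomposition of charge histograms,
Rayleigh-limit size mapping, and population classification).

# Capsid mass accounting

An AAV capsid contains 60 subunits of the three viral proteins VP1, VP2
and VP3 (83.5, 68.6, 62.0 kDa by default) at an average stoichiometry near
1:1:10, plus a single-stranded DNA cargo. All contributions are additive:

```{r mass}
species_mass(species_registry("AAV9_CMV_GFP")) / 1e6  # 4.91 MDa
species_mass(species_registry("AAV9_empty")) / 1e6    # ~3.9 MDa
```

`vp_counts_from_ratio()` apportions subunits by largest-remainder
rounding, the only simple scheme that returns (5, 5, 50) for every
permutation of the 1:1:10 ratio; remainder ties go to VP3, the majority
subunit. Virion-to-virion variability is modeled as a multinomial draw
(`sample_stoichiometry()`).

One arithmetic wrinkle is preserved deliberately: the VP3-only
virus-like particle with a 0.84 MDa cargo computes to 60 × 62.0 kDa +
0.84 MDa = 4.56 MDa, while the literature quotes a calculated 4.54 MDa for
this construct. The rounded kDa inputs cannot reproduce the lower figure;
the registry stores the arithmetic value and does not "correct" it, since
the unrounded subunit masses behind the quoted number are not available.

# The Rayleigh limit as a size axis

A spherical liquid droplet can hold at most the Rayleigh-limit charge
before Coulomb fission, and globular particles electrosprayed from water
charge near the limit of an equally sized droplet. The limiting diameter
for charge z (in elementary units, converted internally to Coulombs) is

$$d_R = 2\left(\frac{z e}{8\pi}\right)^{2/3} (\varepsilon_0\gamma)^{-1/3},$$

with surface tension $\gamma$ = 0.0720 N/m, permittivity $\varepsilon_0$ =
8.8542e-12 F/m and droplet density 1000 kg/m³ as defaults (all overridable
through `rayleigh_constants()`). With these constants 165 e maps to
24.0 nm and 170 e to 24.5 nm — capsid-sized droplets. The same algebra run
from a mass (sphere radius at unit density, then the limit charge, in
`rayleigh_charge_for_mass()`) draws the "Rayleigh line" on 2D mass/charge
histograms; fragment ions whose charge rides this line while their mass
spreads over a continuum are the signature of capsid disassembly with
retained DNA. Charges are kept real-valued everywhere; integerization is a
display decision.

# The synthetic instrument

No public CDMS raw data exist for these samples, so the generator is a
first-class, tested component, not a fixture. Its defaults define the
simulated study conditions.

**Frequency law.** m/z = C/f² with C = 2.9879e12 Th·Hz², chosen so a
4.93 MDa, 165 e ion oscillates at exactly 10.000 kHz. All species of
interest then fall in a 5–25 kHz band, comfortably below the alias limit
for fourth-harmonic fitting at 1 MHz sampling.

**Waveform.** The ion spends a fraction `duty_cycle` of each period inside
the detection tube, giving a rectangular pulse train with plateau
`gain * charge` and harmonic amplitudes $A_n = 2 z G\,|\sin(n\pi d)|/(n\pi)$.
The duty cycle defaults to 0.45 rather than 0.50: a symmetric square wave
would null all even harmonics and leave nothing for harmonics 2 and 4 of
the fit. A mass-losing ion is synthesized with the exact phase integral of
$f(t) = \sqrt{C z / (m_0 - rt)}$.

**Noise.** White Gaussian noise with `noise_rms` = 250 amplitude units at
unit gain. This puts the single 25 ms segment charge uncertainty near
3.6 e and the full 500 ms trap per-ion charge SD near 1 e — typical
single-ion CDMS precision. (The overlapping 25/5 ms segments share data:
a 500 ms event contains only 20 independent segment lengths, so per-ion
precision is set by total trap time, not by the nominal 96-segment count.)

**Scenario presets.** Each preset is a weighted mixture of populations
with a mass model and a charge model. Intact-species "true" masses are the
observed centroids for the corresponding buffer conditions, and the
conformer charge centroids are the fitted values for those conditions;
only centroids are reported in the source measurements, so component
weights and widths are package choices, fixed once: conformer widths
σ = 3–5 e, near-equal weights where several conformers coexist (the
measured distributions are described as evenly populated), and an
85/15 main/shoulder split for the neutral ammonium-acetate condition.
Specifically:

| preset | populations |
|---|---|
| `aa_neutral` | one species, 4.93 MDa; charge 165 e (w 0.85, σ 4) + 150 e shoulder (w 0.15, σ 5) |
| `pbs_neutral` | 5.31 MDa (0.38 MDa salt adducts); 7 conformers at 171…102 e, σ 4, equal weights |
| `vlp_pbs` | VP3-only particle + 0.42 MDa adducts; 5 conformers at 167…102 e |
| `pbs_ph4_37c` | 5.27 MDa; 6 conformers at 166…108 e |
| `aa_ph4_37c` | intact (w 0.65) + fragment continuum 1 MDa–0.9×full on the Rayleigh band (w 0.25) + aggregates (full + 0.3–1.5 MDa, w 0.05) + Rayleigh-charged dimers (w 0.05) |
| `freeze_thaw` | intact 4.6 MDa + 16% degradation split 3:1 fragments:aggregates (`degraded_weight` overridable) |
| `nuclease` | 0–20 bound 34 kDa enzymes, uniform; charge 160 − (40/15)·n ± 3 e; 3% off-trend cluster at 5.0 MDa / 100 e |

Fragment charges are drawn as the Rayleigh-limit charge of the drawn mass
times Uniform(0.85, 1.00); dimers ride slightly above the line
(0.98–1.06), as a two-sphere contact geometry can hold marginally more
charge than one sphere of the same mass.

What the generator does **not** emulate: multi-ion trap events, ion-energy
spread and trap ejection, drifting detector gain, non-white electronic
noise, and charge-state quantization. Passing recovery tests therefore
validates the analysis chain against this idealized instrument, not
against all the failure modes of a real one.

# The STFT analysis

Traces are cut into rectangularly apodized (untapered) 25 ms windows
advanced by 5 ms (96 segments per 500 ms event). Per segment:

1. the discrete spectrum locates the strongest admissible peak (above
   1 kHz and below the alias limit);
2. an octave-error guard checks whether a subharmonic of that peak itself
   carries energy, preferring the lower frequency, so a harmonic is not
   mistaken for the fundamental;
3. the frequency is refined *off-grid* by maximizing the single-tone
   projection (the continuous-frequency periodogram) within one 40 Hz bin
   of the peak, via Brent search — not snapped to the bin spacing;
4. amplitudes of harmonics 1–4 are read out at the refined frequency with
   free phases (rectangular windows destroy phase coherence between
   segments, so phases are never constrained);
5. amplitude magnitudes are debiased by subtracting the noise term
   $4\hat\sigma^2/n$ from the squared amplitude before the square root.
   Without this Rice-bias correction the recovered charge runs ~0.5 e
   high at default noise.

A segment with no peak above 5× the median in-band spectral amplitude is
marked unconverged and carries zero amplitudes.

Per ion, the fundamental frequency and the four harmonic amplitudes are
medians over converged segments (robust to single-segment misfits), m/z
follows from the frequency law, and charge from least squares of the
amplitude vector on the pulse-train pattern, $\hat z = \sum b_n A_n /
\sum b_n^2$. `UNSTABLE` flags ions with under 80% converged segments.

**Mass-change detection.** In-trap evaporation raises the frequency, so
the segment frequencies are regressed on time and `MASS_CHANGE` is flagged
when the slope magnitude exceeds 3× its standard error, with the error
derived from the observed segment-to-segment jitter
(`sd(diff(f0))/sqrt(2)`). One numerical subtlety: neighbouring 25/5 ms
windows share 80% of their samples, which makes successive-difference
jitter estimates and iid slope formulas wildly anticonservative, so the
drift regression runs on the decimated non-overlapping subset (every 5th
fit). At the default noise the flag stays silent on constant-mass ions
while an evaporation rate of order 3×10⁵ Da/s — the scale reported for
bare aqueous nanodrops of this size — is detected essentially always;
intact capsids showing *no* flag is the expected null result.

# Histogram decomposition

Charge histograms use 1 e bins centered on integers; mass histograms
20 kDa bins; all bins half-open [lo, hi). Conformer decomposition fits
$\sum_j a_j\, N(x; c_j, \sigma_j)$ to the *binned counts* by
Levenberg–Marquardt least squares — deliberately the histogram-level fit
used in practice for CDMS charge distributions, not a per-ion mixture
likelihood. Unweighted residuals are the default (Poisson weighting is
available via a flag). Widths are bounded to [half a bin, 30 bins] and
areas to non-negative values so components cannot collapse onto single
bins; components are reported in descending-centroid order. Starting
centroids come from the user or from local maxima of the 3-bin smoothed
histogram, with count-weighted quantiles filling any shortfall.

For `k = "auto"` the package minimizes a BIC-type score: the Pearson
chi-square of the fitted counts plus $3k\log N$, with $N$ the number of
binned ions. The chi-square (rather than the raw residual sum of squares)
matters because bin counts are Poisson: under a homoscedastic-error score
the high-count bins dominate and spurious components chase their counting
noise, which in testing inflated k on unimodal data. With the
count-calibrated score, generating component counts of 1–3 at ≥4σ
separation are recovered reliably.

`centroid()` reports the single-Gaussian centroid and falls back to the
count-weighted mean — flagged — when the fit fails or explains less than
90% of the count variance, as on strongly bimodal input.

# Population classification

Gates mirror what one reads off a 2D mass/charge histogram, with
precedence DIMER > INTACT_FULL > EMPTY > AGGREGATE > FRAGMENT:

* `INTACT_FULL` / `EMPTY` / `DIMER`: ±5% mass windows around the expected
  full, empty, and twice-full masses (the EMPTY gate only operates when an
  empty-capsid mass is supplied);
* `FRAGMENT`: mass below 0.93× the full mass **and** charge within
  0.80–1.02 of the Rayleigh limit for that mass. The 0.93 ceiling keeps
  the intact distribution's low-mass tail (≈1.5% relative SD at default
  noise) out of the fragment gate;
* `AGGREGATE`: more than 250 kDa above the full mass and not in the dimer
  window — free capsid proteins adducted onto intact particles;
* everything else `UNASSIGNED`.

The gates are package defaults, exposed in `population_gates()`; the
underlying source analyses classify visually, so the windows are choices,
not measured quantities. Derived quantities: `population_fractions()`,
`estimate_bound_count()` (nearest-integer mass increment over the ligand
mass — 4.6 → 5.1 MDa with a 34 kDa nuclease gives 15), and
`charge_vs_bound_slope()`, the ordinary least-squares charge-per-ligand
trend (−8/3 e per enzyme for the configured endpoints). Where a bound
count could also be taken from the histogram centroid difference, the
trend-endpoint route is the documented default; both are available since
`estimate_bound_count()` accepts any mass, including a fitted centroid.

# Validation scale and reproducibility

Every stochastic routine takes an explicit seed, and a pipeline run
(`run_pipeline()`) records the seed and every resolved default in its
summary, which suffices to reproduce the run. Population-scale analyses
(5,000–20,000 ions) run on ground-truth ensembles with the measured
per-ion uncertainty applied analytically (`measurements_from_truth()`,
charge SD 1 e); the trace-level chain is validated separately on 200 full
500 ms events, where the recovered mass median lands within 0.5% of truth
and the per-ion charge SD within 1.5 e. The test suite shortens most
trap events to 100 ms; statistical spreads there are larger by design and
the tests assert accordingly.

# Known limitations

* The frequency law, gain and duty cycle are package calibrations; real
  instruments require their own calibration constants, and the analysis
  functions accept them via `trap_calibration()`.
* Harmonic-order disambiguation is designed for one ion per trap event;
  two simultaneous ions are not modeled, and an injected two-tone segment
  simply yields the stronger tone.
* Conformer component weights and widths are free parameters of the
  simulation, not measured quantities; recovering them demonstrates
  internal consistency only.
* The drift detector tests a *linear* frequency trend; strongly nonlinear
  mass loss within an event would be flagged but not characterized.
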