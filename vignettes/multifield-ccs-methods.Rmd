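---
title: "Methods: multi-field drift-tube CCS extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-field drift-tube CCS extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

In drift-tube ion mobility spectrometry (DTIMS) an ion packet drifts a
length $l$ under a uniform field $E = V/l$ through a buffer gas at pressure
$p$ and temperature $T$. At low field the drift velocity is proportional to
$E$, so the arrival time at the detector is a straight line in
$x = p/(TV)$:

$$ t_A \;=\; \frac{l^2}{K_0}\cdot\frac{273.15}{760}\cdot\frac{p}{TV}
   \;+\; t_0, $$

where $K_0$ is the reduced mobility (standardised to 273.15 K and
760 torr by the $273.15/760$ factor) and the intercept $t_0$ is the time
the ion spends outside the drift region. Measuring the same ion at several
electric fields and regressing $t_A$ on $x$ yields $K_0$ from the slope
and $t_0$ from the intercept, without any mobility calibrant. The
Mason–Schamp relation then converts $K_0$ to the momentum-transfer
collision integral (collision cross section, CCS)

$$ \Omega \;=\; \frac{3 z e}{16 N_0 K_0}
   \left(\frac{2\pi}{\mu k_B T}\right)^{1/2}, $$

with $\mu$ the reduced mass of the ion/buffer-gas pair. Because $K_0$ is
already pressure/temperature standardised, the paired gas number density
is the Loschmidt density $N_0$ (273.15 K, 760 torr); $T$ is the drift-gas
temperature. This pairing is required for the two equations to be
self-consistent, and the package fixes it rather than exposing $N$ as a
parameter.

**Units.** Internally everything is carried in one fixed system: time in
ms, length in cm, voltage in V, pressure in torr, temperature in K,
$K_0$ in cm$^2$V$^{-1}$s$^{-1}$. The single ms$\leftrightarrow$s
conversion lives in the regression layer (`fit_mobility()`), nowhere else.

**Ion m/z convention.** Adduct m/z values are formed with atom masses
(`[M+H]` adds 1.007825 Da) and no electron-mass term, matching the
reference values this package reproduces (protonated C11H12N2O2 at
205.0977). The ~3 ppm difference from the electron-corrected convention
is far below the 250 ppm extraction window and comparable to instrument
mass accuracy; users who need the other convention can supply their own
target m/z.

# Why global data association

A peak near the target m/z at one field can be (1) the target ion, (2) a
co-drifting compound indistinguishable by m/z, or (3) noise. The package
treats linking peaks across fields as a multi-object-tracking problem:

1. **Ion transition graph.** Vertices are all surviving peaks in the
   extraction window, plus a source and a sink. Directed edges run from
   each peak to every peak of the adjacent (next-lower-field) group with
   weight $-\log P_{\text{match}}$, the negative log of a
   diffusion-profile match probability. Short paths therefore have
   consistent profiles.
2. **K-shortest paths** (a Hoffman–Pavley-style deviation enumeration;
   exact on the acyclic transition graph) proposes the `max_K = 3000`
   most plausible ion paths.
3. **MAP selection.** A hypothesis is a set of vertex-disjoint paths plus
   artifact labels for the remaining peaks. Its log-posterior is
   $\sum_k \log P(T_k) + \sum_i \log \Pr(x_i \mid T)$, maximised
   exhaustively over disjoint subsets of candidates (beam search with
   width 50 when more than 20 candidates survive deduplication).

## Diffusion-profile match

Each peak carries six profile statistics: apex m/z (`mzc`), m/z FWHM
(`mzw`), fraction of intensity on the low-m/z side (`mzl`), apex arrival
time (`dtc`), ATD FWHM (`dtw`) and the pre-apex intensity fraction
(`dtl`). For a pair of peaks in adjacent fields each difference is scored
as $s_k = \exp(-(\Delta_k/\sigma_k)^2)$ and the match probability is the
weighted geometric mean $\prod_k s_k^{w_k}$. Defaults: equal weights
$w_k = 1/6$; scales $\sigma$ of 20 ppm (`mzc`), 0.5 relative (`mzw`,
`dtc`, `dtw`) and 0.25 absolute (`mzl`, `dtl`). The `dtc` scale is
deliberately loose: apex times legitimately shift with field, so it acts
only as a locality prior. The functional form is smooth, equals 1 at
$\Delta = 0$, and keeps edge weights finite and non-negative.

## Path and peak probabilities

$P(T_k)$ is the weighted geometric mean of the fit linearity and the
profile consistency: $\max(R^2, 0)^{w_r} \, p_{\text{diffusion}}^{1-w_r}$
with $w_r = 0.5$ and $p_{\text{diffusion}}$ the per-edge geometric mean
of the match probabilities. An on-path peak is scored by its
arrival-time residual against the path's own fit,
$\exp\!\big(-\tfrac12 (e_i/(\sigma_t \hat t))^2\big)$ with relative
tolerance $\sigma_t = 0.02$; an artifact scores the constant
$\delta = 0.1$ — the prior probability that a peak in the window is
interference, tunable to the noise level. With disjoint paths the
posterior is additive in per-path gains, so hypothesis enumeration is
cheap and the all-artifact hypothesis (score $n\log\delta$) is always
available.

**Source/sink wiring.** The source connects to every peak and every peak
to the sink at constant cost $-\log 0.5$, so a path may span any
contiguous run of at least `min_fields = 3` fields. This tolerates
detector dropout at the extreme fields without forcing full-span paths;
three points is the minimum for a non-vacuous $R^2$.

# Peak detection and scoring

The detector operates on the averaged intensity map of each field,
restricted to a ±250 ppm window around the target m/z:

- separable Gaussian smoothing (σ = 1 bin per axis);
- local maxima above a noise floor (median + 3 MAD of the smoothed
  window, and never below $10^{-3}$ of the window maximum, which keeps
  numerical ripple in noiseless data from seeding maxima);
- steepest-ascent watershed basins split touching peaks; a peak's
  footprint is its basin above 10% of the apex, clamped at the noise
  floor;
- apex positions refined by log-parabolic interpolation through the apex
  (exact for a sampled Gaussian); FWHM by linear interpolation at half
  apex. Smoothing inflates widths slightly but identically at every
  field, which is what profile *matching* needs; widths are not reported
  as physical diffusion constants;
- per-peak statistics are measured above a local background (the
  footprint minimum of the smoothed map), so a peak riding on the skirt
  of a broad neighbour is characterised by its own profile. Deeply
  blended peaks — an interference much wider in arrival time *at the
  same m/z*, putting a tall pedestal directly under the target — remain
  a genuine limitation: the blend, not the component, is measured.

Three scores gate the peaks (defaults in parentheses):

- **Shape (≥ 0.4).** The ATD profile, treated as a weighted sample, gives
  weighted skewness $S$ and excess kurtosis $C$; the Jarque–Bera
  statistic $n_{\text{eff}}/6\,(S^2 + C^2/4)$ with
  $n_{\text{eff}} = (\sum w)^2 / \sum w^2$ is mapped through the
  $\chi^2_2$ survival function. Gaussian profiles score near 1;
  flat-topped or bimodal profiles decay quickly. The mapping is bounded,
  scale-invariant, and consistent with a 0.4 threshold for accepting
  clean peaks.
- **Isotopic (≥ 0.4).** The angle between observed and theoretical
  isotopomer vectors, oriented so identical distributions score 1:
  $1 - \theta/(\pi/2)$. (The opposite orientation would score a perfect
  match as 0, which is incompatible with a ">0.4 keeps good peaks"
  threshold, so this package fixes the direction.) Observed isotopomer
  intensities integrate a ±15 ppm strip around each envelope position
  within the peak's FWHM time band, on the full field map (higher
  isotopomers lie outside the extraction window).
- **Relative intensity (≥ 0.03).** Summed footprint intensity relative to
  the most abundant peak in the same window; *summed* rather than apex
  intensity so narrow spikes do not pass on height alone.

Theoretical envelopes come from convolving per-element isotope patterns
(IUPAC abundances, CHNOPS + Na/Cl/F/K/Br/I) over integer neutron offsets,
truncated to `n_isotopomers = 5` aggregated peaks spaced ≈ 1.00336 Da.
Charge support is effectively $|z| = 1$; envelope spacing assumes singly
charged ions.

# Regression and post-filtering

Per accepted path the package fits OLS by default;
`method = "irls_bisquare"` uses iteratively reweighted least squares with
the bisquare ψ (tuning constant 4.685 on a MAD scale, ≤ 50 iterations,
convergence 1e-10) to resist occasional apex-picking errors. For the
robust fit, $R^2$ is computed against the final weighted fit; an exactly
collinear input short-circuits to OLS, whose solution the bisquare fit
shares. Post-filters (defaults): |mass error| ≤ 15 ppm, isotopic score
≥ 0.4, $R^2$ ≥ 0.96, and an optional lower bound on the path posterior
$P(T_k)$ (off by default; a typical conservative choice is 0.7). The
results store can reproduce exactly these bounds as SQL predicates, so
thresholds can be re-tuned after the fact by querying.

# The synthetic generator

`generate_frameset()` is the package's test surface and emulates a
stepped-field acquisition: seven fields spanning 10.8–18.5 V/cm over a
90 cm tube (4 torr, 300 K), 30 frames per field. Each ion contributes one
2D Gaussian per isotopomer centred at (isotopomer m/z, model arrival
time); the ATD FWHM is `dt_width_rel` × $t_A$, reproducing the
predictable broadening of a drifting ion cloud with a single knob
(default 0.025, i.e. resolving power 40; m/z width 15 ppm σ; apex
50 counts/frame). Axes default to 0.005 Da bins over ±2 Da per target
cluster and 0.1 ms bins over 0–80 ms. Noise is a uniform baseline
(default 0.5 counts/bin, 1% of the default apex) with optional Poisson
counting noise per bin and frame; decoys are explicit extra ions.

What it deliberately does **not** model: physically rigorous ion-cloud
diffusion, space-charge, TOF artifacts, chemical noise with structured
isotope patterns, mass-calibration drift, or detector saturation. Passing
tests therefore demonstrate the correctness of the extraction machinery
under the stated generative model, not robustness to every instrumental
pathology of real data.

# Numerical choices and problem sizes

- Field grouping is single-linkage clustering on voltage with a 0.5 V
  tolerance (gap splitting on the sorted voltages); per-group $p$, $T$,
  $V$ are arithmetic means over member frames, supporting slow per-frame
  drift.
- Path enumeration uses exact (cost, lexicographic) ordering, so
  equal-cost paths resolve deterministically; MAP ties break towards
  fewer paths, then higher summed on-path intensity.
- Every stochastic step is seeded once through the generator config;
  identical seeds give bit-identical stores and byte-identical library
  exports.
- Test problem sizes: the seven-field linearity check runs the full
  30-frames-per-field acquisition; the 100-ion recovery study and the
  100-replicate decoy study use compact acquisitions (5 and 3 frames per
  field, trimmed arrival-time ranges) so the whole suite remains quick
  while still exercising detection, association and regression end to
  end.

# Known limitations

- Conformers closer in mobility than roughly the ATD width collapse into
  one peak and cannot be separated afterwards.
- The isotopic score needs the first envelope strips inside the map's m/z
  range; targets at the very edge of the acquisition range lose envelope
  evidence (strips outside the axis contribute zero).
- $K_0$ from a negative or zero fitted slope is reported as `NA` and the
  record is rejected downstream rather than silently flipped.
- The identification is *targeted*: the package confirms and measures
  candidate ions for given formulae; it does not discover unknowns, and
  it cannot distinguish a conformer from a co-drifting isomer that
  passes every filter.
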