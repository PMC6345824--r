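---
title: "Methods: bloom phenology from coupled float and satellite chlorophyll"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bloom phenology from coupled float and satellite chlorophyll}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bloomphen)
```

## The problem

Satellite ocean-colour sensors provide the only long, synoptic record of
surface chlorophyll-a from which phytoplankton phenology metrics —
initiation, peak, termination and duration of the main growth period — can
be computed, but they only see the first optical depth of the ocean. In
stratified tropical systems most of the biomass can sit in a subsurface
chlorophyll maximum (SCM) invisible from space, so the question of whether
surface phenology represents the water column is an empirical one.
Biogeochemical profiling floats resolve the full vertical structure and can
arbitrate. `bloomphen` implements the computational chain needed for that
comparison: float-profile corrections and water-column diagnostics,
composite time-series construction from both platforms, and a change-point
phenology detector, together with a synthetic-data module that plants known
timings so the whole chain can be verified end to end.

## The phenology detector

Given a complete composite series $c_k$ ($k = 0, \dots, n-1$ bins of
`period_days` days, default 5):

1. **Threshold** $T = \mathrm{median}(c) \times 1.05$. The "median plus 5%"
   criterion is read multiplicatively (5% *of* the median), the convention
   of the threshold-criterion phenology literature; the additive reading
   (`median + 0.05` in series units) is available via
   `threshold_rule = "absolute"`. The multiplicative reading makes every
   detected index invariant to rescaling the series — asserted as a property
   test with $\lambda \in \{0.5, 2, 10\}$ — which matters because the three
   analysed series are on different scales (mg m⁻³ vs mg m⁻²).
2. **Anomalies and cumulative sums** $a_k = c_k - T$,
   $S_k = \sum_{j \le k} a_j$. The gradient of $S$ (first difference, with
   the first element kept as $a_0$) telescopes back to $a$ exactly, so
   sign changes of the gradient are threshold crossings of the series. Both
   formulations are kept: the detector works on the anomaly signs, and the
   test suite asserts equality with an independently coded brute-force
   threshold scan on 500 random series.
3. **Metrics.** The peak is the series maximum (first occurrence on ties —
   the earliest peak gives the earliest admissible termination window and
   is deterministic). Initiation is the first bin of the above-threshold
   excursion containing the peak; termination is the first bin after the
   peak with a negative anomaly; duration is the index difference.
   Anomalies exactly zero are neither a rise nor a fall.

Edge conventions, since a detector must return *something* on degenerate
input: a series never exceeding the threshold sets `no_initiation` (and
`no_termination`) with absent indices; a series already above threshold in
bin 0 reports initiation 0 with `initiation_at_start`; no negative anomaly
after the peak sets `no_termination`; several distinct excursions set
`multiple_growth_periods`, and the reported metrics describe the excursion
holding the global peak — the *main* growth period. The year is treated as
linear (no wrap-around): the analysis window is chosen, as here, so the
growth period is interior. All flags are data in the report, never errors.

## Composites, gaps and matchups

Bins are anchored at the first observation date: bin $k$ covers the
half-open day interval $[k p, (k+1) p)$ from the origin, and a sample on a
boundary belongs to the later bin. Day-of-series is counted from zero, so a
planted transition on day $d$ falls in bin $\lfloor d/p \rfloor$. Empty
bins are masked gaps; because the cumulative-sum method needs a gap-free
series, interior gaps are filled by linear interpolation between observed
neighbours (the 1-D linear least-squares limit of grid in-painting) and
leading/trailing gaps by constant extension from the nearest observation —
extrapolating a trend into an unobserved series end can manufacture a
spurious crossing, constant extension cannot. Filling is idempotent and
marks every filled bin, and rank correlations between series pair only
observed bins, so interpolation never inflates agreement statistics. The
Spearman correlation (average ranks, two-sided p) reports its pair count
`n` rather than asserting any particular value: with irregular float
sampling the observed-pair count is a property of the data, not of the
method.

Satellite matchup follows the float sampling date exactly, takes the
nearest grid pixel by nearest latitude and longitude independently (an
exact midpoint ties deterministically toward the smaller coordinate), and
averages a 3-pixel longitudinal window centred on it; missing pixels drop
out of the mean and a fully missing window becomes a downstream gap.

## Profile corrections and diagnostics

The correction order is dark offset → calibration factor → NPQ, applied at
most once each (a provenance log on the profile guards re-entry, and
`derive_all` records every applied or skipped step):

- **Dark offset**: median chlorophyll in a deep window (default 900–1000 m,
  just above a typical float parking depth) subtracted everywhere, clipped
  at zero with the clip count logged. Fewer than 3 deep samples skips the
  correction with a warning rather than guessing.
- **Calibration**: division by the community-established factor of 2 for
  WET Labs ECO fluorometers (a plain divisor, so it can be disabled with 1).
- **NPQ**: daytime fluorescence above the depth of the mixed-layer
  fluorescence maximum is replaced by that maximum. This is a documented
  stand-in for empirical shallow-mixing quenching corrections whose full
  parameterisation is not reproduced here; it never decreases a value and
  is switchable off. Its known bias: when an SCM shoulder reaches into the
  mixed layer, the extrapolated maximum slightly exceeds the true surface
  value, so noise-free platform-equality tests disable it. Timing metrics
  are insensitive to this bias (it is smooth in time and small relative to
  the bloom contrast).
- **Oxygen**: a multiplicative optode gain (default 1.06).

Diagnostics: euphotic depth $Z_{eu}$ is where PAR reaches 1% of the
shallowest valid sample, interpolated on $\log(\mathrm{PAR})$ — exact for
exponentially decaying light, which the closed-form tests
($Z_{eu} = \ln(100)/K_d$ for $K_d \in \{0.03, 0.05, 0.1\}$ m⁻¹) exercise.
The first optical depth is exactly $Z_{eu}/4.6$. Surface chlorophyll is the
trapezoidal (depth-weighted) mean over the first optical depth — whether a
plain sample mean or a depth-weighted one is intended by the convention is
ambiguous; depth weighting is chosen because it is grid-independent, and
recorded here. Integrals are trapezoidal with linearly interpolated band
edges and constant shallow-end extension; additivity over adjacent bands
holds to machine precision. MLD uses the density-threshold method
(0.03 kg m⁻³ above the density at 10 m, crossing linearly interpolated);
when the threshold is never crossed the profile bottom is returned with
`mld_at_profile_bottom` rather than an absent value, so deep winter-mixing
profiles keep their place in time series. $N^2 = (g/\bar\rho)\,
\Delta\rho/\Delta z$ at pair mid-depths, negative values kept and flagged.
Density is taken as supplied; when only T/S are present a one-atmosphere
EOS-80 sigma-t is computed (`sw_sigma0`) — adequate for upper-ocean MLD and
stratification work, and deliberately not load-bearing in any test.

## The synthetic generator

`synthetic_scenario` plants a full annual cycle and returns its ground
truth. The truth chlorophyll field is a mixed-layer plateau (bloom-window
value inside $[b_0, b_1)$, background outside) tapering linearly to zero
over 10 m below the scheduled MLD — a discontinuity there would be
amplified by trapezoidal integrals — plus a Gaussian SCM whose amplitude
schedule is zero inside the bloom window (erosion by deep mixing) and whose
depth deepens from 75 to 100 m after it. The emitted fluorescence adds the
instrument effects the profile module must undo: NPQ depression above a
fixed quench depth, a dark offset (default 0.02 mg m⁻³), and multiplicative
lognormal noise (unit mean, CV `noise_cv`) so concentrations stay positive.
Density is a two-layer profile whose pycnocline ramp is offset so the
0.03 kg m⁻³ criterion is crossed exactly at the scheduled MLD in the
continuous field — sampling then bounds the recovered MLD within one grid
step by construction. PAR is a single surface value under constant
exponential attenuation (only the 1% ratio matters to $Z_{eu}$). The
satellite series shares the truth field: each window's noise-free mean is
the truth chlorophyll averaged over the first optical depth with the same
surface-reference convention as the float pipeline, which is what makes the
noise-free coupled equality (and hence $\rho = 1$) hold bin-by-bin.

Defaults are the study conditions: a 365-day series from 30 September, one
profile per day (the emulated float cycled every 1–10 days; the interval is
a knob), a 1–1000 m metre grid, background 0.1 / bloom 0.5 mg m⁻³ surface
chlorophyll, bloom window days 90–185 (a December–March growth period),
MLD 30 m deepening sinusoidally to 200 m during the bloom,
$K_d = 0.05$ m⁻¹ ($Z_{eu} \approx 92$ m, SCM just above it), pycnocline
step 0.5 kg m⁻³. Noise CV 0.1, 10% satellite gaps and 30% NPQ depression
are conventions — the real series' noise and gap statistics are not
quantified anywhere usable — and are flagged as such here. What the
generator does *not* emulate, and what passing tests therefore do not
show: advection and eddies, sensor drift, photoacclimation (chlorophyll
varying per unit biomass), realistic cloud-cover autocorrelation in the gap
pattern, or any bio-optical coupling beyond exponential PAR.

Planted transitions in the recovery tests are placed on composite-period
boundaries. This is deliberate: at 5-day resolution "the bin containing the
planted day" is only a sharp target for boundary-aligned transitions — an
off-boundary termination leaves the partial bin's mean above threshold by
construction and detection lands one bin later. Off-boundary robustness is
what the noise-and-gaps agreement test measures (±1 period).

## Problem sizes and numerics

Pipeline-level tests and the acceptance script use a 5 m depth grid
(1–1000 m, 200 levels) with daily profiles over a 365-day year; recovery
tests that probe grid-step accuracy use the full 1 m grid with 10-day
sampling. The planted-recovery grid is 20 scenarios (bloom onsets every 25
days × durations of 50 and 100 days); the platform-agreement experiment is
100 seeded noisy runs. Detection itself is exact integer arithmetic on
anomaly signs; the only tolerances in the package are the matchup tie-break
(10⁻⁹ degrees, absorbing floating-point midpoints) and the closed-form test
tolerances (1% for $Z_{eu}$ and $N^2$, 0.5% for the Gaussian integral,
one grid step for MLD). All generation is deterministic given the scenario
seed, the satellite stream is decoupled from the profile stream (seed + 1),
and the caller's RNG state is restored afterwards; reports with the same
config and seed are byte-identical, which the suite asserts on the emitted
files.

## Limitations

The NPQ stand-in is the largest simplification (see above). The equation of
state ignores pressure, so `sw_sigma0` should not be used below a few
hundred metres when density differences matter. The detector offers no
wrap-around year and no alternative phenology definitions (biomass-fraction
timings, Gaussian bloom fits). Real Argo quality-control flag handling is
out of scope: the reader accepts the documented CSV profile dialect, and
ingest assumes depth in metres (≈1 dbar per metre near the surface if
converting from pressure upstream).
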