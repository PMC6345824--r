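# bloomphen

Phytoplankton bloom phenology from float and satellite chlorophyll.

Ocean-colour satellites observe chlorophyll-a only in the first optical
depth of the water column, yet satellite time series are the main source of
phytoplankton phenology metrics — the timings of growth-period initiation,
peak and termination, and the duration between them — used as ecosystem
indicators in tropical seas. Biogeochemical profiling floats measure the
same quantity through the whole water column, including the subsurface
chlorophyll maximum (SCM) that satellites cannot see. `bloomphen`
implements, as a tested and reusable pipeline, the workflow for comparing
phenology estimated from the two platforms:

- **Profile corrections and diagnostics** — fluorometric dark-offset
  removal, the factor-of-2 fluorescence calibration bias, a daytime
  non-photochemical quenching (NPQ) correction for shallow-mixing waters, a
  dissolved-oxygen gain; euphotic depth Zeu from the 1% PAR level, first
  optical depth Zeu/4.6, surface-layer and depth-integrated chlorophyll,
  mixed-layer depth (MLD) by the 0.03 kg m⁻³ density-threshold criterion
  against the density at 10 m, and the Brunt–Väisälä frequency
  N² = (g/ρ̄)(Δρ/Δz).
- **Time-series construction** — satellite pixel matchup (nearest pixel
  plus a 3-pixel longitudinal window), 5-day compositing with a half-open
  bin convention, and linear gap filling with constant end extension.
- **Phenology detection** — the cumulative-sums-of-anomalies change-point
  method: with threshold *T* = median × 1.05, anomalies *aₖ = cₖ − T*
  accumulate to *Sₖ = Σⱼ≤ₖ aⱼ*; initiation is the composite period where the
  gradient of *S* first turns positive within the excursion containing the
  peak (the series maximum), termination the first negative gradient after
  the peak, duration their index difference.
- **Synthetic scenarios** — a generator that plants a known annual cycle
  (surface bloom window, SCM at 75–100 m eroded during deep mixing, a
  scheduled MLD with a pycnocline density step, exponential PAR,
  lognormal observation noise, satellite gaps, NPQ depression) so every
  stage is testable against ground truth without any data downloads.

## Worked example

```r
library(bloomphen)

sc  <- synthetic_scenario(depth_grid = seq(1, 1000, by = 5),
                          bloom_start_day = 90, bloom_end_day = 180,
                          noise_cv = 0, gap_fraction = 0, seed = 1)
rpt <- run_pipeline(run_config(scenario = sc))
rpt
```

```
<comparison_report> 365 profiles, 365 matchups, sources: sat_surf, argo_surf, argo_int
<phenology_metrics sat_surf> threshold 0.1051
  initiation : bin 18 (2015-12-29)
  peak       : bin 18 (2015-12-29)
  termination: bin 36 (2016-03-28)
  duration   : 18 periods of 5 days
...
  sat_surf -> argo_surf: initiation +0, peak +0, termination +0 periods
  rho(sat_surf, argo_surf) = 1.000 (n = 73, p = 0)
```

The scenario plants a growth period on days 90–180 of a 365-day series
starting 2015-09-30. Both the satellite surface series and the float
surface series (chlorophyll averaged over the first optical depth) detect
initiation in 5-day bin 18 — the bin containing day 90 — and termination in
bin 36, containing day 180; with noise off the two platforms agree to the
bin and correlate perfectly. Metrics for the euphotic-depth-integrated
series (`argo_int`), pairwise timing differences and Spearman correlations
are also in the report; `output_dir` writes `report.json`, `metrics.csv`
and the per-series diagnostics (anomaly, cumulative sum, gradient) as CSV.

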