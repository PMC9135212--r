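# pestsurv

Spatiotemporal analysis of urban pest-complaint surveillance data.

Municipal reporting systems (311 inquiry lines, housing maintenance code
complaints) are the largest available proxy for the burden of urban
pests such as bed bugs. `pestsurv` implements the analysis chain used to
characterize such data at the neighbourhood level, together with a
synthetic-data generator so that every stage is testable without the
administrative extracts themselves:

1. **Harmonic trend regression** for monthly complaint series: OLS on
   `[1, t, sin ωt, cos ωt, t·sin ωt, t·cos ωt]` (ω = 2π/12), the
   standard linearization of annual seasonality whose amplitude changes
   linearly in time. The secular trend is a t-test on the linear
   coefficient; the instantaneous seasonal amplitude is
   `A(t) = sqrt((β₂+β₄t)² + (β₃+β₅t)²)`.
2. **Indirect standardization**: expected counts `E_i = r·n_i` with
   reference rate `r = Σy/Σn` per stratum (year by default), and
   standardized incidence ratios `SIR_i = y_i/E_i`.
3. **Bayesian hierarchical spatiotemporal Poisson model**:
   `y_it ~ Poisson(E_it·exp(η_it))` with
   `η_it = b₀ + u_i + v_i + γ_t + φ_t + δ_it` — BYM spatial convolution
   (ICAR `u` + iid `v`), RW2 temporal `γ` + iid `φ`, and a space–time
   interaction `δ` of Knorr-Held type I (iid), II (RW2 in time within
   area) or III (ICAR in space within period). Fitting is
   Metropolis-within-Gibbs MCMC (Rcpp core) with conjugate Gamma
   precision updates using generalized ranks, sum-to-zero constraints
   enforced by re-centring every sweep, and model comparison by DIC.
4. **Readers** for 311-style CSV exports (configurable column dialects,
   keyword extraction for pest-specific records) and GeoJSON
   neighbourhood polygons (queen contiguity), plus plain-text edge-list
   and long-format panel CSV formats shared across all stages.

The methods vignette (`vignettes/spatiotemporal-surveillance.Rmd`)
documents the models, priors, constraint handling, generator
calibration and known limitations.

## Worked example

```r
library(pestsurv)

# a disconnected areal lattice (two 4x4 components, like a city with an
# island borough) and six years of monthly counts
lat <- make_lattice(4, 4, n_components = 2, seed = 1)
lat
#> area_lattice: 32 areas, 48 edges, 2 component(s)

# citywide monthly series: summer peaks, decaying amplitude, declining trend
s <- simulate_monthly_series(72, level = 100, trend_slope = -0.5,
                             amplitude_start = 20, amplitude_slope = -0.15,
                             phase = 2 * pi * 7 / 12, noise_sd = 3, seed = 2)
fit_harmonic_trend(s)
#> Harmonic trend fit: simulated (n = 72 )
#>            estimate      se
#> intercept 101.10143 0.80064
#> trend      -0.52754 0.01946
#> sin       -11.85402 1.14572
#> cos       -19.03052 1.11126
#> t_sin       0.10130 0.02759
#> t_cos       0.16967 0.02729
#> trend t = -27.104, p = 1.74e-37; amplitude-change F = 25.929, p = 4.9e-09
#> R-squared = 0.955
```

The trend coefficient recovers the simulated decline of −0.5 complaints
per month (p < 0.001), and the amplitude-change test confirms the
shrinking seasonal swing.

```r
# area x month panel -> yearly SIRs -> spatiotemporal model
cfg <- sim_config(grid_rows = 4, grid_cols = 4, n_components = 2,
                  T_months = 72, seed = 1)
sim <- simulate_panel(lat, cfg)
yearly <- sir(expected_counts(aggregate_panel_years(sim$panel)))
head(yearly, 3)
#>    area_id year population   y        E      sir
#> 1     A001    1   42878.41 168 126.5682 1.327347
#> 7     A002    1   54073.01 170 159.6124 1.065080
#> 13    A003    1   75149.60 250 221.8262 1.127009

names(yearly)[names(yearly) == "year"] <- "time"
fit_st_model(yearly, lat,
             st_model_spec("I", n_iter = 4000, n_burn = 1500, thin = 2,
                           seed = 3))
#> Spatiotemporal Poisson model fit (interaction type I)
#> 32 areas x 6 periods; 1250 retained draws
#> DIC = 1567.9 (p_d = 52.1, mean deviance = 1515.8)
#>                         component parameter       mean     q025      q975
#> 1                       Intercept        b0   -0.04151  -0.1085 3.241e-02
#> 2        Spatial BYM (structured)     tau_u 1061.48458  99.9923 4.455e+03
#> 3               Spatial BYM (IID)     tau_v   14.51245   8.3204 2.297e+01
#> 4                    Temporal RW2 tau_gamma 3035.07645 391.4281 8.870e+03
#> 5                    Temporal IID   tau_phi 4348.05605 782.4718 1.176e+04
#> 6 Space-time interaction (type I) tau_delta 1978.17701 639.1405 5.022e+03
```

The intercept's credible interval covers the simulated truth (b₀ = 0),
and the spatial IID precision (truth 20) is recovered at 14.5 with a 95%
interval of (8.3, 23.0). `relative_risk(fit, "interaction")` and
`relative_risk(fit, "full")` return the posterior-mean risk surfaces;
`compare_models()` fits several interaction types and ranks them by DIC.

## The analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # lattice, monthly panel, citywide series
Rscript analysis/02_trend.R        # harmonic fits + concordance regression
Rscript analysis/03_standardize.R  # yearly expected counts and SIRs
Rscript analysis/04_stmodel.R      # ST model fits, DIC comparison, RR export
```

`run_pipeline()` wires the same stages into a single seeded call and
writes a manifest, so a fixed seed reproduces every output byte for
byte.

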