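# teleplan

Biodemography-coupled larval dispersal modelling for marine invertebrates.

Many benthic marine animals disperse only as planktonic larvae, so the time
a larva can survive in the water column — its pelagic larval duration
(PLD) — sets the geographic reach of a generation. `teleplan` implements a
complete desk-scale pipeline for asking how differences in larval mortality
translate into differences in dispersal:

1. **Mortality estimation.** Larval abundance in culture follows the
   exponential (instantaneous-rate) survival model
   *N_t = N₀ e^(−Mt)*, with *M* (day⁻¹) the instantaneous mortality rate.
   `fit_mortality()` estimates *M* by OLS on ln(abundance) vs time from raw
   aliquot census counts and returns a classed model object with the usual
   `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate`
   methods.
2. **Fecundity and PLD.** `estimate_fecundity()` back-calculates clutch
   size *N₀* from serial-dilution counts; `pld_last_survivor()` computes
   the clutch-exhaustion PLD, *t\* = ln(N₀)/M* — the age at which the last
   larva of the clutch is expected to survive.
3. **Lagrangian dispersal.** `make_ocean()` builds analytic,
   divergence-free velocity fields (uniform, solid-body, double-gyre,
   meandering coastal jet) with coastline, shelf, and bathymetry;
   `run_release()` advects virtual larvae with an RK4 kernel under a
   weekly release schedule; `detect_settlement()` applies the
   500 m-isobath shelf settlement rule with a minimum competency age
   (default 25 days); `run_scenarios()` and `compare_paired()` run
   paired two-PLD experiments and test per-cohort metrics (abundance,
   displacement, settled area) with paired t tests on log scale;
   `iterate_generations()` steps multi-generation range expansion until a
   target region is reached.

Synthetic data generators (`simulate_survival()`,
`simulate_dilution_counts()`, the ocean recipes) make the whole pipeline
runnable and testable without any external data.

## Worked example

Fit mortality in light- and dark-reared cultures (here simulated at rates
0.093 and 0.165 day⁻¹, the kind of contrast seen in light-dependent
developmental benefits), then derive the two PLDs from a shared fecundity:

```r
library(teleplan)

sims_light <- simulate_survival(survival_sim_spec(n0 = 2000, m = 0.093,
                                                  treatment = "light", seed = 101))
sims_dark  <- simulate_survival(survival_sim_spec(n0 = 2000, m = 0.165,
                                                  treatment = "dark", seed = 102))
(fit_light <- fit_mortality(sims_light))
#> Exponential survival model  N_t = N0 * exp(-M t)
#>   treatment: light
#>   M     = 0.09658 day^-1  (SE 0.009998)
#>   ln N0 = 7.638  (N0 ~ 2075)
#>   fit: pooled, 60 census points, R^2 = 0.617
(fit_dark <- fit_mortality(sims_dark))
#>   M     = 0.1754 day^-1  (SE 0.01094)  ...

fec <- estimate_fecundity(c(10, 10, 10), aliquot_ml = 0.5,
                          dilution_factors = c(100, 100), total_ml = 100)
#> Fecundity estimate: N0 = 2e+07 eggs

scenario_durations(c(light = fit_light$m, dark = fit_dark$m), n0 = fec$n0)
#>   scenario          m  pld_days    ln_n0
#> 1    light 0.09658356 174.05905 16.81124
#> 2     dark 0.17540295  95.84356 16.81124

round(survival_ratio(fit_light$m, fit_dark$m, 5), 2)   # 1.48x at 5 dph
round(duration_ratio(174.06, 95.84), 2)                # 1.82x longer PLD
```

The fitted rates recover the simulated truth to within one standard error;
the lower mortality roughly doubles the time a clutch can stay at sea.
Feed the two durations into a paired dispersal experiment on a synthetic
meandering coastal jet:

```r
field <- make_ocean(ocean_spec(
  lon = c(-30, -14), lat = c(0, 30), dx = 0.5, dy = 0.5, days = 1,
  recipe = "coastal_jet_with_eddies",
  params = list(v_jet = 0.4, jet_offset_km = 120, jet_width_km = 100,
                meander_amp_km = 150, meander_wavelength_km = 600),
  coast_lon = -15, shelf_width_km = 120))
habitat <- shelf_mask(field, region = list(lon = c(-30, -14), lat = c(0, 20)))
sched <- release_schedule(data.frame(lon = -16, lat = 28), n_per_event = 25,
                          n_events = 6, interval = 7, jitter_deg = 0.25,
                          cohort_length = 14)
run <- run_scenarios(list(dispersal_scenario("light", 181),
                          dispersal_scenario("dark", 102)),
                     field, sched, habitat, dt = 0.25, seed = 13)
head(run$metrics, 2)
#>   cohort scenario n_settled mean_displacement_km settled_area_km2 n_released
#> 1      0    light        50             1194.795         5904.026         50
#> 2      1    light        50             1198.504         5904.026         50

compare_paired(run$metrics, "n_settled", scenario_order = c("light", "dark"))
#> Paired comparison of n_settled (light vs dark), ln-transformed
#>   ratio = 1.07, t(2) = 3.65, two-tailed p = 0.0676
```

Both scenarios share one trajectory set (particles are passive and the
random draws do not depend on lifetime), so the comparison is exactly
paired: the longer PLD settles a superset of the shorter one in every
cohort, and the ratios measure the effect of pelagic duration alone.

See `vignettes/dispersal-methods.Rmd` for the models, assumptions, and
design decisions in full.

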