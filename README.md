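# synseasons

Tools for understanding the seasonal population dynamics of coastal
*Synechococcus* (and similar picophytoplankton) from automated hourly flow
cytometry. The central question such time series pose is how much of a
change in cell concentration comes from cells dividing versus cells being
lost (grazing, viral lysis, advection). Concentration alone cannot answer
it; the diel reshaping of the population's cell-*size* distribution can.

## What the package computes

**Division rate from size distributions.** Cell volumes are binned on a
log2 lattice with *p* classes per doubling. In each 10-minute step a cell
grows into the next class with probability
γ(E) = γ<sub>max</sub>(1 − e<sup>−E/E\*</sup>) (E = incident radiation),
divides into two cells *p* classes down with probability
δ<sub>i</sub> = δ<sub>max</sub>/(1 + e<sup>−η(ln v<sub>i</sub> − ln v\*)</sup>),
or remains. Projecting dawn-to-dawn gives hourly predicted class
proportions q<sub>k</sub>(θ) and a realized division rate
μ = ln(N<sub>end</sub>/N<sub>start</sub>). Hourly observed counts are
modelled as Dirichlet-multinomial with α = c·q<sub>k</sub> (one
overdispersion precision c per day), and θ is estimated per day by
multi-start bounded maximum likelihood (`fit_day()`). Because the
likelihood sees only proportions, the estimate is independent of cell
concentration — uniform thinning by grazers does not move it.

**Everything around it.**

- `net_growth_rate()` — μ<sub>net</sub>(t) = ln(N̄(τ+24h)/N̄(τ)) from
  48-h-smoothed hourly concentrations averaged over a 3-h dawn window;
  `loss_rate()` = μ − μ<sub>net</sub>; `production_estimate()` for rough
  carbon production.
- `compute_par()`, `fit_kd()`, `kd_climatology()`,
  `mean_light_at_depth()` — PAR attenuation coefficients from irradiance
  profiles (ln E(z) = b − K<sub>d</sub>z) and depth-averaged light
  E₀(1 − e<sup>−K<sub>d</sub>H</sup>)/(K<sub>d</sub>H) for a mixed column.
- `classify_stratification()`, `regress_theta_sigma()`,
  `daily_stratification()`, `fill_temperature_gaps()` — a stratification
  index from paired 4-m/12-m temperatures calibrated against CTD density
  profiles (0.2 kg m⁻³ / 0.68 °C thresholds, strict two-thirds-of-daylight
  daily rule).
- `population_mode()`, `daily_features()`, `bead_normalize()` — daily
  cell-property series: minimum modal volume, dawn modal phycoerythrin
  fluorescence.
- `daily_climatology()`, `weekly_median_climatology()`, `anomalies()`,
  `monthly_median()` — multi-year seasonal patterns.
- `fit_light_response()`, `fit_by_temperature_bins()` — saturating
  μ = μ<sub>max</sub>(1 − e<sup>−αE/μ<sub>max</sub></sup>) curves, pooled
  and within 2 °C temperature bins, with light-limited/saturated day
  classification.
- `gen_environment()`, `gen_observation_day()`,
  `gen_concentration_series()`, `gen_irradiance_profiles()`,
  `gen_hydrography()` — synthetic-data generators for every input, so the
  whole pipeline runs with no external data; `run_all()` orchestrates all
  stages and writes a reproducible manifest.

See `vignettes/division-rate-methods.Rmd` for the model, its assumptions
and the numerical choices.

## Worked example

Generate one synthetic day with a known division rate of 0.7 d⁻¹, observe
1000 cells per hour, and re-estimate the rate from the hourly size
distributions alone:

```r
library(synseasons)

env   <- gen_environment(scenario_config(seed = 1, n_days = 365))
light <- dawn_window_light(env, 150)          # 10-min light, dawn to dawn
truth <- calibrate_division_rate(0.7, light)  # params whose true rate is 0.7
obs   <- gen_observation_day(truth, light, cells_per_hour = 1000, seed = 2)
fit   <- fit_day(obs, light, fit_config(n_subpops = 1))
round(c(true = obs$meta$true_rate, estimated = fit$division_rate), 3)
#>      true estimated
#>     0.700     0.715
```

The estimate (0.715 d⁻¹) recovers the generating rate to within the
sampling noise of 25 hourly count vectors. The light environment works the
same way:

```r
kd <- fit_kd(gen_irradiance_profiles(0.25, noise_cv = 0.05, seed = 3))
c(kd = kd$kd, r_squared = kd$r_squared)
#>        kd r_squared
#> 0.2494    0.998
mean_light_at_depth(20, kd$kd)   # MJ m^-2 d^-1 averaged over a 15-m column
#> [1] 5.22
```

A 20 MJ m⁻² day at the surface averages to ~5.2 MJ m⁻² over a well-mixed
15-m column at this attenuation — the magnitude of light reduction that
makes depth-averaging matter for interpreting light limitation.

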