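---
title: "Estimating picophytoplankton division rates from diel size distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating picophytoplankton division rates from diel size distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synseasons)
```

## The problem

Coastal *Synechococcus* populations cycle through an annual pattern of
bloom and decline. Interpreting that pattern requires separating two
per-capita rates that jointly set the change in cell concentration: the
division rate $\mu$ (how fast cells are produced) and the loss rate $\ell$
(grazing, viral lysis, advection). Concentration data alone cannot separate
them. An automated flow cytometer sampling hourly, however, observes the
*size distribution* of the population through the day, and the diel
signature of synchronized growth and division in that distribution carries
enough information to estimate $\mu$ without using concentrations at all.
`synseasons` implements that estimator together with the supporting
analyses a seasonal interpretation needs: the in-situ light environment, a
stratification index, net-growth and loss rates, daily cell-property
series, climatologies, and division-rate versus light response curves. A
synthetic-data module generates every input the pipeline consumes, so the
whole chain is testable without instrument data.

## The size-structured matrix model

Cell volumes are binned onto a log2 lattice (`size_grid()`): class $i$ has
center $v_{\min} 2^{(i-1)/p}$ with $p$ classes per volume doubling
(defaults $v_{\min} = 0.02\,\mu m^3$, $p = 4$, $m = 25$ classes, spanning
roughly 0.02–1.3 $\mu m^3$ — wide margin around the 0.25–0.6 $\mu m^3$
modal volumes typical of temperate coastal *Synechococcus*). The lattice
makes division exact: halving a class-$i$ volume lands on the center of
class $i-p$.

In each 10-minute step a cell may:

* **grow** into the next class with probability
  $\gamma(E) = \gamma_{\max}\,(1 - e^{-E/E^*})$, a saturating function of
  the instantaneous incident radiation $E$ (W m$^{-2}$); at night
  $\gamma = 0$;
* **divide** into two cells of class $i - p$ with probability
  $\delta_i = \delta_{\max} / (1 + e^{-\eta(\ln v_i - \ln v^*)})$, a
  logistic function of log volume with threshold $v^*$ and steepness
  $\eta$; classes $i \le p$ cannot divide (their daughters would fall off
  the grid);
* or **remain** in its class.

The top class retains its growth fraction, and the model has no mortality,
so total model cells never decrease. The starting size distribution of each
subpopulation is log-normal ($\mu_{LN}, \sigma_{LN}$), binned by CDF
differences across class edges; one or two subpopulations can be mixed with
weight $f$. Projecting dawn-to-dawn (144 steps) yields hourly predicted
proportion vectors $q_k$ and the realized division rate
$\mu = \ln(N_{end}/N_{start})$.

Only the *dependencies* of growth (on light) and division (on size) are
constrained by the underlying science; the specific saturating-exponential
and logistic forms used here were chosen as the smoothest bounded
two-parameter options in the model family, and are stated as package
design decisions. Likewise "light" means the within-day 10-minute incident
series, not a daily scalar: a single scalar could not produce diel size
structure.

## Observation model and fitting

Hourly counts $y_k$ over size classes are modelled as
Dirichlet-multinomial with parameters $\alpha = c\,q_k(\theta)$: a
multinomial whose cell-to-cell overdispersion is controlled by a single
per-day precision $c$ (large $c$ recovers the multinomial). The likelihood
uses only proportions, never totals, which is what makes the estimator
insensitive to grazing or any other process that thins cells uniformly.

`fit_day()` maximizes the summed Dirichlet-multinomial log-likelihood over
$\theta$ with bounded L-BFGS-B from Latin-hypercube start points (default
20; one start is data-informed from the first hour's moments). Missing
hours are dropped from the sum — no imputation — and days with fewer than
20 of 25 hourly observations are flagged unusable. One- and
two-subpopulation configurations are both fitted when requested and the
winner is chosen by BIC; convergence tolerance is $10^{-6}$ with ties
broken by first-found. All randomness flows from one integer seed, so a
repeated fit is bit-identical.

Numerical notes: predicted proportions are floored at $10^{-12}$ and
renormalized inside the objective so that an observed count in a class
where the projection has underflowed produces a finite penalty rather than
a $-\infty$ cliff; the multinomial coefficient (constant in $\theta$) is
dropped during optimization and added back when reporting the
log-likelihood; the projection loop is compiled code since it sits inside
the likelihood.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions:

* **Environment** (`gen_environment()`): hourly temperature is a sinusoid
  through configured extrema (defaults 0 °C in mid-February, 21 °C in
  mid-August) with optional AR(1) noise; daily radiation is a sinusoid
  between 4 and 26 MJ m$^{-2}$ d$^{-1}$ anchored at the solstice; within-day
  light is a half-sine over the daylight period from solar geometry
  (NOAA sunrise equations) at the default site (41.3°N, 70.6°W), sampled at
  10-minute midpoints so the step sums integrate to the daily value.
  Solar geometry also defines "dawn" (sunrise rounded to the hour) and
  "daylight" (elevation above the horizon), since neither has another
  operational definition.
* **Observations** (`gen_observation_day()`): forward-projects the model,
  draws Dirichlet-multinomial counts per hour, then thins cells
  independently — grazing that removes cells without changing the size
  distribution.
* **Concentrations** (`gen_concentration_series()`): exponential growth
  from daily division minus loss, modulated at the M2 tidal period
  (12.42 h) and lognormal noise.
* **Light profiles** (`gen_irradiance_profiles()`): exponential attenuation
  with lognormal depth noise; optional green-peaked spectra (peak near
  545 nm, as for coastal water) whose 400–700 nm integral equals the scalar
  PAR — the spectral shape is cosmetic, only the PAR integral is consumed.
* **Hydrography** (`gen_hydrography()`): three designed density scenarios
  (well-mixed; a ≥ 0.3 kg m$^{-3}$ step between 3 and 12 m; a step confined
  to the top 3 m) with paired 4-m/12-m temperature series consistent with
  the density scenario and 5% of hours masked as gaps.

What passing tests on these data do **not** show: real size distributions
include measurement noise correlated across classes, populations mix more
than two components, grazing need not be size-uniform, and real light
fields have clouds and spectral variation. The generators establish that
the estimator recovers what it is defined to estimate under its own
assumptions — a necessary, not sufficient, condition for field use.

## Supporting analyses

**Light.** PAR is the 400–700 nm trapezoid integral of dark-subtracted
spectral irradiance; negative post-subtraction values are treated as
missing rather than zeroed, to avoid a systematic bias in either
direction. $K_d$ comes from OLS of $\ln E(z)$ on depth; cast values are
averaged within a deployment, deployment means within 14 days of each
other are merged, and the merged points are interpolated linearly over
year day with periodic wrap (the year is a circle; un-wrapped
interpolation would leave the winter boundary undefined). Depth-averaged
exposure in an $H$-m mixed column uses the closed form
$\bar E = E_0 (1 - e^{-K_d H})/(K_d H)$ ($H = 15$ m by default), with
numeric quadrature retained as the test oracle.

**Stratification.** A profile is stratified when potential density deviates
more than 0.2 kg m$^{-3}$ from a surface reference — or from the 4-m
reference when the feature is confined to the top 3 m. The paired-depth
temperature proxy uses the calibration regression
$\Delta\theta = -0.0354 - 3.24\,\Delta\sigma$ and a threshold of 0.68 °C;
a day is stratified when strictly more than two-thirds of its daylight
hours with data exceed the threshold. The 0.68 °C value is kept as a fixed
configurable constant rather than recomputed from the regression: the
regression evaluated at $\Delta\sigma = -0.2$ gives ≈ 0.61 °C, and since
the rounding path between the two published constants is unknowable, both
are exposed in configuration.

**Rates.** Net growth is
$\mu_{net}(t) = \ln\bigl(\bar N(\tau + 24h)/\bar N(\tau)\bigr)$ on a
48-hour centered, missing-aware running mean of hourly concentration, with
$\bar N$ the 3-hour average around dawn; loss is $\ell = \mu - \mu_{net}$,
exactly, on every row. Window coverage is judged against the full 48-hour
span, so heavily truncated edge windows return missing instead of a biased
mean. The production estimate uses $N(e^{\mu}-1)$ new cells per day by
default ($N\mu$ available as the linear alternative); the carbon:volume
ratio is a required input with no asserted default.

**Cell properties.** Hourly population modes are histogram modes on a fixed
log lattice (64 bins per decade, ties to the lower bin — deterministic,
unlike a kernel density). The daily volume feature is the minimum hourly
mode (insensitive to division-driven afternoon growth); PE fluorescence is
the dawn mode; PE per volume divides by the *same-hour* dawn volume mode,
keeping both factors from the same physiological moment.

**Climatologies.** Daily climatologies are year-day means (Feb 29 dropped
first so day numbers align across years); weekly climatologies are medians
of pooled raw daily values — never medians of daily climatology values;
monthly nutrient-style climatologies report pooled medians with
linear-interpolation quartiles. Week is $\lceil d/7 \rceil$ folded into
week 52.

**Light response.** $\mu = \mu_{\max}(1 - e^{-\alpha E / \mu_{\max}})$ is
fitted by bounded Levenberg–Marquardt from five seeded starts (the
$\alpha\,\mu_{\max}$ ridge is flat when all days are light-saturated), both
pooled and within left-closed 2 °C temperature bins from 0 to 22 °C. A day
is classified light-limited when its radiation falls below
$E_{90} = \mu_{\max}\ln 10 / \alpha$, the irradiance where the bin's curve
reaches 90% of its asymptote — a package choice of operational threshold
for a qualitative notion. Both incident and attenuated radiation are
accepted as the light variable.

## Problem sizes and verification

The test suite exercises the estimator at the scale the method is meant
for: a 50-day parameter-recovery study (true rates uniform in
0.05–1 d$^{-1}$, 1000 cells per hour) requiring median absolute error
≤ 0.05 d$^{-1}$ and 90th percentile ≤ 0.15 d$^{-1}$; a 20-day
thinning study (50% uniform thinning must shift the median estimate by
≤ 0.05 d$^{-1}$); exhaustive enumeration of the Dirichlet-multinomial for
all $n \le 6$, $k \le 3$; 200 Monte-Carlo replicates of $K_d$ estimation
under 5% lognormal noise (bias ≤ 2%); and byte-identical manifests for
repeated pipeline runs. Recovery and thinning studies use 6 optimizer
starts per day, the package's chosen balance of start-point coverage
against the multi-day study size; single-day analyses default to 20.

```{r quick-example, eval = FALSE}
env <- gen_environment(scenario_config(seed = 1, n_days = 365))
light <- dawn_window_light(env, 150)
truth <- calibrate_division_rate(0.7, light)
obs <- gen_observation_day(truth, light, cells_per_hour = 1000, seed = 2)
fit <- fit_day(obs, light, fit_config(n_subpops = 1))
c(true = obs$meta$true_rate, estimated = fit$division_rate)
```

## Known limitations

* The estimator assumes the within-day light series is known; at night
  growth is zero by default (a dark-growth floor is configurable but off).
* A single per-day precision $c$ is shared across hours; per-hour
  overdispersion is not modelled.
* The two-subpopulation fit doubles the parameter count on 25 observation
  vectors; BIC selection is conservative and summer assemblages with more
  than two components will be lumped.
* Loss cannot be partitioned into grazing, lysis and advection — only
  their sum is identified.
* The stratification index inherits the published inconsistency between
  its density and temperature thresholds (see above); both are exposed.
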