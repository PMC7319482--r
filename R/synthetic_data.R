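#' Scenario configuration for the synthetic-data generators
#'
#' Defaults emulate a temperate coastal site: water temperature cycling
#' between about 0 degC in mid-February and 21 degC in mid-August, and daily
#' integrated solar radiation between about 4 MJ m^-2 in late December and
#' 26 MJ m^-2 in late June.
#'
#' @param seed integer; fixed seed implies byte-identical outputs.
#' @param n_days number of days to generate (year days `1:n_days`).
#' @param latitude,longitude site coordinates (degrees, longitude positive
#'   east).
#' @param temperature_annual named vector `c(min, max, day_min, day_max)`
#'   (degC, degC, year day of minimum, year day of maximum).
#' @param radiation_annual named vector `c(min, max)` (MJ m^-2 d^-1); the
#'   annual maximum is anchored at the summer solstice (year day 172).
#' @param cells_per_hour expected counted cells per hourly sample.
#' @param thinning_fraction fraction of cells removed per hour uniformly at
#'   random (grazing emulation), in `[0, 1)`.
#' @param true_params a [model_params()] used by [gen_observation_day()].
#' @param kd_true PAR attenuation coefficient (m^-1).
#' @param temp_noise_sd AR(1) innovation SD for hourly temperature (degC).
#' @param rad_noise_cv lognormal CV of daily radiation (cloudiness).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, n_days = 30L,
                            latitude = 41.325, longitude = -70.567,
                            temperature_annual = c(min = 0, max = 21,
                                                   day_min = 45, day_max = 227),
                            radiation_annual = c(min = 4, max = 26),
                            cells_per_hour = 1000L,
                            thinning_fraction = 0,
                            true_params = NULL,
                            kd_true = 0.25,
                            temp_noise_sd = 0, rad_noise_cv = 0) {
  stopifnot(n_days >= 1, thinning_fraction >= 0, thinning_fraction < 1)
  if (temperature_annual[["min"]] >= temperature_annual[["max"]]) {
    stop("temperature extrema invalid: min must be < max")
  }
  if (radiation_annual[["min"]] >= radiation_annual[["max"]]) {
    stop("radiation extrema invalid: min must be < max")
  }
  if (is.null(true_params)) true_params <- default_true_params()
  structure(list(seed = as.integer(seed), n_days = as.integer(n_days),
                 latitude = latitude, longitude = longitude,
                 temperature_annual = temperature_annual,
                 radiation_annual = radiation_annual,
                 cells_per_hour = as.integer(cells_per_hour),
                 thinning_fraction = thinning_fraction,
                 true_params = true_params, kd_true = kd_true,
                 temp_noise_sd = temp_noise_sd, rad_noise_cv = rad_noise_cv),
            class = "scenario_config")
}

#' Default generating parameters for one subpopulation
#'
#' A single subpopulation with modal starting volume near 0.28 um^3,
#' moderate light-saturated growth and a division threshold near twice the
#' starting mode, giving realized division rates around 0.5-0.7 d^-1 under
#' mid-season light.
#' @param precision Dirichlet-multinomial concentration.
#' @return a [model_params()].
#' @export
default_true_params <- function(precision = 1000) {
  model_params(subpop_params(gamma_max = 0.15, E_star = 120,
                             delta_max = 0.12, v_star = 0.45, eta = 8,
                             mu_LN = log(0.28), sigma_LN = 0.18),
               precision = precision)
}

#' Generate the physical environment series
#'
#' Hourly temperature follows a sinusoid through the configured extrema plus
#' optional AR(1) noise. Daily integrated radiation follows a sinusoid
#' between the configured extrema (maximum at the solstice). Within-day
#' incident light is a half-sine over the daylight period implied by solar
#' geometry at the site, sampled at 10-min midpoints so the step sums
#' integrate to the daily value.
#'
#' @param config a [scenario_config()].
#' @return object of class `environment_series`: list with `hourly`
#'   (yearday, hour, temp_c), `daily` (yearday, rad_MJ, sunrise, sunset,
#'   daylength, dawn_hour), `light` (144 x n_days matrix of W m^-2 at 10-min
#'   midpoints of each calendar day), and the `config`.
#' @export
gen_environment <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  nd <- config$n_days
  yd <- seq_len(nd)
  ta <- config$temperature_annual
  tmid <- (ta[["min"]] + ta[["max"]]) / 2
  tamp <- (ta[["max"]] - ta[["min"]]) / 2
  hours <- rep(0:23, nd)
  ydh <- rep(yd, each = 24)
  tt <- ydh + hours / 24
  temp <- tmid + tamp * cos(2 * pi * (tt - ta[["day_max"]]) / 365)
  if (config$temp_noise_sd > 0) {
    n <- length(temp)
    e <- rnorm(n, sd = config$temp_noise_sd)
    ar <- stats::filter(e, 0.95, method = "recursive")
    temp <- temp + as.numeric(ar)
  }
  ra <- config$radiation_annual
  rmid <- (ra[["min"]] + ra[["max"]]) / 2
  ramp <- (ra[["max"]] - ra[["min"]]) / 2
  rad <- rmid + ramp * cos(2 * pi * (yd - 172) / 365)
  if (config$rad_noise_cv > 0) {
    rad <- rad * rlnorm(nd, meanlog = -config$rad_noise_cv^2 / 2,
                        sdlog = config$rad_noise_cv)
  }
  st <- sun_times(yd, config$latitude, config$longitude)
  light <- matrix(0, 144, nd)
  mid_h <- (seq_len(144) - 0.5) / 6   # 10-min midpoints, decimal hours UTC
  for (d in seq_len(nd)) {
    D <- st$daylength[d]
    if (D <= 0) next
    epeak <- pi * rad[d] * 1e6 / (2 * D * 3600)   # W m^-2
    x <- (mid_h - st$sunrise[d]) / D
    e <- ifelse(x > 0 & x < 1, epeak * sin(pi * x), 0)
    light[, d] <- e
  }
  structure(list(
    hourly = data.frame(yearday = ydh, hour = hours, temp_c = temp),
    daily = data.frame(yearday = yd, rad_MJ = rad,
                       sunrise = st$sunrise, sunset = st$sunset,
                       daylength = st$daylength,
                       dawn_hour = round(st$sunrise) %% 24),
    light = light, config = config),
    class = "environment_series")
}

#' Dawn-to-dawn 10-min incident light for one day
#'
#' Extracts the 144-step light series from the dawn hour of `yearday` to the
#' dawn hour of the next day, the window over which [project_day()] and
#' [fit_day()] operate. Steps past the end of the generated series reuse the
#' last day (they fall in darkness).
#'
#' @param env an `environment_series` from [gen_environment()].
#' @param yearday day whose dawn starts the window.
#' @return numeric vector of length 144 (W m^-2).
#' @export
dawn_window_light <- function(env, yearday) {
  d <- match(yearday, env$daily$yearday)
  if (is.na(d)) stop("yearday not in environment series")
  dawn <- env$daily$dawn_hour[d]
  steps <- dawn * 6 + 0:143            # 10-min steps from midnight of day d
  day_idx <- d + steps %/% 144
  day_idx[day_idx > ncol(env$light)] <- ncol(env$light)
  env$light[cbind(steps %% 144 + 1, day_idx)]
}

#' Generate one synthetic day of hourly size-distribution observations
#'
#' Forward-projects the model, then at each observation hour draws a count
#' vector from a Dirichlet-multinomial with the predicted proportions and
#' the configured precision, and finally removes each counted cell
#' independently with probability `thinning_fraction` (uniform thinning, as
#' by grazing, which changes totals but not expected proportions). All
#' distribution draws happen before any thinning draws, so two runs with the
#' same seed and different thinning share the same underlying count vectors.
#'
#' @param params a [model_params()] (the generating truth).
#' @param light 144-step dawn-to-dawn incident series (W m^-2).
#' @param cells_per_hour cells counted per hourly sample before thinning.
#' @param thinning_fraction per-cell removal probability in `[0, 1)`.
#' @param seed integer seed.
#' @param grid a [size_grid()].
#' @return a [size_distribution_series()]; `meta` carries the true division
#'   rate (`true_rate`), the generating parameters and the projection.
#' @export
gen_observation_day <- function(params, light, cells_per_hour = 1000,
                                thinning_fraction = 0, seed = 1L,
                                grid = size_grid()) {
  stopifnot(thinning_fraction >= 0, thinning_fraction < 1)
  proj <- project_day(params, light, grid)
  q <- proj$q
  set.seed(seed)
  nh <- nrow(q)
  counts <- matrix(0L, nh, grid$m)
  for (k in seq_len(nh)) {
    a <- params$precision * q[k, ]
    g <- rgamma(grid$m, shape = a)
    if (sum(g) <= 0) g <- q[k, ]
    counts[k, ] <- as.integer(rmultinom(1, cells_per_hour, g / sum(g)))
  }
  if (thinning_fraction > 0) {
    counts[] <- rbinom(length(counts), counts, 1 - thinning_fraction)
  }
  rate <- division_rate_from_projection(proj)
  size_distribution_series(counts, grid,
                           meta = list(true_rate = rate$rate,
                                       true_subpop_rates = rate$subpop_rates,
                                       params = params, projection = proj,
                                       seed = seed,
                                       thinning_fraction = thinning_fraction))
}

#' Calibrate the division cap so the projected rate hits a target
#'
#' Adjusts `delta_max` of every subpopulation (scaled jointly) by
#' root-finding so that the realized dawn-to-dawn division rate of
#' [project_day()] equals `target_rate`.
#'
#' @param target_rate desired division rate (d^-1).
#' @param light 144-step incident series.
#' @param base a [model_params()] to start from.
#' @param grid a [size_grid()].
#' @return a [model_params()] with adjusted `delta_max`.
#' @export
calibrate_division_rate <- function(target_rate, light, base = default_true_params(),
                                    grid = size_grid()) {
  rate_at <- function(dm_scale) {
    subs <- lapply(base$subpops, function(s) {
      s$delta_max <- min(dm_scale * s$delta_max, 0.8)
      s
    })
    p <- model_params(subs, base$mix_fraction, base$precision)
    division_rate_from_projection(project_day(p, light, grid))$rate
  }
  f <- function(x) rate_at(x) - target_rate
  sc <- stats::uniroot(f, c(1e-4, 6), tol = 1e-8)$root
  subs <- lapply(base$subpops, function(s) {
    s$delta_max <- min(sc * s$delta_max, 0.8)
    s
  })
  model_params(subs, base$mix_fraction, base$precision)
}

#' Generate an hourly cell-concentration series
#'
#' `N(t) = n0 * exp(integral(division - loss))`, modulated by a sinusoid at
#' the M2 tidal period (12.42 h) of the given fractional amplitude, plus
#' lognormal observation noise.
#'
#' @param division,loss per-day rates (d^-1), vectors of equal length
#'   (recycled per day; piecewise constant within each day).
#' @param n0 starting concentration (cells mL^-1), > 0.
#' @param tidal_amplitude fractional amplitude of the 12.42-h modulation.
#' @param seed integer seed.
#' @param noise_cv lognormal CV of multiplicative observation noise.
#' @return data.frame with `hour` (0-based) and `cells_per_ml`; hour h of
#'   day d is `24 * (d - 1) + h`.
#' @export
gen_concentration_series <- function(division, loss, n0, tidal_amplitude = 0,
                                     seed = 1L, noise_cv = 0) {
  stopifnot(n0 > 0, length(division) == length(loss))
  set.seed(seed)
  nd <- length(division)
  hours <- 0:(24 * nd - 1)
  r_hourly <- rep(division - loss, each = 24) / 24
  cum <- c(0, cumsum(r_hourly))[seq_along(hours)]
  n <- n0 * exp(cum)
  if (tidal_amplitude > 0) {
    n <- n * (1 + tidal_amplitude * sin(2 * pi * hours / 12.42))
  }
  if (noise_cv > 0) {
    n <- n * rlnorm(length(n), meanlog = -noise_cv^2 / 2, sdlog = noise_cv)
  }
  data.frame(hour = hours, cells_per_ml = n)
}

#' Generate irradiance profiles with exponential attenuation
#'
#' At each depth, irradiance is `surface_par * exp(-kd_true * z)` times
#' lognormal noise. With `spectral = TRUE` each depth also carries a
#' green-peaked spectrum on a 1-nm grid (350-800 nm) whose 400-700 nm
#' integral equals the scalar PAR value, plus a constant dark offset that is
#' recorded separately.
#'
#' @param kd_true attenuation coefficient (m^-1), > 0.
#' @param surface_par PAR just below the surface (W cm^-2).
#' @param depths positive depths (m).
#' @param spectral emit per-wavelength irradiance as well as scalar PAR.
#' @param noise_cv lognormal sdlog of multiplicative noise per depth.
#' @param seed integer seed.
#' @param dark_offset spectral dark signal (uW cm^-2 nm^-1) added to emitted
#'   spectra and recorded as the dark spectrum.
#' @return object of class `irradiance_profile`: list with `depths`, `par`
#'   (W cm^-2, noise applied, dark-free), optional `wavelength` and
#'   `spectra` (uW cm^-2 nm^-1 matrix, wavelengths x depths, dark included),
#'   `dark` (dark spectrum), `surface_par`, `kd_true`.
#' @export
gen_irradiance_profiles <- function(kd_true, surface_par = 0.03,
                                    depths = 1:12, spectral = FALSE,
                                    noise_cv = 0, seed = 1L,
                                    dark_offset = 0.05) {
  stopifnot(kd_true > 0, all(depths > 0))
  set.seed(seed)
  par <- surface_par * exp(-kd_true * depths)
  if (noise_cv > 0) par <- par * rlnorm(length(depths), sdlog = noise_cv)
  out <- list(depths = depths, par = par, surface_par = surface_par,
              kd_true = kd_true)
  if (spectral) {
    wl <- 350:800
    shape <- exp(-((wl - 545)^2) / (2 * 70^2))   # green-peaked, coastal
    # scale so the 400-700 nm trapezoid integral (in W cm^-2) matches PAR
    inpar <- wl >= 400 & wl <= 700
    tz <- sum((shape[inpar][-1] + shape[inpar][-sum(inpar)]) / 2)  # 1-nm steps
    spectra <- sapply(par, function(p) shape * (p * 1e6 / tz) + dark_offset)
    out$wavelength <- wl
    out$spectra <- spectra
    out$dark <- rep(dark_offset, length(wl))
  }
  structure(out, class = "irradiance_profile")
}

#' Generate synthetic hydrography (CTD profiles + paired temperature series)
#'
#' Three designed scenarios: `mixed` (density varies < 0.05 kg m^-3 over
#' 0-15 m), `sub3m_stratified` (a density step >= 0.3 kg m^-3 at a depth
#' between 3 and 12 m) and `surface_only` (step confined to the top 3 m).
#' The paired hourly 4-m/12-m temperature series is generated consistently
#' with the density scenario (via the Delta-theta/Delta-sigma relationship
#' used by the stratification index) and 5% of hours are masked as gaps.
#'
#' @param scenario one of `"mixed"`, `"sub3m_stratified"`, `"surface_only"`.
#' @param seed integer seed.
#' @param n_profiles number of CTD profiles to emit.
#' @param n_hours length of the paired temperature series.
#' @param gap_fraction fraction of hours masked missing in each series.
#' @return list of class `hydrography_set`: `profiles` (list of data.frames
#'   with depth_m, temperature_c, sigma_kg_m3), `temps` (data.frame hour,
#'   temp_4m_c, temp_12m_c), `scenario`.
#' @export
gen_hydrography <- function(scenario = c("mixed", "sub3m_stratified",
                                         "surface_only"),
                            seed = 1L, n_profiles = 20L, n_hours = 1000L,
                            gap_fraction = 0.05) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  z <- seq(0.2, 15, by = 0.2)
  base_sigma <- 24.5
  mk_profile <- function() {
    noise <- rnorm(length(z), sd = 0.005)
    sigma <- switch(scenario,
      mixed = base_sigma + noise,
      sub3m_stratified = {
        zstep <- runif(1, 4, 10)
        base_sigma + ifelse(z > zstep, 0.35, 0) + noise
      },
      surface_only = base_sigma + ifelse(z > 1.5, 0.35, 0) + noise)
    # temperature consistent with density (warm = light)
    temp <- 15 - 3.24 * (sigma - base_sigma) + rnorm(length(z), sd = 0.01)
    data.frame(depth_m = z, temperature_c = temp, sigma_kg_m3 = sigma)
  }
  profiles <- replicate(n_profiles, mk_profile(), simplify = FALSE)
  dsig_412 <- switch(scenario, mixed = 0, sub3m_stratified = -0.35,
                     surface_only = 0)
  dtheta <- -0.0354 - 3.24 * dsig_412
  t12 <- 12 + 0.5 * sin(2 * pi * seq_len(n_hours) / (24 * 30)) +
    rnorm(n_hours, sd = 0.05)
  t4 <- t12 + dtheta + rnorm(n_hours, sd = 0.05)
  gaps4 <- runif(n_hours) < gap_fraction
  gaps12 <- runif(n_hours) < gap_fraction
  t4[gaps4] <- NA
  t12[gaps12] <- NA
  structure(list(profiles = profiles,
                 temps = data.frame(hour = seq_len(n_hours) - 1,
                                    temp_4m_c = t4, temp_12m_c = t12),
                 scenario = scenario),
            class = "hydrography_set")
}
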