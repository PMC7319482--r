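test_that("environment generator hits the configured annual extrema", {
  cfg <- scenario_config(seed = 2L, n_days = 240L,
                         temperature_annual = c(min = 0, max = 21,
                                                day_min = 45, day_max = 227))
  env <- gen_environment(cfg)
  t227 <- env$hourly$temp_c[env$hourly$yearday == 227 & env$hourly$hour == 0]
  expect_equal(t227, 21, tolerance = 0.01)
  expect_error(gen_environment(scenario_config(
    temperature_annual = c(min = 10, max = 5, day_min = 45, day_max = 227))),
    "invalid")
})

test_that("noiseless environment is exactly sinusoidal and deterministic", {
  cfg <- scenario_config(seed = 4L, n_days = 30L)
  e1 <- gen_environment(cfg)
  e2 <- gen_environment(cfg)
  expect_identical(e1, e2)
  ta <- cfg$temperature_annual
  tt <- e1$hourly$yearday + e1$hourly$hour / 24
  expected <- mean(ta[c("min", "max")]) +
    diff(ta[c("min", "max")]) / 2 * cos(2 * pi * (tt - ta[["day_max"]]) / 365)
  expect_equal(e1$hourly$temp_c, unname(expected), tolerance = 1e-12)
})

test_that("10-min light samples integrate to the configured daily radiation", {
  env <- gen_environment(scenario_config(seed = 3L, n_days = 200L))
  for (d in c(10, 80, 172)) {
    integral_MJ <- sum(env$light[, d]) * 600 / 1e6
    expect_equal(integral_MJ, env$daily$rad_MJ[d], tolerance = 1e-3)
  }
  # independent quadrature oracle for one day: fine-grid half-sine
  d <- 100
  st <- sun_times(d, env$config$latitude, env$config$longitude)
  epeak <- pi * env$daily$rad_MJ[d] * 1e6 / (2 * st$daylength * 3600)
  hh <- seq(0, 24, length.out = 20001)
  x <- (hh - st$sunrise) / st$daylength
  fine <- ifelse(x > 0 & x < 1, epeak * sin(pi * x), 0)
  oracle_MJ <- sum((fine[-1] + fine[-length(fine)]) / 2 * diff(hh) * 3600) / 1e6
  expect_equal(oracle_MJ, env$daily$rad_MJ[d], tolerance = 1e-4)
})

test_that("uniform thinning halves totals but preserves the count vectors' origin", {
  light <- test_light()
  p <- default_true_params()
  full <- gen_observation_day(p, light, cells_per_hour = 2000, seed = 77L)
  thin <- gen_observation_day(p, light, cells_per_hour = 2000,
                              thinning_fraction = 0.5, seed = 77L)
  # same seed: thinning is applied on top of identical underlying draws
  expect_true(all(thin$counts <= full$counts))
  expect_equal(mean(thin$totals) / mean(full$totals), 0.5, tolerance = 0.05)
  # proportions statistically unchanged
  pf <- colSums(full$counts) / sum(full$counts)
  pt <- colSums(thin$counts) / sum(thin$counts)
  expect_lt(sum(abs(pf - pt)) / 2, 0.03)
})

test_that("observed proportions converge to the deterministic projection", {
  # law of large numbers: huge precision and counts -> tiny TV distance
  light <- test_light()
  p <- default_true_params(precision = 1e9)
  proj <- project_day(p, light, size_grid())
  obs <- gen_observation_day(p, light, cells_per_hour = 1e5, seed = 5L)
  tv <- vapply(c(1, 12, 25), function(k)
    sum(abs(obs$counts[k, ] / obs$totals[k] - proj$q[k, ])) / 2, numeric(1))
  expect_lt(max(tv), 0.02)
})

test_that("replicate-mean hourly proportions match the projection within MC error", {
  light <- test_light()
  p <- default_true_params(precision = 500)
  proj <- project_day(p, light, size_grid())
  n_rep <- 60L
  n_cells <- 400L
  acc <- matrix(0, 3, size_grid()$m)
  hours <- c(1L, 13L, 25L)
  for (r in seq_len(n_rep)) {
    o <- gen_observation_day(p, light, cells_per_hour = n_cells,
                             seed = 9000L + r)
    acc <- acc + o$counts[hours, ] / n_cells
  }
  phat <- acc / n_rep
  # DM variance per class: q(1-q)/n * (n+c)/(1+c); with 75 class-hour
  # comparisons the largest |z| is expected near 3 under the null, so bound
  # the max at 4 SE and require the average |z| to be consistent with an
  # unbiased generator
  zs <- NULL
  for (j in seq_along(hours)) {
    q <- proj$q[hours[j], ]
    se <- sqrt(q * (1 - q) / n_cells * (n_cells + 500) / (1 + 500) / n_rep)
    z <- abs(phat[j, ] - q) / pmax(se, 1e-6)
    expect_true(all(abs(phat[j, ] - q) <= 4 * se + 1e-4))
    zs <- c(zs, z[q > 1e-4])
  }
  expect_lt(mean(zs), 1.5)
})

test_that("concentration generator reproduces exponential growth exactly", {
  cs <- gen_concentration_series(rep(0.3, 4), rep(0.3, 4), n0 = 1e4)
  expect_equal(cs$cells_per_ml, rep(1e4, 96))
  cs2 <- gen_concentration_series(rep(0.5, 5), rep(0.3, 5), n0 = 1e3)
  expect_equal(log(cs2$cells_per_ml[25] / cs2$cells_per_ml[1]), 0.2,
               tolerance = 1e-12)
})

test_that("48-h smoothing removes nearly all tidal variance", {
  cs <- gen_concentration_series(rep(0.2, 20), rep(0.2, 20), n0 = 1e4,
                                 tidal_amplitude = 0.3)
  x <- cs$cells_per_ml
  sm <- stats::filter(x, rep(1 / 49, 49), sides = 2)
  mid <- !is.na(sm)
  var_mod <- var(x[mid] - 1e4)        # variance of the tidal modulation
  var_left <- var(sm[mid] - 1e4)      # what smoothing leaves behind
  expect_lt(var_left / var_mod, 0.05)
})

test_that("irradiance profile generator is exact when noiseless and reproducible", {
  pr <- gen_irradiance_profiles(0.31, surface_par = 0.028, depths = 1:8)
  k <- fit_kd(pr)
  expect_equal(k$kd, 0.31, tolerance = 1e-10)
  expect_equal(k$b, log(0.028), tolerance = 1e-10)
  a <- gen_irradiance_profiles(0.3, noise_cv = 0.1, seed = 1L)
  b <- gen_irradiance_profiles(0.3, noise_cv = 0.1, seed = 1L)
  d <- gen_irradiance_profiles(0.3, noise_cv = 0.1, seed = 2L)
  expect_identical(a, b)
  expect_false(identical(a$par, d$par))
})

test_that("spectral profiles integrate back to the scalar PAR", {
  pr <- gen_irradiance_profiles(0.25, surface_par = 0.03, depths = c(2, 5),
                                spectral = TRUE)
  for (j in 1:2) {
    par_j <- compute_par(pr$wavelength, pr$spectra[, j], dark = pr$dark)
    expect_equal(as.numeric(par_j), pr$par[j], tolerance = 0.005)
  }
})

test_that("hydrography scenarios classify as designed and gaps are ~5%", {
  for (sc in c("mixed", "sub3m_stratified", "surface_only")) {
    h <- gen_hydrography(sc, seed = 3L, n_profiles = 15L)
    cls <- vapply(h$profiles, function(p)
      as.character(classify_stratification(p)), "")
    expected <- switch(sc, mixed = "well_mixed",
                       sub3m_stratified = "stratified_below_3m",
                       surface_only = "surface_only")
    expect_true(all(cls == expected))
  }
  h <- gen_hydrography("mixed", seed = 8L, n_hours = 1000L)
  frac <- mean(is.na(h$temps$temp_4m_c))
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})
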