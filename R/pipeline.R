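#' Run the full synthetic pipeline end to end
#'
#' Generates a synthetic scenario and pushes it through every stage:
#' environment generation, per-day division-rate estimation from size
#' distributions, concentration-based net growth and loss rates, daily
#' cell-property features, the light environment (Kd fits, climatology,
#' attenuated radiation), stratification, climatologies, and the
#' light-response fit. Each stage writes a CSV into `out_dir` and the run
#' ends with a JSON manifest (config snapshot, seeds, file hashes, row
#' counts) such that identical config + seeds reproduce identical manifests.
#'
#' @param config a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @param fit a [fit_config()] for the division-rate fits.
#' @param net_growth_true assumed true net growth rate (d^-1) used to set
#'   the generating loss rates (`loss_true = true division - this`).
#' @param n0 starting cell concentration (cells mL^-1).
#' @param tidal_amplitude,conc_noise_cv concentration-series generator
#'   settings.
#' @return invisibly, a list with all stage outputs and the manifest.
#' @export
run_all <- function(config = scenario_config(),
                    out_dir = tempfile("synseasons_run_"),
                    fit = fit_config(n_subpops = 1L, n_starts = 8L),
                    net_growth_true = 0.05, n0 = 2e4,
                    tidal_amplitude = 0.2, conc_noise_cv = 0.05) {
  stopifnot(inherits(config, "scenario_config"), inherits(fit, "fit_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  grid <- size_grid()

  # stage 1: environment ----------------------------------------------------
  env <- gen_environment(config)
  files["environment_hourly"] <- write_stage_csv(env$hourly, out_dir,
                                                 "environment_hourly")
  files["environment_daily"] <- write_stage_csv(env$daily, out_dir,
                                                "environment_daily")

  # stage 2: per-day division-rate estimation -------------------------------
  division <- data.frame(yearday = env$daily$yearday, mu_true = NA_real_,
                         mu_hat = NA_real_, loglik = NA_real_,
                         n_subpops = NA_integer_, status = NA_character_)
  for (d in seq_len(config$n_days)) {
    light <- dawn_window_light(env, env$daily$yearday[d])
    obs <- gen_observation_day(config$true_params, light,
                               cells_per_hour = config$cells_per_hour,
                               thinning_fraction = config$thinning_fraction,
                               seed = config$seed * 1000L + d, grid = grid)
    fd <- fit_day(obs, light, fit_config(n_subpops = fit$n_subpops,
                                         n_starts = fit$n_starts,
                                         seed = fit$seed + d,
                                         maxit = fit$maxit, tol = fit$tol,
                                         min_hours = fit$min_hours))
    division$mu_true[d] <- obs$meta$true_rate
    division$status[d] <- fd$status
    if (identical(fd$status, "ok")) {
      division$mu_hat[d] <- fd$division_rate
      division$loglik[d] <- fd$loglik
      division$n_subpops[d] <- fd$n_subpops
    }
  }
  files["division"] <- write_stage_csv(division, out_dir, "division")

  # stage 3-4: concentration, net growth, loss ------------------------------
  loss_true <- division$mu_true - net_growth_true
  conc <- gen_concentration_series(division$mu_true, loss_true, n0 = n0,
                                   tidal_amplitude = tidal_amplitude,
                                   seed = config$seed, noise_cv = conc_noise_cv)
  files["concentration"] <- write_stage_csv(conc, out_dir, "concentration")
  ngr <- net_growth_rate(conc, config$latitude, config$longitude)
  rates <- data.frame(yearday = division$yearday,
                      dawn_hour = ngr$dawn_hour,
                      mu = division$mu_hat,
                      mu_net = ngr$mu_net,
                      loss = loss_rate(division$mu_hat, ngr$mu_net),
                      flag = ngr$flag)
  files["rates"] <- write_stage_csv(rates, out_dir, "rates")

  # stage 5: cell-property features -----------------------------------------
  set.seed(config$seed + 7L)
  feats <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    dawn <- env$daily$dawn_hour[d]
    diel <- 0.12 * sin(2 * pi * ((0:23) - dawn - 6) / 24)  # min near dawn
    vol_modes <- pe_modes <- rep(NA_real_, 24)
    for (h in 1:24) {
      v <- rlnorm(300, meanlog = log(0.3) + diel[h], sdlog = 0.15)
      pe <- v * rlnorm(300, meanlog = log(2), sdlog = 0.1)
      vol_modes[h] <- population_mode(v)
      pe_modes[h] <- population_mode(pe)
    }
    feats[[d]] <- cbind(yearday = env$daily$yearday[d],
                        daily_features(vol_modes, pe_modes, dawn))
  }
  features <- do.call(rbind, feats)
  files["features"] <- write_stage_csv(features, out_dir, "features")

  # stage 6: light environment ----------------------------------------------
  prof_days <- unique(round(seq(10, 350, length.out = 8)))
  kd_pts <- data.frame(yearday = prof_days, kd = NA_real_)
  for (i in seq_along(prof_days)) {
    pr <- gen_irradiance_profiles(config$kd_true, noise_cv = 0.05,
                                  seed = config$seed * 100L + i)
    kd_pts$kd[i] <- fit_kd(pr)$kd
  }
  kdc <- kd_climatology(kd_pts)
  light_tab <- data.frame(yearday = env$daily$yearday,
                          rad_MJ = env$daily$rad_MJ)
  light_tab$kd <- kdc$kd_mean[match(light_tab$yearday, kdc$yearday)]
  light_tab$rad_at_depth_MJ <- mean_light_at_depth(light_tab$rad_MJ,
                                                   light_tab$kd)
  files["light"] <- write_stage_csv(light_tab, out_dir, "light")

  # stage 7: stratification -------------------------------------------------
  hyd <- gen_hydrography("mixed", seed = config$seed,
                         n_hours = max(config$n_days * 24L, 48L))
  ctd_class <- vapply(hyd$profiles, function(p)
    as.character(classify_stratification(p)), "")
  strat <- vector("list", config$n_days)
  for (d in seq_len(config$n_days)) {
    idx <- (d - 1) * 24 + 1:24
    dth <- hyd$temps$temp_4m_c[idx] - hyd$temps$temp_12m_c[idx]
    mask <- is_daylight(env$daily$yearday[d], 0:23,
                        config$latitude, config$longitude)
    ds <- daily_stratification(dth, mask)
    strat[[d]] <- data.frame(yearday = env$daily$yearday[d],
                             frac_daylight_stratified = ds$frac_stratified,
                             stratified_flag = ds$daily_flag,
                             coverage = ds$coverage)
  }
  strat <- do.call(rbind, strat)
  files["stratification"] <- write_stage_csv(strat, out_dir, "stratification")

  # stage 8: climatologies ---------------------------------------------------
  dates <- as.Date("2000-12-31") + env$daily$yearday
  temp_daily <- tapply(env$hourly$temp_c, env$hourly$yearday, mean)
  clim_temp <- daily_climatology(dates, as.numeric(temp_daily))
  files["climatology_temp"] <- write_stage_csv(clim_temp, out_dir,
                                               "climatology_temp")
  clim_mu <- weekly_median_climatology(dates, division$mu_hat)
  files["climatology_division"] <- write_stage_csv(clim_mu, out_dir,
                                                   "climatology_division")

  # stage 9: light response -------------------------------------------------
  lr <- fit_light_response(division$mu_hat, light_tab$rad_MJ)
  resp <- data.frame(mu_max = lr$mu_max, alpha = lr$alpha, rss = lr$rss,
                     n = lr$n, flag = lr$flag)
  files["response"] <- write_stage_csv(resp, out_dir, "response")

  # manifest -----------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("synseasons")),
    config = config[setdiff(names(config), "true_params")],
    true_params = unclass(config$true_params$subpops[[1]]),
    mix_fraction = config$true_params$mix_fraction,
    precision = config$true_params$precision,
    fit = unclass(fit),
    stage_rows = lapply(list(environment_hourly = env$hourly,
                             division = division, rates = rates,
                             features = features, light = light_tab,
                             stratification = strat), nrow),
    ctd_well_mixed_fraction = mean(ctd_class == "well_mixed"),
    file_md5 = as.list(tools::md5sum(unname(files))))
  names(manifest$file_md5) <- names(files)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(env = env, division = division, rates = rates,
                 features = features, light = light_tab, strat = strat,
                 kd_climatology = kdc, response = lr, manifest = manifest,
                 out_dir = out_dir, files = files,
                 manifest_path = manifest_path))
}

#' Load a run configuration from a flat YAML file
#'
#' Recognized keys mirror the arguments of [scenario_config()]; unknown keys
#' abort before any stage runs.
#'
#' @param path YAML file path.
#' @return a [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(scenario_config)), "true_params")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in c("temperature_annual", "radiation_annual")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(scenario_config, raw)
}
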