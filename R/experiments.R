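#' Division-rate parameter-recovery experiment
#'
#' Generates synthetic days whose true division rates are drawn uniformly
#' from `rate_range` (imposed by calibrating the division cap against the
#' day's light curve), simulates hourly size-distribution observations, fits
#' each day by maximum likelihood, and reports true and estimated rates.
#' Days are spread across the annual light cycle so short and long days are
#' both represented.
#'
#' @param n_days number of synthetic days.
#' @param seed master seed; day-level seeds derive from it.
#' @param cells_per_hour counted cells per hourly sample.
#' @param rate_range range of true division rates (d^-1).
#' @param n_starts optimizer starts per day.
#' @param thinning_fraction per-cell removal probability applied to the
#'   observations.
#' @param base a [model_params()] the calibration starts from.
#' @return data.frame with `day`, `yearday`, `mu_true`, `mu_hat`,
#'   `abs_error`, `status`.
#' @export
recovery_experiment <- function(n_days = 50L, seed = 1L,
                                cells_per_hour = 1000L,
                                rate_range = c(0.05, 1.0),
                                n_starts = 6L, thinning_fraction = 0,
                                base = default_true_params()) {
  env <- gen_environment(scenario_config(seed = seed, n_days = 365L))
  grid <- size_grid()
  set.seed(seed)
  yeardays <- sample(30:330, n_days, replace = TRUE)
  targets <- runif(n_days, rate_range[1], rate_range[2])
  out <- data.frame(day = seq_len(n_days), yearday = yeardays,
                    mu_true = NA_real_, mu_hat = NA_real_,
                    status = NA_character_)
  for (i in seq_len(n_days)) {
    light <- dawn_window_light(env, yeardays[i])
    truth <- calibrate_division_rate(targets[i], light, base, grid)
    obs <- gen_observation_day(truth, light,
                               cells_per_hour = cells_per_hour,
                               thinning_fraction = thinning_fraction,
                               seed = seed * 1000L + i, grid = grid)
    fit <- fit_day(obs, light,
                   fit_config(n_subpops = 1L, n_starts = n_starts,
                              seed = seed + i))
    out$mu_true[i] <- obs$meta$true_rate
    out$status[i] <- fit$status
    if (identical(fit$status, "ok")) out$mu_hat[i] <- fit$division_rate
  }
  out$abs_error <- abs(out$mu_hat - out$mu_true)
  out
}

#' Thinning-invariance experiment
#'
#' For each synthetic day, fits the same underlying observations twice: once
#' intact and once after uniform per-cell thinning (sharing the seed so the
#' underlying count draws coincide). Because the likelihood sees only
#' proportions, the two estimates should agree closely — the operational
#' statement that the method does not rely on changes in cell concentration.
#'
#' @inheritParams recovery_experiment
#' @param thinning_fraction per-cell removal probability for the thinned
#'   arm.
#' @return data.frame with `day`, `mu_true`, `mu_hat_full`,
#'   `mu_hat_thinned`, `shift` (absolute difference).
#' @export
thinning_experiment <- function(n_days = 20L, seed = 1L,
                                cells_per_hour = 1000L,
                                thinning_fraction = 0.5,
                                rate_range = c(0.05, 1.0),
                                n_starts = 6L,
                                base = default_true_params()) {
  env <- gen_environment(scenario_config(seed = seed, n_days = 365L))
  grid <- size_grid()
  set.seed(seed + 1L)
  yeardays <- sample(30:330, n_days, replace = TRUE)
  targets <- runif(n_days, rate_range[1], rate_range[2])
  out <- data.frame(day = seq_len(n_days), mu_true = NA_real_,
                    mu_hat_full = NA_real_, mu_hat_thinned = NA_real_)
  for (i in seq_len(n_days)) {
    light <- dawn_window_light(env, yeardays[i])
    truth <- calibrate_division_rate(targets[i], light, base, grid)
    cfg <- fit_config(n_subpops = 1L, n_starts = n_starts, seed = seed + i)
    obs_full <- gen_observation_day(truth, light, cells_per_hour,
                                    thinning_fraction = 0,
                                    seed = seed * 2000L + i, grid = grid)
    obs_thin <- gen_observation_day(truth, light, cells_per_hour,
                                    thinning_fraction = thinning_fraction,
                                    seed = seed * 2000L + i, grid = grid)
    f_full <- fit_day(obs_full, light, cfg)
    f_thin <- fit_day(obs_thin, light, cfg)
    out$mu_true[i] <- obs_full$meta$true_rate
    if (identical(f_full$status, "ok")) out$mu_hat_full[i] <- f_full$division_rate
    if (identical(f_thin$status, "ok")) out$mu_hat_thinned[i] <- f_thin$division_rate
  }
  out$shift <- abs(out$mu_hat_full - out$mu_hat_thinned)
  out
}
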