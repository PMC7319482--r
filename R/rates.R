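#' Missing-aware centered running mean
#'
#' @param x numeric series.
#' @param halfwidth points either side of the center included in the window.
#' @param min_coverage minimum fraction of non-missing points a window needs;
#'   windows below it return NA.
#' @return smoothed series, same length.
#' @keywords internal
running_mean <- function(x, halfwidth = 24L, min_coverage = 0.5) {
  n <- length(x)
  out <- rep(NA_real_, n)
  full <- 2 * halfwidth + 1
  for (i in seq_len(n)) {
    w <- x[max(1, i - halfwidth):min(n, i + halfwidth)]
    # coverage is judged against the full window: hours beyond the series'
    # edges count as missing
    if (sum(!is.na(w)) / full >= min_coverage) out[i] <- mean(w, na.rm = TRUE)
  }
  out
}

#' Daily net growth rate from hourly cell concentrations
#'
#' Concentrations are smoothed with a centered 48-h running mean (to damp
#' tidal and other high-frequency variability), averaged over the 3-h window
#' surrounding each day's dawn hour (dawn - 1, dawn, dawn + 1), and the net
#' growth rate of day t is the log ratio of the dawn-window averages 24 h
#' apart:
#' `mu_net(t) = ln( Nbar(tau(t) + 24h) / Nbar(tau(t)) )`.
#' The dawn hour comes from solar geometry at the site, rounded to the
#' nearest hour, matching the window used for division-rate estimation.
#'
#' @param conc data.frame with `hour` (0-based, hour h of day d is
#'   `24 (d - 1) + h`) and `cells_per_ml`.
#' @param lat,lon site coordinates (degrees).
#' @param start_yearday year day corresponding to day 1 of the series.
#' @return data.frame with `day`, `yearday`, `dawn_hour`, `mu_net`, `flag`
#'   (`"ok"` or `"missing_dawn_window"`).
#' @export
net_growth_rate <- function(conc, lat = 41.325, lon = -70.567,
                            start_yearday = 1L) {
  stopifnot(all(c("hour", "cells_per_ml") %in% names(conc)))
  hours <- conc$hour
  n_hours <- max(hours) + 1
  x <- rep(NA_real_, n_hours)
  x[hours + 1] <- conc$cells_per_ml
  sm <- running_mean(x, halfwidth = 24L)
  n_days <- n_hours %/% 24
  dawn_window_mean <- function(abs_hour) {
    idx <- abs_hour + c(-1, 0, 1) + 1
    if (any(idx < 1 | idx > n_hours)) return(NA_real_)
    v <- sm[idx]
    if (any(is.na(v))) return(NA_real_) else mean(v)
  }
  out <- data.frame(day = seq_len(n_days))
  out$yearday <- start_yearday + out$day - 1
  out$dawn_hour <- dawn_hour(out$yearday, lat, lon)
  out$mu_net <- NA_real_
  for (d in seq_len(n_days)) {
    tau <- (d - 1) * 24 + out$dawn_hour[d]
    n0 <- dawn_window_mean(tau)
    n1 <- dawn_window_mean(tau + 24)
    if (!is.na(n0) && !is.na(n1) && n0 > 0 && n1 > 0) {
      out$mu_net[d] <- log(n1 / n0)
    }
  }
  out$flag <- ifelse(is.na(out$mu_net), "missing_dawn_window", "ok")
  out
}

#' Loss rate by back-calculation
#'
#' `loss = division - net growth`, the aggregate of predation (grazing and
#' viral lysis) and net advective exchange; missing inputs give missing
#' output.
#'
#' @param division,net_growth per-day rates (d^-1), equal length.
#' @return per-day loss rate (d^-1).
#' @export
loss_rate <- function(division, net_growth) {
  stopifnot(length(division) == length(net_growth))
  division - net_growth
}

#' Rough daily primary-production estimate
#'
#' New cells per mL per day are `N (e^mu - 1)` (default) or `N mu` (linear
#' form); production is new cells times cell volume times a carbon:volume
#' ratio, converted to mg C m^-3 d^-1. The carbon:volume ratio has no
#' asserted default and must be supplied.
#'
#' @param concentration cells mL^-1.
#' @param division division rate (d^-1).
#' @param cell_volume um^3 per cell.
#' @param c_per_volume carbon:volume ratio (fg C um^-3).
#' @param form `"exponential"` (`N (e^mu - 1)`) or `"linear"` (`N mu`).
#' @return production in mg C m^-3 d^-1.
#' @export
production_estimate <- function(concentration, division, cell_volume,
                                c_per_volume,
                                form = c("exponential", "linear")) {
  form <- match.arg(form)
  stopifnot(all(concentration > 0), all(cell_volume > 0), c_per_volume > 0)
  new_cells <- switch(form,
                      exponential = concentration * (exp(division) - 1),
                      linear = concentration * division)
  # fg C mL^-1 d^-1 -> mg C m^-3 d^-1: 1e-12 mg/fg * 1e6 mL/m^3
  new_cells * cell_volume * c_per_volume * 1e-6
}
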