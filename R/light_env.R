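#' PAR from a spectral irradiance measurement
#'
#' Subtracts the closest-in-time dark spectrum, then integrates irradiance
#' over 400-700 nm by the trapezoid rule and converts from uW cm^-2 to
#' W cm^-2. Negative post-subtraction values are treated as missing (their
#' wavelengths are dropped from the integral), not zeroed.
#'
#' @param wavelength wavelength grid (nm), must cover 400-700 nm.
#' @param spectrum spectral irradiance (uW cm^-2 nm^-1) on that grid.
#' @param dark dark spectrum on the same grid, or a list of dark records
#'   `list(time =, spectrum =)` from which the closest in time to
#'   `time` is chosen.
#' @param time measurement time (numeric, same units as dark record times);
#'   only needed when `dark` is a list of records.
#' @return PAR in W cm^-2, with attribute `grid_gap_flag` set when the
#'   wavelength grid has a gap > 10 nm inside 400-700 nm.
#' @export
compute_par <- function(wavelength, spectrum, dark = NULL, time = NULL) {
  stopifnot(length(wavelength) == length(spectrum))
  if (min(wavelength) > 400 || max(wavelength) < 700) {
    stop("wavelength grid must cover 400-700 nm")
  }
  if (!is.null(dark)) {
    if (is.list(dark) && !is.null(dark$records)) {
      stopifnot(!is.null(time))
      i <- which.min(abs(dark$times - time))
      dark <- dark$records[[i]]
    }
    stopifnot(length(dark) == length(spectrum))
    spectrum <- spectrum - dark
  }
  inpar <- wavelength >= 400 & wavelength <= 700
  wl <- wavelength[inpar]
  sp <- spectrum[inpar]
  gap_flag <- max(diff(wl)) > 10
  ok <- !is.na(sp) & sp >= 0
  wl <- wl[ok]; sp <- sp[ok]
  if (length(wl) < 2) stop("fewer than 2 usable wavelengths in 400-700 nm")
  par_uw <- sum(diff(wl) * (sp[-1] + sp[-length(sp)]) / 2)
  structure(par_uw * 1e-6, grid_gap_flag = gap_flag)
}

#' Estimate the PAR attenuation coefficient from an irradiance profile
#'
#' Assumes exponential attenuation `E(z) = E(0-) exp(-Kd z)` and fits
#' ordinary least squares of `ln E(z)` on depth; `Kd` is minus the slope and
#' the intercept `b` estimates `ln E(0-)`. Non-positive irradiance values
#' are excluded; at least 3 usable depths are required.
#'
#' @param profile an `irradiance_profile` (list with `depths` and `par`), or
#'   supply `depths` and `par` directly.
#' @param depths,par alternative direct inputs (m; W cm^-2).
#' @return list with `kd` (m^-1), `b`, `r_squared`, `n`, `flag`.
#' @export
fit_kd <- function(profile = NULL, depths = profile$depths, par = profile$par) {
  stopifnot(length(depths) == length(par))
  ok <- is.finite(par) & par > 0 & is.finite(depths)
  if (sum(ok) < 3) {
    return(list(kd = NA_real_, b = NA_real_, r_squared = NA_real_,
                n = sum(ok), flag = "too_few_depths"))
  }
  z <- depths[ok]
  y <- log(par[ok])
  fit <- stats::lm.fit(cbind(1, z), y)
  b <- fit$coefficients[[1]]
  kd <- -fit$coefficients[[2]]
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  list(kd = kd, b = b,
       r_squared = if (sst > 0) 1 - ssr / sst else NA_real_,
       n = sum(ok), flag = "ok")
}

#' Attenuation-coefficient climatology by year day
#'
#' Deployment-mean Kd values are first filtered by location (configured
#' exclusion list), then points whose year days fall within `merge_window`
#' days of one another are merged by averaging (year day and value), and the
#' merged points are linearly interpolated to every year day with periodic
#' wrap across the year boundary. Min/max envelopes are interpolated the
#' same way from the per-merge extremes.
#'
#' @param deployment_means data.frame with columns `yearday`, `kd` and
#'   optionally `location`.
#' @param merge_window days within which points are averaged together.
#' @param exclude_locations character vector of locations to drop.
#' @return object of class `kd_climatology`: data.frame `yearday` (1-365),
#'   `kd_mean`, `kd_min`, `kd_max`, plus attributes `points` (the merged
#'   source points) and `flag`.
#' @export
kd_climatology <- function(deployment_means, merge_window = 14,
                           exclude_locations = character()) {
  d <- deployment_means
  if (!is.null(d$location) && length(exclude_locations)) {
    d <- d[!(d$location %in% exclude_locations), , drop = FALSE]
  }
  stopifnot(nrow(d) >= 1, all(d$kd > 0))
  d <- d[order(d$yearday), , drop = FALSE]
  # merge runs of points within the window of each other
  grp <- cumsum(c(1, diff(d$yearday) > merge_window))
  pts <- do.call(rbind, lapply(split(d, grp), function(g) {
    data.frame(yearday = mean(g$yearday), kd = mean(g$kd),
               kd_min = min(g$kd), kd_max = max(g$kd))
  }))
  flag <- "ok"
  if (nrow(pts) == 1) {
    flag <- "single_point"
    out <- data.frame(yearday = 1:365, kd_mean = pts$kd,
                      kd_min = pts$kd_min, kd_max = pts$kd_max)
  } else {
    wrap_interp <- function(x, y) {
      # periodic interpolation: extend the first/last points across the wrap
      xx <- c(x[length(x)] - 365, x, x[1] + 365)
      yy <- c(y[length(y)], y, y[1])
      stats::approx(xx, yy, xout = 1:365)$y
    }
    out <- data.frame(yearday = 1:365,
                      kd_mean = wrap_interp(pts$yearday, pts$kd),
                      kd_min = wrap_interp(pts$yearday, pts$kd_min),
                      kd_max = wrap_interp(pts$yearday, pts$kd_max))
  }
  structure(out, points = pts, flag = flag, class = c("kd_climatology",
                                                      "data.frame"))
}

#' Depth-averaged daily light exposure in a mixed water column
#'
#' Cells assumed to visit all depths of an `H`-m column within a day
#' experience on average
#' `E0 * (1 - exp(-Kd * H)) / (Kd * H)`,
#' the closed form of the depth integral of exponentially attenuated
#' irradiance.
#'
#' @param E0 incident radiation (MJ m^-2 d^-1).
#' @param Kd attenuation coefficient (m^-1), > 0 (the transparent limit
#'   `Kd -> 0` returns `E0`).
#' @param H water-column height (m), default 15.
#' @return average light exposure (MJ m^-2 d^-1), vectorized over inputs.
#' @export
mean_light_at_depth <- function(E0, Kd, H = 15) {
  stopifnot(all(Kd >= 0), H > 0)
  x <- Kd * H
  # -expm1(-x)/x avoids cancellation as Kd -> 0 and tends to 1 there
  ifelse(x == 0, E0, E0 * (-expm1(-x)) / x)
}
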