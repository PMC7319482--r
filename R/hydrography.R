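#' Preprocess a raw CTD cast
#'
#' Retains the downcast — identified automatically as the longest contiguous
#' segment of strictly increasing depth — and averages samples into 0.2-m
#' depth bins.
#'
#' @param raw data.frame with time-ordered `depth_m`, `temperature_c`,
#'   `sigma_kg_m3`.
#' @param bin_width depth bin width (m).
#' @return data.frame of class `ctd_profile` with bin-center `depth_m` and
#'   bin-mean `temperature_c`, `sigma_kg_m3`.
#' @export
preprocess_cast <- function(raw, bin_width = 0.2) {
  stopifnot(nrow(raw) >= 10)
  inc <- diff(raw$depth_m) > 0
  r <- rle(inc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) stop("cast rejected: no descending segment")
  best <- runs[which.max(r$lengths[runs])]
  seg <- raw[starts[best]:(ends[best] + 1), , drop = FALSE]
  if (nrow(seg) < 10) stop("cast rejected: no descending segment of >= 10 samples")
  bin <- round(seg$depth_m / bin_width) * bin_width
  agg <- aggregate(seg[c("temperature_c", "sigma_kg_m3")],
                   by = list(depth_m = bin), FUN = mean)
  agg <- agg[order(agg$depth_m), ]
  rownames(agg) <- NULL
  class(agg) <- c("ctd_profile", "data.frame")
  agg
}

#' Classify water-column stratification from a density profile
#'
#' A profile is stratified when potential density deviates by more than
#' `threshold` from a reference value: the near-surface value, or the 4-m
#' value when stratification is confined to the top 3 m. Classification:
#' exceedance below 3 m from either reference gives `stratified_below_3m`;
#' exceedance only within the top 3 m gives `surface_only`; otherwise
#' `well_mixed`.
#'
#' @param profile data.frame with `depth_m` and `sigma_kg_m3` (a
#'   `ctd_profile` or synthetic equivalent) spanning at least 0.5-12 m.
#' @param threshold density threshold (kg m^-3), default 0.2.
#' @return character scalar, one of `"well_mixed"`, `"stratified_below_3m"`,
#'   `"surface_only"`; attribute `flag` notes a substituted 4-m bin.
#' @export
classify_stratification <- function(profile, threshold = 0.2) {
  z <- profile$depth_m
  s <- profile$sigma_kg_m3
  stopifnot(min(z) <= 0.5, max(z) >= 12)
  ref_surf <- s[which.min(z)]
  flag <- "ok"
  i4 <- which.min(abs(z - 4))
  if (abs(z[i4] - 4) > 0.4) {
    stop("no density bin within 0.4 m of 4 m depth")
  } else if (abs(z[i4] - 4) > 1e-9) {
    flag <- "nearest_4m_bin_used"
  }
  ref_4m <- s[i4]
  exceed_surf <- abs(s - ref_surf) > threshold
  cls <- if (!any(exceed_surf)) {
    "well_mixed"
  } else if (min(z[exceed_surf]) > 3) {
    # the stratification feature starts below 3 m
    "stratified_below_3m"
  } else if (any(abs(s[z > 4] - ref_4m) > threshold)) {
    # strong surface stratification: re-evaluate against the 4-m reference
    "stratified_below_3m"
  } else {
    "surface_only"
  }
  structure(cls, flag = flag)
}

#' Regress the paired-depth temperature difference on the density difference
#'
#' Ordinary least squares of `Delta-theta(4,12)` on `Delta-sigma(4,12)`,
#' used to calibrate the temperature threshold of the stratification index
#' against the density threshold.
#'
#' @param dsigma,dtheta paired differences: `sigma(4m) - sigma(12m)`
#'   (kg m^-3) and `theta(4m) - theta(12m)` (degC).
#' @return list with `slope`, `intercept`, `r_squared`, `n`, `flag`.
#' @export
regress_theta_sigma <- function(dsigma, dtheta) {
  ok <- is.finite(dsigma) & is.finite(dtheta)
  dsigma <- dsigma[ok]; dtheta <- dtheta[ok]
  stopifnot(length(dsigma) >= 3)
  if (stats::var(dsigma) == 0) {
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = NA_real_, n = length(dsigma),
                flag = "zero_variance"))
  }
  fit <- stats::lm.fit(cbind(1, dsigma), dtheta)
  ssr <- sum(fit$residuals^2)
  sst <- sum((dtheta - mean(dtheta))^2)
  list(slope = fit$coefficients[[2]], intercept = fit$coefficients[[1]],
       r_squared = if (sst > 0) 1 - ssr / sst else 0,
       n = length(dsigma), flag = "ok")
}

#' Daily stratification classification from hourly temperature differences
#'
#' An hour is stratified when `Delta-theta(4,12)` exceeds `theta_threshold`
#' (default 0.68 degC, the temperature difference associated with a 0.2
#' kg m^-3 density difference). A day is stratified when strictly more than
#' two-thirds of its daylight hours with data are stratified. Missing hours
#' are excluded from numerator and denominator; days with < 50% daylight
#' coverage are flagged, and days with no daylight data are undefined (NA),
#' not FALSE.
#'
#' @param dtheta hourly `theta(4m) - theta(12m)` (degC) for one day,
#'   aligned with `daylight`.
#' @param daylight logical daylight mask, same length.
#' @param theta_threshold temperature threshold (degC).
#' @return list with `hourly_flag` (logical, NA where missing),
#'   `frac_stratified` (share of daylight hours with data that are
#'   stratified), `daily_flag` (logical or NA), `coverage`, `low_coverage`.
#' @export
daily_stratification <- function(dtheta, daylight, theta_threshold = 0.68) {
  stopifnot(length(dtheta) == length(daylight), any(daylight))
  hourly <- dtheta > theta_threshold
  day_idx <- which(daylight)
  have <- day_idx[!is.na(dtheta[day_idx])]
  coverage <- length(have) / length(day_idx)
  if (!length(have)) {
    return(list(hourly_flag = hourly, frac_stratified = NA_real_,
                daily_flag = NA, coverage = 0, low_coverage = TRUE))
  }
  frac <- mean(hourly[have])
  list(hourly_flag = hourly, frac_stratified = frac,
       daily_flag = frac > 2 / 3,        # strictly greater than two-thirds
       coverage = coverage, low_coverage = coverage < 0.5)
}

#' Gap-fill a primary temperature series from secondary and spot records
#'
#' Gaps in the primary (4-m) hourly series are filled with
#' regression-adjusted values from the secondary (12-m) series; the linear
#' regression is fitted separately for each calendar month (months with
#' fewer than `min_pairs` paired hours borrow the nearest month's fit and
#' are flagged). Any remaining gaps are filled from tertiary spot values at
#' matching hours. Non-missing primary values are never altered, and every
#' filled value carries a source flag.
#'
#' @param primary,secondary numeric hourly series of equal length (NA =
#'   gap).
#' @param month integer month (1-12) per hour.
#' @param tertiary optional numeric series of spot values aligned with the
#'   hours (NA where absent).
#' @param min_pairs minimum paired hours for a month-specific regression.
#' @return data.frame with `filled`, `source` (one of `"primary"`,
#'   `"secondary"`, `"tertiary"`, `NA`), and `month_flag` (TRUE where a
#'   borrowed month fit was used).
#' @export
fill_temperature_gaps <- function(primary, secondary, month,
                                  tertiary = NULL, min_pairs = 50L) {
  n <- length(primary)
  stopifnot(length(secondary) == n, length(month) == n)
  months <- sort(unique(month))
  coefs <- list()
  npairs <- integer(12)
  for (mo in months) {
    i <- month == mo & !is.na(primary) & !is.na(secondary)
    npairs[mo] <- sum(i)
    if (sum(i) >= min_pairs) {
      fit <- stats::lm.fit(cbind(1, secondary[i]), primary[i])
      coefs[[mo]] <- fit$coefficients
    }
  }
  fitted_months <- which(!vapply(seq_len(12), function(m)
    is.null(coefs[m][[1]]), TRUE))
  if (!length(fitted_months)) stop("no month has enough overlap for regression")
  filled <- primary
  source <- ifelse(is.na(primary), NA_character_, "primary")
  month_flag <- logical(n)
  gap <- is.na(primary) & !is.na(secondary)
  for (mo in months) {
    i <- gap & month == mo
    if (!any(i)) next
    use_mo <- mo
    if (is.null(coefs[mo][[1]])) {
      use_mo <- fitted_months[which.min(pmin(abs(fitted_months - mo),
                                             12 - abs(fitted_months - mo)))]
      month_flag[i] <- TRUE
    }
    cf <- coefs[[use_mo]]
    filled[i] <- cf[1] + cf[2] * secondary[i]
    source[i] <- "secondary"
  }
  if (!is.null(tertiary)) {
    i <- is.na(filled) & !is.na(tertiary)
    filled[i] <- tertiary[i]
    source[i] <- "tertiary"
  }
  data.frame(filled = filled, source = source, month_flag = month_flag)
}
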