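#' Year day with leap-day removal
#'
#' Feb 29 values are dropped and later days of leap years shifted down one,
#' so day numbers align across years (1-365).
#'
#' @param dates Date vector.
#' @return data.frame with `date`, `yearday` (NA on Feb 29).
#' @keywords internal
yearday_no_leap <- function(dates) {
  md <- format(dates, "%m-%d")
  yd <- as.integer(format(dates, "%j"))
  y <- as.integer(format(dates, "%Y"))
  leap <- (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
  yd[leap & yd > 60] <- yd[leap & yd > 60] - 1L
  yd[md == "02-29"] <- NA_integer_
  data.frame(date = dates, yearday = yd)
}

#' Daily climatology (mean and SD per year day)
#'
#' Averages values for each year day across available years; Feb 29 is
#' dropped before year-day assignment.
#'
#' @param dates Date vector.
#' @param values numeric vector, same length.
#' @return data.frame of class `climatology_table` with `yearday`, `mean`,
#'   `sd`, `n`.
#' @export
daily_climatology <- function(dates, values) {
  stopifnot(length(dates) == length(values))
  yd <- yearday_no_leap(dates)$yearday
  keep <- !is.na(yd) & !is.na(values)
  yd <- yd[keep]; v <- values[keep]
  out <- do.call(rbind, lapply(split(v, yd), function(x) {
    data.frame(mean = mean(x), sd = stats::sd(x), n = length(x))
  }))
  out <- cbind(yearday = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  class(out) <- c("climatology_table", "data.frame")
  out
}

#' Weekly median climatology from pooled raw daily values
#'
#' Weeks are `ceil(yearday / 7)` with days beyond week 52 folded into week
#' 52. The weekly value is the median of all raw daily values (all years)
#' belonging to the week — daily climatology values are never used as an
#' intermediate.
#'
#' @inheritParams daily_climatology
#' @return data.frame of class `climatology_table` with `week`, `median`,
#'   `n`.
#' @export
weekly_median_climatology <- function(dates, values) {
  stopifnot(length(dates) == length(values))
  yd <- yearday_no_leap(dates)$yearday
  keep <- !is.na(yd) & !is.na(values)
  wk <- pmin(ceiling(yd[keep] / 7), 52)
  v <- values[keep]
  out <- do.call(rbind, lapply(split(v, wk), function(x) {
    data.frame(median = stats::median(x), n = length(x))
  }))
  out <- cbind(week = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  class(out) <- c("climatology_table", "data.frame")
  out
}

#' Anomalies relative to the daily climatology
#'
#' Subtracts the year-day mean from each daily value; year days not covered
#' by the climatology give missing anomalies.
#'
#' @inheritParams daily_climatology
#' @param clim a `climatology_table` from [daily_climatology()].
#' @return data.frame with `date`, `yearday`, `anomaly`.
#' @export
anomalies <- function(dates, values, clim) {
  stopifnot(length(dates) == length(values))
  yd <- yearday_no_leap(dates)$yearday
  m <- clim$mean[match(yd, clim$yearday)]
  data.frame(date = dates, yearday = yd, anomaly = values - m)
}

#' Monthly median climatology with quartile spread
#'
#' For sparse series (e.g. nutrients): per calendar month, pooled across
#' years, the median, 25th/75th quantiles (linear-interpolation convention),
#' min, max and n.
#'
#' @inheritParams daily_climatology
#' @return data.frame of class `climatology_table` with `month`, `median`,
#'   `q25`, `q75`, `min`, `max`, `n`.
#' @export
monthly_median <- function(dates, values) {
  stopifnot(length(dates) == length(values))
  mo <- as.integer(format(dates, "%m"))
  keep <- !is.na(values)
  mo <- mo[keep]; v <- values[keep]
  out <- do.call(rbind, lapply(split(v, mo), function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(median = q[2], q25 = q[1], q75 = q[3],
               min = min(x), max = max(x), n = length(x))
  }))
  out <- cbind(month = as.integer(rownames(out)), out)
  rownames(out) <- NULL
  class(out) <- c("climatology_table", "data.frame")
  out
}
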