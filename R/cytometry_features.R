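#' Bead-normalize per-cell channel values
#'
#' Divides each value by the modal value of the closest-in-time reference
#' bead record on the same channel. Samples with no bead record within
#' `max_gap_h` hours are flagged and left unnormalized (NA).
#'
#' @param values per-cell channel values.
#' @param times measurement time per value (hours, numeric).
#' @param bead_series data.frame with `time` (hours) and `modal_value`.
#' @param max_gap_h maximum tolerated time gap to a bead record.
#' @return data.frame with `normalized` and `flag` (`"ok"` /
#'   `"no_bead_within_window"`).
#' @export
bead_normalize <- function(values, times, bead_series, max_gap_h = 48) {
  stopifnot(length(values) == length(times), nrow(bead_series) >= 1,
            all(bead_series$modal_value > 0))
  idx <- vapply(times, function(t) which.min(abs(bead_series$time - t)), 1L)
  gap <- abs(bead_series$time[idx] - times)
  ok <- gap <= max_gap_h
  normalized <- ifelse(ok, values / bead_series$modal_value[idx], NA_real_)
  data.frame(normalized = normalized,
             flag = ifelse(ok, "ok", "no_bead_within_window"))
}

#' Modal value of a per-cell distribution
#'
#' Histogram mode on a fixed log-spaced grid (default 64 bins per decade,
#' anchored at 1 so the lattice is independent of the data): the mode is the
#' geometric center of the highest-count bin, with ties broken toward the
#' lower bin. Requires at least `min_cells` cells.
#'
#' @param values positive per-cell values.
#' @param bins_per_decade bins per factor of 10.
#' @param min_cells minimum cells for a defined mode.
#' @return modal value, or NA (flagged via attribute `flag`) with too few
#'   cells.
#' @export
population_mode <- function(values, bins_per_decade = 64L, min_cells = 50L) {
  values <- values[is.finite(values) & values > 0]
  if (length(values) < min_cells) {
    return(structure(NA_real_, flag = "too_few_cells"))
  }
  k <- floor(log10(values) * bins_per_decade)   # bin index on fixed lattice
  tab <- table(k)
  top <- max(tab)
  kmode <- min(as.integer(names(tab)[tab == top]))   # tie -> lower bin
  structure(10^((kmode + 0.5) / bins_per_decade), flag = "ok")
}

#' Daily cell-property features from hourly modal series
#'
#' The daily cell-volume feature is the minimum over the day's hourly volume
#' modes (insensitive to division-driven afternoon growth); the PE
#' fluorescence feature is the modal value at the dawn hour (avoiding
#' quenching and division artifacts later in the day); PE per volume divides
#' the dawn PE mode by the dawn volume mode.
#'
#' @param volume_modes,pe_modes numeric vectors of hourly modal values
#'   indexed by hour 0-23 (NA = missing).
#' @param dawn_hour integer dawn hour (0-23).
#' @param min_hours minimum present hourly volume modes for the volume
#'   feature.
#' @return data.frame with `min_volume_mode`, `dawn_pe_mode`,
#'   `pe_per_volume`, `flag`.
#' @export
daily_features <- function(volume_modes, pe_modes, dawn_hour,
                           min_hours = 12L) {
  stopifnot(length(volume_modes) == 24, length(pe_modes) == 24,
            dawn_hour %in% 0:23)
  n_vol <- sum(!is.na(volume_modes))
  min_vol <- if (n_vol >= min_hours) min(volume_modes, na.rm = TRUE) else NA_real_
  dawn_pe <- pe_modes[dawn_hour + 1]
  dawn_vol <- volume_modes[dawn_hour + 1]
  pe_per_vol <- if (!is.na(dawn_pe) && !is.na(dawn_vol)) dawn_pe / dawn_vol else NA_real_
  flag <- if (is.na(min_vol)) "insufficient_volume_coverage"
          else if (is.na(dawn_pe)) "dawn_pe_missing" else "ok"
  data.frame(min_volume_mode = min_vol, dawn_pe_mode = dawn_pe,
             pe_per_volume = pe_per_vol, flag = flag)
}
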