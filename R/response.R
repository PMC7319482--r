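#' Fit the saturating division-rate versus irradiance curve
#'
#' Nonlinear least squares of
#' `mu = mu_max * (1 - exp(-alpha * E / mu_max))`
#' with positivity bounds, where `alpha` is the initial slope (the
#' derivative at E = 0) and `mu_max` the asymptote. Multi-start (default 5
#' seeded starts) guards against the flat ridge where `alpha * E >> mu_max`.
#'
#' @param mu daily division rates (d^-1).
#' @param E daily incident (or attenuated) radiation (MJ m^-2 d^-1).
#' @param n_starts number of start points.
#' @param seed integer seed for start-point jitter.
#' @return list of class `light_response_fit`: `mu_max`, `alpha`, `rss`,
#'   `n`, `flag` (`"ok"`, `"insufficient_data"` or `"no_convergence"`).
#' @export
fit_light_response <- function(mu, E, n_starts = 5L, seed = 1L) {
  ok <- is.finite(mu) & is.finite(E)
  mu <- mu[ok]; E <- E[ok]
  if (length(mu) < 5 || max(E) < 2 * max(min(E), 1e-12)) {
    return(structure(list(mu_max = NA_real_, alpha = NA_real_,
                          rss = NA_real_, n = length(mu),
                          flag = "insufficient_data"),
                     class = "light_response_fit"))
  }
  dat <- data.frame(mu = mu, E = E)
  set.seed(seed)
  mu0 <- max(stats::quantile(mu, 0.9), 1e-3)
  a0 <- max(mu0 / stats::median(E[E > 0]), 1e-4)
  starts <- data.frame(
    mu_max = mu0 * exp(stats::runif(n_starts, -0.7, 0.7)),
    alpha = a0 * exp(stats::runif(n_starts, -1.5, 1.5)))
  starts[1, ] <- c(mu0, a0)
  best <- NULL
  for (k in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(mu ~ mu_max * (1 - exp(-alpha * E / mu_max)),
                        data = dat,
                        start = list(mu_max = starts$mu_max[k],
                                     alpha = starts$alpha[k]),
                        lower = c(1e-6, 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(mu_max = unname(cf["mu_max"]), alpha = unname(cf["alpha"]),
                   rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(mu_max = NA_real_, alpha = NA_real_,
                          rss = NA_real_, n = length(mu),
                          flag = "no_convergence"),
                     class = "light_response_fit"))
  }
  structure(c(best, list(n = length(mu), flag = "ok")),
            class = "light_response_fit")
}

#' Predicted division rate from a light-response fit
#' @param fit a `light_response_fit`.
#' @param E radiation values.
#' @return predicted rates.
#' @export
predict_light_response <- function(fit, E) {
  fit$mu_max * (1 - exp(-fit$alpha * E / fit$mu_max))
}

#' Light-response fits within temperature bins
#'
#' Partitions days into left-closed 2 degC temperature bins (default 0-22
#' degC, last bin closed), fits the saturating curve within each bin with at
#' least `min_points` points, and classifies each day as light-limited (its
#' radiation falls below the irradiance at which the bin's fitted curve
#' reaches 90% of `mu_max`, i.e. `E90 = mu_max ln(10) / alpha`) or
#' light-saturated.
#'
#' @param mu,E daily division rate and radiation.
#' @param temperature daily mean temperature (degC).
#' @param breaks bin edges (degC).
#' @param min_points minimum days per bin to attempt a fit.
#' @param ... passed to [fit_light_response()].
#' @return list with `fits` (data.frame: bin, t_lo, t_hi, mu_max, alpha,
#'   rss, n, flag) and `days` (data.frame: bin, mu, E, temperature,
#'   classification).
#' @export
fit_by_temperature_bins <- function(mu, E, temperature,
                                    breaks = seq(0, 22, by = 2),
                                    min_points = 5L, ...) {
  stopifnot(length(mu) == length(E), length(E) == length(temperature))
  bin <- cut(temperature, breaks = breaks, right = FALSE,
             include.lowest = TRUE)
  nb <- nlevels(bin)
  rows <- vector("list", nb)
  e90 <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    i <- which(as.integer(bin) == b)
    if (length(i) < min_points) {
      rows[[b]] <- data.frame(bin = levels(bin)[b], t_lo = breaks[b],
                              t_hi = breaks[b + 1], mu_max = NA, alpha = NA,
                              rss = NA, n = length(i), flag = "sparse_bin")
      next
    }
    f <- fit_light_response(mu[i], E[i], ...)
    rows[[b]] <- data.frame(bin = levels(bin)[b], t_lo = breaks[b],
                            t_hi = breaks[b + 1], mu_max = f$mu_max,
                            alpha = f$alpha, rss = f$rss, n = f$n,
                            flag = f$flag)
    if (identical(f$flag, "ok")) e90[b] <- f$mu_max * log(10) / f$alpha
  }
  fits <- do.call(rbind, rows)
  cls <- rep(NA_character_, length(mu))
  bi <- as.integer(bin)
  has_fit <- !is.na(bi) & !is.na(e90[pmax(bi, 1)])
  cls[has_fit] <- ifelse(E[has_fit] < e90[bi[has_fit]],
                         "light_limited", "light_saturated")
  cls[E == 0] <- "light_limited"   # zero radiation is limiting under any fit
  list(fits = fits,
       days = data.frame(bin = bin, mu = mu, E = E,
                         temperature = temperature, classification = cls))
}
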