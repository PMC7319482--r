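#' @useDynLib synseasons, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plnorm optim rgamma rmultinom rbinom runif rnorm rlnorm
NULL

#' Parameters of one subpopulation
#'
#' Each subpopulation is described by a light-dependent growth probability,
#' a size-dependent division probability, and a log-normal starting volume
#' distribution. Probabilities are per 10-min model step.
#'
#' @param gamma_max maximum per-step probability of growing into the next
#'   size class (attained at saturating light), in `[0, 1)`.
#' @param E_star light half-saturation scale (W m^-2) of the growth response.
#' @param delta_max maximum per-step division probability, in `[0, 1)`.
#'   `gamma_max + delta_max` must be < 1 so no transition row exceeds 1.
#' @param v_star division size threshold (um^3): volume at which the division
#'   probability reaches half of `delta_max`.
#' @param eta steepness of the division sigmoid (per ln-um^3).
#' @param mu_LN,sigma_LN log-normal parameters (of ln volume) of the starting
#'   size distribution.
#' @return object of class `subpop_params`.
#' @export
subpop_params <- function(gamma_max, E_star, delta_max, v_star, eta,
                          mu_LN, sigma_LN) {
  stopifnot(gamma_max >= 0, gamma_max < 1, delta_max >= 0, delta_max < 1,
            E_star > 0, v_star > 0, eta > 0, sigma_LN > 0)
  if (gamma_max + delta_max >= 1) {
    stop("gamma_max + delta_max must be < 1 (total exit probability per step)")
  }
  structure(list(gamma_max = gamma_max, E_star = E_star,
                 delta_max = delta_max, v_star = v_star, eta = eta,
                 mu_LN = mu_LN, sigma_LN = sigma_LN),
            class = "subpop_params")
}

#' Full parameter set of the size-structured model
#'
#' @param subpops list of one or two [subpop_params()] objects.
#' @param mix_fraction weight of subpopulation 1 in `[0, 1]`; forced to 1
#'   with a single subpopulation.
#' @param precision Dirichlet-multinomial concentration c > 0; the Dirichlet
#'   parameters for an observed hour are `c * q` with `q` the predicted
#'   proportions.
#' @return object of class `model_params`.
#' @export
model_params <- function(subpops, mix_fraction = 1, precision = 1e4) {
  if (inherits(subpops, "subpop_params")) subpops <- list(subpops)
  stopifnot(length(subpops) %in% 1:2,
            all(vapply(subpops, inherits, TRUE, "subpop_params")),
            mix_fraction >= 0, mix_fraction <= 1,
            is.finite(precision), precision > 0)
  if (length(subpops) == 1) mix_fraction <- 1
  structure(list(subpops = subpops, mix_fraction = mix_fraction,
                 precision = precision),
            class = "model_params")
}

#' Light-dependent per-step growth probability
#'
#' Saturating-exponential response: `gamma = gamma_max * (1 - exp(-E/E_star))`.
#'
#' @param E instantaneous incident radiation (W m^-2), scalar or vector.
#' @param sub a [subpop_params()] object.
#' @return growth probability, same length as `E`; monotone nondecreasing in E.
#' @export
growth_prob <- function(E, sub) {
  if (any(E < 0)) stop("negative irradiance")
  sub$gamma_max * (1 - exp(-E / sub$E_star))
}

#' Size-dependent per-step division probability by class
#'
#' Logistic in ln volume with midpoint `v_star` and steepness `eta`; classes
#' `i <= p` cannot divide (their daughters would fall off the grid) and get
#' exactly zero.
#'
#' @param grid a [size_grid()].
#' @param sub a [subpop_params()].
#' @return numeric vector of length `grid$m`, nondecreasing in class.
#' @export
division_prob <- function(grid, sub) {
  d <- sub$delta_max / (1 + exp(-sub$eta * (log(grid$centers) - log(sub$v_star))))
  d[seq_len(grid$p)] <- 0
  d
}

#' Starting size distribution binned onto the grid
#'
#' Log-normal probability mass per class, computed as CDF differences across
#' the class edges and renormalized over the grid.
#'
#' @inheritParams division_prob
#' @return proportion vector of length `grid$m` summing to 1, with attribute
#'   `coverage` (fraction of log-normal mass inside the grid) and
#'   `grid_too_narrow` flag set when coverage < 0.99.
#' @export
initial_distribution <- function(sub, grid) {
  cdf <- plnorm(grid$edges, meanlog = sub$mu_LN, sdlog = sub$sigma_LN)
  mass <- diff(cdf)
  coverage <- sum(mass)
  if (coverage <= 0) stop("starting distribution has no mass on the grid")
  w <- mass / coverage
  attr(w, "coverage") <- coverage
  attr(w, "grid_too_narrow") <- coverage < 0.99
  w
}

obs_steps_hourly <- function(nsteps, steps_per_hour = 6L) {
  as.integer(seq(0L, nsteps, by = steps_per_hour))
}

#' Forward-project the model over one dawn-to-dawn window
#'
#' Cells advance in 10-min steps: with probability `gamma(E_t)` a cell grows
#' into the next class, with probability `delta_i` a class-i cell divides
#' into two cells of class i - p, otherwise it stays. The top class retains
#' its growth fraction so no cell leaves the grid, and the model has no
#' mortality, so total model cells never decrease.
#'
#' @param params a [model_params()].
#' @param light per-step incident radiation (W m^-2) at 10-min resolution
#'   covering the window; length 144 (or 145, in which case the last value
#'   is ignored).
#' @param grid a [size_grid()].
#' @return object of class `projection_result`: list with `q` (25 x m hourly
#'   mixture proportion matrix, first row the initial state), `n_start`,
#'   `n_end`, `nsub_start`, `nsub_end`, `hours` (0..24 since dawn), `grid`.
#' @export
project_day <- function(params, light, grid) {
  stopifnot(inherits(params, "model_params"), inherits(grid, "size_grid"))
  if (length(light) == 145L) light <- light[seq_len(144L)]
  if (length(light) != 144L) {
    stop("light must cover the dawn-to-dawn window at 10-min resolution (144 steps)")
  }
  if (any(light < 0)) stop("negative irradiance")
  s <- length(params$subpops)
  m <- grid$m
  weights <- if (s == 1) 1 else c(params$mix_fraction, 1 - params$mix_fraction)
  w0 <- matrix(0, m, s)
  gam <- matrix(0, length(light), s)
  del <- matrix(0, m, s)
  for (j in seq_len(s)) {
    sub <- params$subpops[[j]]
    w0[, j] <- initial_distribution(sub, grid) * weights[j]
    gam[, j] <- growth_prob(light, sub)
    del[, j] <- division_prob(grid, sub)
    if (max(gam[, j]) + max(del[, j]) > 1) {
      stop("invalid transition row: gamma + delta exceeds 1 for some class")
    }
  }
  res <- cpp_project(w0, gam, del, grid$p, obs_steps_hourly(length(light)))
  structure(list(q = res$q, n_start = res$n_start, n_end = res$n_end,
                 nsub_start = res$nsub_start, nsub_end = res$nsub_end,
                 w_final = res$w_final,
                 hours = 0:(nrow(res$q) - 1), grid = grid),
            class = "projection_result")
}

#' Division rate from a projection
#'
#' The daily division rate is `ln(N_end / N_start)` over the dawn-to-dawn
#' window; because the model conserves cells except for division, this is the
#' realized per-capita division rate.
#'
#' @param proj a `projection_result`.
#' @return list with `rate` (d^-1) and `subpop_rates`.
#' @export
division_rate_from_projection <- function(proj) {
  stopifnot(proj$n_start > 0)
  list(rate = log(proj$n_end / proj$n_start),
       subpop_rates = log(proj$nsub_end / proj$nsub_start))
}

#' Dirichlet-multinomial log probability mass
#'
#' Log pmf of counts `y` given expected proportions `q` and concentration
#' `c` (Dirichlet parameters `alpha = c * q`). Classes with `q = 0` and
#' `y = 0` contribute nothing; a positive count in a zero-probability class
#' makes the result `-Inf`.
#'
#' @param y non-negative integer count vector.
#' @param q proportion vector summing to 1.
#' @param c concentration (precision) > 0.
#' @return log probability (scalar).
#' @export
dirmult_loglik <- function(y, q, c) {
  stopifnot(length(y) == length(q), all(y >= 0), c > 0,
            abs(sum(q) - 1) < 1e-8)
  if (any(y > 0 & q <= 0)) return(-Inf)
  keep <- q > 0
  y <- y[keep]; a <- c * q[keep]
  n <- sum(y)
  lgamma(n + 1) - sum(lgamma(y + 1)) +
    lgamma(c) - lgamma(n + c) +
    sum(lgamma(y + a) - lgamma(a))
}

#' Hourly size-distribution observations for one dawn-to-dawn window
#'
#' @param counts integer matrix, hours (nominally 25, dawn to next dawn
#'   inclusive) x size classes; rows of all-NA mark missing hours.
#' @param grid the [size_grid()] the columns refer to.
#' @param hours hours since dawn for each row (default `0:(nrow-1)`).
#' @param meta optional list of metadata (e.g. generator truth).
#' @return object of class `size_distribution_series`.
#' @export
size_distribution_series <- function(counts, grid, hours = NULL, meta = list()) {
  counts <- as.matrix(counts)
  stopifnot(inherits(grid, "size_grid"), ncol(counts) == grid$m)
  if (is.null(hours)) hours <- 0:(nrow(counts) - 1)
  stopifnot(length(hours) == nrow(counts), !is.unsorted(hours, strictly = TRUE))
  ok <- !apply(counts, 1, function(r) all(is.na(r)))
  if (any(counts[ok, ] < 0, na.rm = TRUE)) stop("negative counts")
  structure(list(counts = counts, grid = grid, hours = as.integer(hours),
                 totals = rowSums(counts), meta = meta),
            class = "size_distribution_series")
}

#' @export
print.size_distribution_series <- function(x, ...) {
  cat(sprintf("size_distribution_series: %d hours (%d present), %d classes, median n=%g\n",
              nrow(x$counts), sum(!is.na(x$totals)), x$grid$m,
              stats::median(x$totals, na.rm = TRUE)))
  invisible(x)
}
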