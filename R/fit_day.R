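#' Fit configuration for [fit_day()]
#'
#' @param n_subpops integer vector of subpopulation counts to fit (subset of
#'   `c(1, 2)`); all requested configurations are fitted and reported, and
#'   the best by BIC is selected.
#' @param n_starts number of Latin-hypercube start points per configuration.
#' @param seed integer seed controlling the start points (the only source of
#'   randomness in the fit).
#' @param maxit maximum L-BFGS-B iterations per start.
#' @param tol relative convergence tolerance on the objective and parameters.
#' @param min_hours minimum number of present hourly observations; days with
#'   fewer are flagged unusable.
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_subpops = c(1L, 2L), n_starts = 20L, seed = 1L,
                       maxit = 200L, tol = 1e-6, min_hours = 20L) {
  stopifnot(all(n_subpops %in% 1:2), n_starts >= 1, tol > 0)
  structure(list(n_subpops = as.integer(n_subpops),
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 maxit = as.integer(maxit), tol = tol,
                 min_hours = as.integer(min_hours)),
            class = "fit_config")
}

# -- parameter vector packing ------------------------------------------------
# Per subpopulation, on the optimizer scale:
#   gamma_max, log(E_star), delta_max, log(v_star), log(eta), mu_LN,
#   log(sigma_LN)
# plus shared mix fraction f (2 subpops only) and log(precision c).

.theta_bounds <- function(grid, s) {
  per <- list(
    lower = c(1e-4, log(2),    1e-4, log(grid$centers[grid$p + 1]),
              log(1),  log(grid$edges[1]),          log(0.05)),
    upper = c(0.45, log(2000), 0.45, log(grid$centers[grid$m]),
              log(40), log(grid$edges[grid$m + 1]), log(0.8)))
  lower <- rep(per$lower, s)
  upper <- rep(per$upper, s)
  if (s == 2) { lower <- c(lower, 0.05); upper <- c(upper, 0.95) }
  lower <- c(lower, log(5)); upper <- c(upper, log(1e6))
  list(lower = lower, upper = upper)
}

.theta_to_params <- function(theta, s) {
  subs <- vector("list", s)
  for (j in seq_len(s)) {
    t0 <- theta[(j - 1) * 7 + 1:7]
    subs[[j]] <- subpop_params(gamma_max = t0[1], E_star = exp(t0[2]),
                               delta_max = t0[3], v_star = exp(t0[4]),
                               eta = exp(t0[5]), mu_LN = t0[6],
                               sigma_LN = exp(t0[7]))
  }
  f <- if (s == 2) theta[7 * s + 1] else 1
  c_prec <- exp(theta[length(theta)])
  model_params(subs, mix_fraction = f, precision = c_prec)
}

# Dirichlet-multinomial negative log-likelihood over present hours, dropping
# the multinomial coefficient (constant in the parameters). Q rows are
# floored at a tiny value and renormalized so the objective stays finite.
.dm_nll <- function(Y, Q, c_prec, nk) {
  Q <- pmax(Q, 1e-12)
  Q <- Q / rowSums(Q)
  A <- c_prec * Q
  -(sum(lgamma(Y + A) - lgamma(A)) +
      nrow(Y) * lgamma(c_prec) - sum(lgamma(nk + c_prec)))
}

# constant part of the full log pmf (multinomial coefficient), added back
# when reporting the log-likelihood
.dm_logconst <- function(Y, nk) {
  sum(lgamma(nk + 1)) - sum(lgamma(Y + 1))
}

.make_objective <- function(Y, nk, light, grid, s, obs_steps) {
  m <- grid$m
  force(obs_steps)
  function(theta) {
    c_prec <- exp(theta[length(theta)])
    f <- if (s == 2) theta[7 * s + 1] else 1
    weights <- if (s == 1) 1 else c(f, 1 - f)
    w0 <- matrix(0, m, s); gam <- matrix(0, length(light), s)
    del <- matrix(0, m, s)
    for (j in seq_len(s)) {
      t0 <- theta[(j - 1) * 7 + 1:7]
      cdf <- plnorm(grid$edges, meanlog = t0[6], sdlog = exp(t0[7]))
      mass <- diff(cdf)
      tot <- sum(mass)
      if (tot <= 0) return(1e10)
      w0[, j] <- mass / tot * weights[j]
      gam[, j] <- t0[1] * (1 - exp(-light / exp(t0[2])))
      d <- t0[3] / (1 + exp(-exp(t0[5]) * (log(grid$centers) - t0[4])))
      d[seq_len(grid$p)] <- 0
      del[, j] <- d
    }
    pr <- cpp_project(w0, gam, del, grid$p, obs_steps)
    nll <- .dm_nll(Y, pr$q, c_prec, nk)
    if (!is.finite(nll)) 1e10 else nll
  }
}

# data-informed start: moments of the earliest present hour's distribution
.smart_start <- function(Y, grid, s, bounds) {
  y1 <- Y[1, ]
  lv <- log(grid$centers)
  mu0 <- sum(y1 * lv) / sum(y1)
  sd0 <- sqrt(sum(y1 * (lv - mu0)^2) / sum(y1))
  sd0 <- min(max(sd0, 0.08), 0.7)
  per <- function(mu) c(0.1, log(150), 0.05, min(max(mu + log(2),
                                                     log(grid$centers[grid$p + 1])),
                                                 log(grid$centers[grid$m])),
                        log(5), mu, log(sd0))
  theta <- if (s == 1) per(mu0) else c(per(mu0 - 0.2), per(mu0 + 0.2))
  if (s == 2) theta <- c(theta, 0.5)
  theta <- c(theta, log(500))
  pmin(pmax(theta, bounds$lower + 1e-9), bounds$upper - 1e-9)
}

.fit_one_config <- function(Y, nk, light, grid, s, obs_steps, config) {
  bounds <- .theta_bounds(grid, s)
  npar <- length(bounds$lower)
  obj <- .make_objective(Y, nk, light, grid, s, obs_steps)
  set.seed(config$seed + s)
  u <- lhs::randomLHS(config$n_starts, npar)
  starts <- t(t(u) * (bounds$upper - bounds$lower) + bounds$lower)
  starts[1, ] <- .smart_start(Y, grid, s, bounds)
  best <- NULL
  convergence <- integer(config$n_starts)
  values <- rep(NA_real_, config$n_starts)
  factr <- config$tol / .Machine$double.eps
  for (k in seq_len(config$n_starts)) {
    fit <- tryCatch(
      optim(starts[k, ], obj, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = config$maxit, factr = factr)),
      error = function(e) NULL)
    if (is.null(fit)) { convergence[k] <- 99L; next }
    convergence[k] <- fit$convergence
    values[k] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || all(convergence != 0)) {
    return(list(status = "failed", convergence = convergence))
  }
  params <- .theta_to_params(best$par, s)
  proj <- project_day(params, light, grid)
  rates <- division_rate_from_projection(proj)
  loglik <- -best$value + .dm_logconst(Y, nk)
  k_hours <- nrow(Y)
  list(status = "ok", params = params, loglik = loglik,
       bic = -2 * loglik + npar * log(k_hours),
       division_rate = rates$rate, subpop_rates = rates$subpop_rates,
       n_subpops = s, convergence = convergence, start_values = values)
}

#' Estimate the daily division rate by maximum likelihood
#'
#' Fits the size-structured matrix model to one day of hourly size
#' distributions, maximizing the Dirichlet-multinomial log-likelihood of the
#' observed count vectors given the model's predicted hourly proportions.
#' Optimization is multi-start bounded L-BFGS-B from Latin-hypercube start
#' points (plus one data-informed start); missing hours are dropped from the
#' likelihood. One- and two-subpopulation configurations are fitted as
#' requested and the winner chosen by BIC.
#'
#' The division-rate estimate depends only on the *shape* of the hourly size
#' distributions (proportions), never on total counts, so uniform thinning
#' of cells (e.g. by grazing) leaves it unchanged in expectation.
#'
#' @param obs a [size_distribution_series()].
#' @param light per-step incident radiation, as for [project_day()].
#' @param config a [fit_config()].
#' @return object of class `fit_result`: the selected model's `params`,
#'   `loglik`, `division_rate` (d^-1), `subpop_rates`, plus `fits` (one
#'   entry per requested configuration), `status`, `seed`, `n_starts`, and
#'   per-start `convergence` codes.
#' @export
fit_day <- function(obs, light, config = fit_config()) {
  stopifnot(inherits(obs, "size_distribution_series"),
            inherits(config, "fit_config"))
  if (length(light) == 145L) light <- light[seq_len(144L)]
  stopifnot(length(light) == 144L)
  present <- !apply(obs$counts, 1, function(r) all(is.na(r)))
  if (sum(present) < config$min_hours) {
    return(structure(list(status = "unusable",
                          n_hours = sum(present),
                          division_rate = NA_real_, loglik = NA_real_,
                          seed = config$seed),
                     class = "fit_result"))
  }
  Y <- obs$counts[present, , drop = FALSE]
  nk <- rowSums(Y)
  obs_steps <- as.integer(obs$hours[present] * 6L)
  fits <- lapply(config$n_subpops, function(s) {
    .fit_one_config(Y, nk, light, obs$grid, s, obs_steps, config)
  })
  names(fits) <- paste0("subpops_", config$n_subpops)
  ok <- vapply(fits, function(f) identical(f$status, "ok"), TRUE)
  if (!any(ok)) {
    return(structure(list(status = "failed", fits = fits,
                          division_rate = NA_real_, loglik = NA_real_,
                          seed = config$seed),
                     class = "fit_result"))
  }
  bics <- vapply(fits, function(f) if (identical(f$status, "ok")) f$bic else Inf,
                 numeric(1))
  sel <- fits[[which.min(bics)]]
  structure(list(status = "ok", params = sel$params, loglik = sel$loglik,
                 division_rate = sel$division_rate,
                 subpop_rates = sel$subpop_rates,
                 n_subpops = sel$n_subpops, bic = sel$bic,
                 fits = fits, convergence = sel$convergence,
                 n_starts = config$n_starts, seed = config$seed,
                 n_hours = sum(present)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat(sprintf("fit_result: status %s\n", x$status))
    return(invisible(x))
  }
  cat(sprintf(
    "fit_result: %d subpop(s), division rate %.3f d^-1, loglik %.1f (%d starts)\n",
    x$n_subpops, x$division_rate, x$loglik, x$n_starts))
  invisible(x)
}
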