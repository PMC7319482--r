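test_that("size grid lattice doubles correctly and closes under halving", {
  g <- size_grid(0.05, p = 1, m = 5)
  expect_equal(g$centers, c(0.05, 0.1, 0.2, 0.4, 0.8))

  g2 <- size_grid(0.02, p = 4, m = 9)
  expect_equal(g2$centers[5], 2 * g2$centers[1])

  g3 <- size_grid(0.03, p = 3, m = 12)
  i <- (g3$p + 1):g3$m
  expect_equal(g3$centers[i] / 2, g3$centers[i - g3$p])

  expect_error(size_grid(0.05, p = 5, m = 5), "exceed")
})

test_that("growth probability saturates in light", {
  sub <- subpop_params(0.2, 100, 0.1, 0.4, 5, log(0.3), 0.2)
  expect_equal(growth_prob(0, sub), 0)
  expect_equal(growth_prob(1e9, sub), 0.2)
  expect_equal(growth_prob(100, sub), 0.2 * (1 - exp(-1)))
  expect_error(growth_prob(-1, sub), "negative")
  e <- seq(0, 500, by = 10)
  expect_true(all(diff(growth_prob(e, sub)) >= 0))
})

test_that("division probability is a sigmoid in ln volume, zero below the grid floor", {
  g <- size_grid(0.02, p = 4, m = 25)
  v_star <- g$centers[12]
  sub <- subpop_params(0.1, 100, 0.2, v_star, 8, log(0.3), 0.2)
  d <- division_prob(g, sub)
  expect_equal(d[seq_len(g$p)], rep(0, g$p))
  expect_equal(d[12], 0.2 / 2)           # midpoint of the sigmoid
  expect_true(all(diff(d[-seq_len(g$p)]) >= 0))
  # steep limit approaches a step at v_star
  sub2 <- subpop_params(0.1, 100, 0.2, v_star, 500, log(0.3), 0.2)
  d2 <- division_prob(g, sub2)
  expect_lt(max(d2[g$centers < v_star * 0.9]), 1e-6)
  expect_gt(min(d2[g$centers > v_star * 1.1]), 0.2 - 1e-6)
})

test_that("initial distribution matches lognormal quadrature and concentrates correctly", {
  g <- size_grid(0.02, p = 4, m = 25)
  sub <- subpop_params(0.1, 100, 0.1, 0.4, 5, log(0.3), 0.25)
  w <- initial_distribution(sub, g)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  # quadrature oracle per class
  for (i in c(1, 8, 15, 25)) {
    oracle <- integrate(dlnorm, g$edges[i], g$edges[i + 1],
                        meanlog = log(0.3), sdlog = 0.25,
                        rel.tol = 1e-12)$value
    expect_equal(w[i] * attr(w, "coverage"), oracle, tolerance = 1e-8)
  }
  # tiny sigma concentrates >= 99% mass in the class holding the mean
  sub2 <- subpop_params(0.1, 100, 0.1, 0.4, 5, log(g$centers[10]), 0.01)
  w2 <- initial_distribution(sub2, g)
  expect_gte(w2[10], 0.99)
  # narrow grid flagged
  gn <- size_grid(0.02, p = 4, m = 6)
  wn <- initial_distribution(sub, gn)
  expect_true(attr(wn, "grid_too_narrow"))
})

test_that("projection conserves cells without division and is stationary without growth", {
  g <- size_grid()
  light <- test_light()
  p0 <- model_params(subpop_params(0.15, 120, 0, 0.45, 8, log(0.28), 0.18))
  pr <- project_day(p0, light, g)
  expect_equal(pr$n_end, pr$n_start, tolerance = 1e-12)
  expect_equal(division_rate_from_projection(pr)$rate, 0, tolerance = 1e-12)
  # no growth and no division: proportions frozen at the initial distribution
  pid <- model_params(subpop_params(0, 100, 0, 0.45, 8, log(0.28), 0.18))
  pri <- project_day(pid, light, g)
  w0 <- initial_distribution(pid$subpops[[1]], g)
  for (k in c(1, 13, 25)) expect_equal(pri$q[k, ], as.numeric(w0),
                                       tolerance = 1e-12)
})

test_that("cell number never decreases along a projection", {
  g <- size_grid()
  light <- test_light()
  set.seed(42)
  for (r in 1:5) {
    gm <- runif(1, 0, 0.4); dm <- runif(1, 0, 0.4)
    p <- model_params(subpop_params(gm, runif(1, 20, 500), dm,
                                    runif(1, 0.2, 0.8), runif(1, 2, 20),
                                    log(runif(1, 0.1, 0.5)),
                                    runif(1, 0.1, 0.4)))
    # N is monitored at start/end; check hourly by chaining sub-windows
    pr <- project_day(p, light, g)
    expect_gte(pr$n_end, pr$n_start - 1e-12)
  }
})

test_that("one synchronized division doubles the population (rate ln 2)", {
  # all cells in one class with delta = 1 there via a steep sigmoid, no growth
  g <- size_grid(0.02, p = 4, m = 25)
  target <- 10L
  sub <- subpop_params(gamma_max = 0, E_star = 100, delta_max = 0.99,
                       v_star = g$centers[target] / 1.2, eta = 2000,
                       mu_LN = log(g$centers[target]), sigma_LN = 0.005)
  p <- model_params(sub)
  light <- rep(0, 144)
  pr <- project_day(p, light, g)
  # after 144 steps at delta ~= 0.99 every cell has divided exactly once
  # (daughters in class target - p have delta ~= 0 there)
  expect_equal(division_rate_from_projection(pr)$rate, log(2),
               tolerance = 1e-3)
})

test_that("division rate combines subpopulation totals correctly", {
  proj <- structure(list(n_start = 1, n_end = 1.5,
                         nsub_start = c(0.5, 0.5), nsub_end = c(0.5, 1.0)),
                    class = "projection_result")
  r <- division_rate_from_projection(proj)
  expect_equal(r$rate, log(1.5))
  expect_equal(r$subpop_rates, c(0, log(2)))
})

test_that("Dirichlet-multinomial pmf matches enumeration and multinomial limit", {
  # uniform alpha = (1,1): every outcome of n = 2 equally likely
  expect_equal(dirmult_loglik(c(1, 1), c(0.5, 0.5), 2), log(1 / 3))
  expect_equal(dirmult_loglik(c(2, 0), c(0.5, 0.5), 2), log(1 / 3))
  # total probability 1 by exhaustive enumeration
  expect_equal(dm_total_prob(4, c(0.2, 0.5, 0.3), 7.3), 1, tolerance = 1e-10)
  expect_equal(dm_total_prob(6, c(0.9, 0.1), 0.5), 1, tolerance = 1e-10)
  # large-c limit converges to the multinomial pmf
  y <- c(3, 1, 2)
  q <- c(0.5, 0.2, 0.3)
  expect_equal(dirmult_loglik(y, q, 1e9),
               dmultinom(y, prob = q, log = TRUE), tolerance = 1e-6)
  # zero-probability class: impossible outcome, not an exception
  expect_identical(dirmult_loglik(c(1, 1, 1), c(0.5, 0.5, 0), 10), -Inf)
  expect_equal(dirmult_loglik(c(1, 1, 0), c(0.5, 0.5, 0), 2), log(1 / 3))
})

test_that("transition operator conserves probability when division is off", {
  # random parameter draws: with delta = 0 the implied matrix is a proper
  # stochastic operator, so any initial mass vector keeps its total
  g <- size_grid(0.05, p = 2, m = 8)
  set.seed(7)
  for (r in 1:10) {
    p <- model_params(subpop_params(runif(1, 0, 0.9), runif(1, 10, 300), 0,
                                    0.4, 5, log(runif(1, 0.06, 0.6)),
                                    runif(1, 0.05, 0.5)))
    light <- runif(144, 0, 400)
    pr <- project_day(p, light, g)
    expect_equal(pr$n_end, pr$n_start, tolerance = 1e-12)
  }
})
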