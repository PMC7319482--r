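# Shared fixtures for the test suite. Everything is generated in code.

# a short spring environment at the default site
test_env <- function(n_days = 6L, seed = 11L) {
  gen_environment(scenario_config(seed = seed, n_days = n_days))
}

# a representative 144-step dawn-to-dawn light series (moderate day length)
test_light <- function() {
  env <- gen_environment(scenario_config(seed = 5L, n_days = 130L))
  dawn_window_light(env, 120L)
}

# enumerate all count vectors of total n over k classes
enumerate_counts <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- NULL
  for (i in 0:n) {
    sub <- enumerate_counts(n - i, k - 1)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

# exhaustive Dirichlet-multinomial total probability (independent oracle for
# normalization: sums exp(log pmf) over every outcome)
dm_total_prob <- function(n, q, c) {
  y <- enumerate_counts(n, length(q))
  sum(apply(y, 1, function(yy) exp(dirmult_loglik(yy, q, c))))
}
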