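# Shared fixtures and independent oracles.

# Independent Poisson log-likelihood: written out from the probability mass
# function, not via the package's log_likelihood().
oracle_ll <- function(coefs, X, d, z) {
  eta <- drop(X %*% coefs)
  sum(d * (log(z) + eta) - z * exp(eta) - lgamma(d + 1))
}

# Generic numerical ML oracle: quasi-Newton minimization of -2 log L with
# analytic gradient from a neutral start, restarted until stationary.
oracle_fit <- function(X, d, z) {
  start <- c(log(sum(d) / sum(z)), rep(0, ncol(X) - 1))
  fn <- function(b) -2 * oracle_ll(b, X, d, z)
  gr <- function(b) -2 * drop(crossprod(X, d - z * exp(drop(X %*% b))))
  ctrl <- list(iter.max = 2000, eval.max = 5000, rel.tol = 1e-14)
  opt <- nlminb(start, fn, gr, control = ctrl)
  for (k in 1:3) opt <- nlminb(opt$par, fn, gr, control = ctrl)
  list(deviance = opt$objective, coefficients = opt$par)
}

# Random small age-period table simulated from a smooth low-degree surface,
# optionally with a planted cohort bump.
random_small_table <- function(seed, n_age = 6, n_period = 5,
                               degree = 2, bump = NULL, beta_c = 0,
                               exposure = 1e5) {
  ages <- seq(30, 30 + 10 * (n_age - 1), by = 10)
  periods <- seq(1960, 1960 + 10 * (n_period - 1), by = 10)
  m <- (degree + 1)^2
  set.seed(seed)
  theta <- c(log(2e-4), round(rnorm(m - 1, 0, 0.3), 3))
  sc <- simulation_scenario(ages, periods, theta, bump = bump,
                            beta_c = beta_c, exposure = exposure,
                            seed = seed + 1, age_width = 10,
                            period_width = 10)
  spec <- basis_spec(age_degree = degree, period_degree = degree,
                     age_center = mean(ages), age_scale = sd(ages),
                     period_center = mean(periods), period_scale = sd(periods))
  list(table = simulate_table(sc, spec), spec = spec, theta = theta,
       scenario = sc)
}

# Plain data frame for constructor tests.
toy_cells <- function() {
  data.frame(
    age = c(42.5, 47.5, 42.5),
    period = c(1992.5, 1992.5, 1997.5),
    deaths = c(10, 20, 15),
    person_years = c(2e5, 1.8e5, 2.1e5))
}
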