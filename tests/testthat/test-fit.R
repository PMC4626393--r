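test_that("log-likelihood matches hand-evaluated Poisson terms", {
  tab <- age_period_table(data.frame(age = 40, period = 1990,
                                     deaths = 2, person_years = 1))
  spec <- basis_spec(0, 0)
  # d = 2, z = 1, b0 = 0: ll = 2*0 - 1 - log 2
  expect_equal(log_likelihood(0, table = tab, spec = spec), -1 - log(2))
  # saturated plug-in b0 = log(d/z) at unit exposure
  d <- 7; z <- 1
  tab2 <- age_period_table(data.frame(age = 40, period = 1990,
                                      deaths = d, person_years = z))
  expect_equal(log_likelihood(log(d / z), table = tab2, spec = spec),
               d * log(d / z) - d - lgamma(d + 1))
  # a huge negative rate with observed deaths drives ll toward -Inf
  expect_lt(suppressWarnings(log_likelihood(-200, table = tab2, spec = spec)),
            -1000)
  expect_warning(log_likelihood(-200, table = tab2, spec = spec), "50")
})

test_that("single-cell intercept-only fit is the Poisson rate MLE d/z", {
  tab <- age_period_table(data.frame(age = 40, period = 1990,
                                     deaths = 7, person_years = 100))
  fit <- fit_ml(tab, basis_spec(0, 0))
  expect_true(fit$converged)
  expect_equal(exp(unname(fit$theta_hat)), 0.07, tolerance = 1e-8)
  expect_null(fit$beta_c_hat)
})

test_that("deviance is self-consistent and the score vanishes at the optimum", {
  for (seed in c(2, 9, 31)) {
    fix <- random_small_table(seed, bump = cohort_bump(1930, 5), beta_c = 2)
    fit <- fit_ml(fix$table, fix$spec, bump = cohort_bump(1930, 5))
    expect_true(fit$converged)
    # -2 logLik recomputed from the data through the likelihood function
    expect_equal(
      fit$deviance_stat,
      -2 * log_likelihood(fit$theta_hat, fit$beta_c_hat, fix$table,
                          fix$spec, cohort_bump(1930, 5)),
      tolerance = 1e-6)
    # IRLS normal equations: X'(d - fitted) = 0 per column
    expect_lt(max(abs(fit$score)), 1e-6)
    # intercept present: fitted deaths conserve observed deaths
    expect_equal(sum(fit$fitted), sum(fix$table$deaths), tolerance = 1e-8)
    # covariance symmetric positive definite
    expect_equal(fit$covariance, t(fit$covariance))
    expect_true(all(eigen(fit$covariance, symmetric = TRUE,
                          only.values = TRUE)$values > 0))
  }
})

test_that("fit matches a generic numerical ML optimizer on random tables", {
  for (seed in 1:8) {
    bump <- if (seed %% 2 == 0) cohort_bump(1935, 6) else NULL
    fix <- random_small_table(seed, bump = bump,
                              beta_c = if (is.null(bump)) 0 else 1.5)
    fit <- fit_ml(fix$table, fix$spec, bump = bump)
    X <- design_matrix(fix$table, fix$spec, bump)
    oracle <- oracle_fit(X, fix$table$deaths, fix$table$person_years)
    expect_lt(abs(fit$deviance_stat - oracle$deviance), 1e-6)
  }
})

test_that("rank-deficient designs fail loudly, naming collinear columns", {
  set.seed(1)
  tab <- age_period_table(data.frame(
    age = seq(20, 70, 10), period = 1990,
    deaths = rpois(6, 20), person_years = 1e4))
  # a single period with explicit centering makes every p column zero
  spec <- basis_spec(1, 1, age_center = 45, age_scale = 10,
                     period_center = 1990, period_scale = 5)
  expect_error(fit_ml(tab, spec), "collinear.*p")
})

test_that("too few cells and non-convergence are reported, not hidden", {
  tab <- age_period_table(data.frame(
    age = c(40, 50), period = 1990, deaths = c(3, 5), person_years = 1e3))
  expect_error(fit_ml(tab, basis_spec(2, 0, age_center = 45, age_scale = 5)),
               "fewer cells")
  fix <- random_small_table(13)
  expect_warning(fit <- fit_ml(fix$table, fix$spec, max_iter = 1),
                 "did not converge")
  expect_false(fit$converged)
  expect_error(wald_tests(fit), "converge")
})

test_that("Wald tests report estimate/SE ratios with two-sided normal p-values", {
  fix <- random_small_table(7, bump = cohort_bump(1930, 5), beta_c = 2)
  fit <- fit_ml(fix$table, fix$spec, bump = cohort_bump(1930, 5))
  wt <- wald_tests(fit)
  expect_equal(nrow(wt), length(fit$coefficients))
  expect_equal(wt$term[nrow(wt)], "cohort")
  expect_equal(wt$z_value, wt$estimate / wt$std_error)
  # independent two-sided tail via numerical integration of the normal density
  for (i in c(1, nrow(wt))) {
    p_indep <- 2 * integrate(dnorm, abs(wt$z_value[i]), Inf)$value
    expect_equal(wt$p_value[i], p_indep, tolerance = 1e-8)
  }
  # reference point: z = 2 gives p ~ 0.04550
  expect_equal(2 * pnorm(-2), 0.0455, tolerance = 1e-3)
})

test_that("the bump column never increases the deviance index", {
  for (seed in c(3, 14, 25, 36)) {
    fix <- random_small_table(seed, bump = cohort_bump(1930, 5),
                              beta_c = seed %% 3 - 1)
    null_fit <- fit_ml(fix$table, fix$spec)
    bump_fit <- fit_ml(fix$table, fix$spec, bump = cohort_bump(1930, 5))
    expect_lte(bump_fit$deviance_stat, null_fit$deviance_stat + 1e-8)
  }
})

test_that("Wald intervals for beta_c cover the truth at the nominal rate", {
  covered <- 0
  for (s in 1:100) {
    sc0 <- default_scenario("bump-positive")
    sc <- simulation_scenario(sc0$ages, sc0$periods, sc0$theta,
                              cohort_bump(1950, 4), beta_c = 4,
                              exposure = 1e6, seed = 5000 + s)
    fit <- fit_ml(simulate_table(sc), bump = cohort_bump(1950, 4))
    wt <- wald_tests(fit)
    b <- wt[wt$term == "cohort", ]
    covered <- covered +
      (abs(b$estimate - 4) <= qnorm(0.975) * b$std_error)
  }
  expect_gte(covered, 93)
})

test_that("fit serializes to JSON with coefficients and metadata", {
  fix <- random_small_table(4, bump = cohort_bump(1930, 5), beta_c = 1)
  fit <- fit_ml(fix$table, fix$spec, bump = cohort_bump(1930, 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  obj <- jsonlite::fromJSON(path)
  expect_equal(obj$deviance, fit$deviance_stat)
  expect_equal(obj$bump$mu, 1930)
  expect_equal(nrow(obj$coefficients), length(fit$coefficients))
})
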