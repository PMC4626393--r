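#' Poisson log-likelihood of an age-period model
#'
#' Evaluates the full log-likelihood `sum_j d_j (log z_j + b0_j) -
#' z_j exp(b0_j) - log d_j!` where `b0_j = theta' x(a_j, p_j) [+ beta_c *
#' phi_j]` is the varying coefficient at cell j. The `-log d!` constant is
#' retained so that `-2 * log_likelihood` is an absolute goodness-of-fit
#' index; it cancels in any comparison of models on the same table.
#'
#' @param theta coefficient vector for the polynomial basis (length
#'   `basis_dim(spec)`).
#' @param beta_c cohort-bump coefficient, or `NULL` when fitting without the
#'   bump term.
#' @param table an [age_period_table].
#' @param spec a [basis_spec].
#' @param bump a [cohort_bump] (required when `beta_c` is given).
#' @return The scalar log-likelihood.
#' @export
log_likelihood <- function(theta, beta_c = NULL, table, spec, bump = NULL) {
  if (is.null(beta_c) != is.null(bump)) {
    stop("beta_c and bump must be supplied together or both omitted")
  }
  X <- design_matrix(table, spec, bump)
  coefs <- c(theta, beta_c)
  if (length(coefs) != ncol(X)) {
    stop("coefficient length ", length(coefs),
         " does not match design dimension ", ncol(X))
  }
  b0 <- drop(X %*% coefs)
  if (any(abs(b0) > 50)) {
    warning("linear predictor exceeds |50| at ",
            sum(abs(b0) > 50), " cell(s); exp(b0) may overflow")
  }
  d <- table$deaths
  z <- table$person_years
  terms <- d * (log(z) + b0) - z * exp(b0) - lgamma(d + 1)
  bad <- which(!is.finite(terms))
  if (length(bad) > 0) {
    stop("log-likelihood overflow at cell(s) ", cell_label(table, bad))
  }
  sum(terms)
}

#' Maximum-likelihood fit of the varying-coefficient Poisson model
#'
#' Fits `deaths ~ Poisson(person_years * exp(b0(a, p)))` with
#' `b0 = theta' x(a, p) + beta_c * phi(p - a; mu, sigma)` by iteratively
#' reweighted least squares (the log person-years enter as an offset). The
#' bump parameters (mu, sigma) are held fixed; see [grid_search()] for their
#' profile-deviance estimation. The start is deterministic: all coefficients
#' zero except the intercept at `log(sum(deaths)/sum(person_years))`.
#' Standard errors come from the inverse observed Fisher information
#' `X' diag(fitted) X` (equal to the expected information under the canonical
#' log link).
#'
#' @param table an [age_period_table].
#' @param spec a [basis_spec]; defaults to the cubic-by-cubic basis
#'   standardized on `table`.
#' @param bump a [cohort_bump], or `NULL` for the polynomial-only null model.
#' @param max_iter maximum IRLS iterations (default 100).
#' @param tol relative deviance-change convergence tolerance (default 1e-10);
#'   a fit is also accepted as converged when the maximum absolute score
#'   component is below 1e-8.
#' @return An object of class `cohort_fit` with components `coefficients`,
#'   `theta_hat`, `beta_c_hat` (`NULL` without a bump), `covariance`,
#'   `log_lik`, `deviance_stat` (`-2 * log_lik`), `converged`, `iterations`,
#'   `fitted` (expected deaths per cell), `spec`, `bump`, and `data`.
#' @examples
#' sc <- default_scenario("bump-positive")
#' tab <- simulate_table(sc)
#' fit <- fit_ml(tab, bump = sc$bump)
#' tail(wald_tests(fit), 1)   # inference on beta_c
#' @export
fit_ml <- function(table, spec = NULL, bump = NULL, max_iter = 100,
                   tol = 1e-10) {
  stopifnot(inherits(table, "age_period_table"))
  spec <- spec %||% basis_spec(table = table)
  X <- design_matrix(table, spec, bump)
  n <- nrow(X)
  k <- ncol(X)
  if (n < k) {
    stop("fewer cells (", n, ") than parameters (", k, ")")
  }
  qr_x <- qr(X)
  if (qr_x$rank < k) {
    dependent <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):k]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dependent, collapse = ", "))
  }
  d <- table$deaths
  z <- table$person_years
  start <- c(log(sum(d) / sum(z)), rep(0, k - 1))
  fit <- suppressWarnings(stats::glm.fit(
    x = X, y = d, family = stats::poisson(), offset = log(z),
    start = start,
    control = stats::glm.control(epsilon = tol, maxit = max_iter)
  ))
  mu <- fit$fitted.values
  score <- drop(crossprod(X, d - mu))
  converged <- isTRUE(fit$converged) || max(abs(score)) < 1e-8
  if (!converged) {
    warning("IRLS did not converge in ", max_iter, " iterations")
  }
  info <- crossprod(X * mu, X)
  covariance <- tryCatch(chol2inv(chol(info)), error = function(e) {
    stop("observed information matrix is numerically singular")
  })
  dimnames(covariance) <- list(colnames(X), colnames(X))
  coefs <- stats::setNames(fit$coefficients, colnames(X))
  ll <- sum(stats::dpois(d, mu, log = TRUE))
  m <- basis_dim(spec)
  structure(
    list(coefficients = coefs,
         theta_hat = coefs[seq_len(m)],
         beta_c_hat = if (is.null(bump)) NULL else unname(coefs[m + 1L]),
         covariance = covariance,
         log_lik = ll,
         deviance_stat = -2 * ll,
         converged = converged,
         iterations = fit$iter,
         fitted = mu,
         score = score,
         spec = spec,
         bump = bump,
         data = table),
    class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, digits = 4, ...) {
  cat("Varying-coefficient Poisson fit",
      if (is.null(x$bump)) "(no cohort bump)" else
        sprintf("with cohort bump (mu = %g, sigma = %g)",
                x$bump$mu, x$bump$sigma), "\n")
  cat(sprintf("  n = %d cells, %d parameters, -2 log L = %.*f%s\n",
              nrow(x$data), length(x$coefficients), digits, x$deviance_stat,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(wald_tests(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Wald tests for every coefficient
#'
#' Per-coefficient estimate, standard error (square root of the covariance
#' diagonal), z-value and two-sided normal p-value. When the model includes a
#' cohort bump, its coefficient `beta_c` appears in the last row (term
#' `"cohort"`); its test is the significance test of the detected cohort
#' effect.
#'
#' @param fit a converged [fit_ml()] result.
#' @return Data frame with columns `term`, `estimate`, `std_error`,
#'   `z_value`, `p_value`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "cohort_fit"))
  if (!fit$converged) stop("fit did not converge; Wald inference unavailable")
  v <- diag(fit$covariance)
  if (any(!is.finite(v) | v <= 0)) {
    stop("non-positive variance on the covariance diagonal; ",
         "information matrix numerically singular")
  }
  se <- sqrt(v)
  z <- unname(fit$coefficients / se)
  data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    std_error = unname(se),
    z_value = z,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Serialize a fit to JSON
#'
#' Writes the coefficient table (term, estimate, SE, z, p), the deviance
#' index `-2 log L`, convergence metadata, and echoes of the basis
#' standardization and bump parameters, so a fit is fully reproducible from
#' the JSON plus the data.
#'
#' @param fit a [fit_ml()] result.
#' @param path output path; when `NULL` the JSON string is returned instead.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "cohort_fit"))
  obj <- list(
    coefficients = wald_tests(fit),
    deviance = fit$deviance_stat,
    log_lik = fit$log_lik,
    converged = fit$converged,
    iterations = fit$iterations,
    n_cells = nrow(fit$data),
    basis = fit$spec[c("age_degree", "period_degree", "age_center",
                       "age_scale", "period_center", "period_scale")],
    bump = if (is.null(fit$bump)) NULL else fit$bump[c("mu", "sigma")]
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
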