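#' Polynomial interaction basis specification
#'
#' Defines the tensor-product polynomial basis x(a, p) whose terms are
#' `a^i * p^j` for `i = 0..age_degree`, `j = 0..period_degree` (dimension
#' `m = (age_degree + 1) * (period_degree + 1)`; the cubic-by-cubic default
#' gives m = 16), together with the affine standardization applied to age and
#' period before the powers are taken. Standardizing to mean 0 / sd 1 keeps
#' the design well conditioned for cubic terms over decades-wide ranges; the
#' constants are stored in the spec so a fit is reproducible from the spec
#' alone. The Gaussian cohort basis is *not* standardized — it is always
#' evaluated on raw `period - age` in calendar years (see [cohort_density()]).
#'
#' @param age_degree,period_degree non-negative integer polynomial degrees
#'   (default cubic).
#' @param table optional [age_period_table]; when supplied, centering and
#'   scaling constants default to the mean and standard deviation of the
#'   table's cell ages and periods.
#' @param age_center,age_scale,period_center,period_scale explicit affine
#'   constants `x -> (x - center)/scale`; defaults are the table moments, or
#'   center 0 / scale 1 when no table is given. Scales must be nonzero.
#' @return An object of class `basis_spec`.
#' @examples
#' spec <- basis_spec(age_degree = 1, period_degree = 1)
#' polynomial_row(2, -1, spec)   # (1, a, p, ap) = (1, 2, -1, -2)
#' @export
basis_spec <- function(age_degree = 3, period_degree = 3, table = NULL,
                       age_center = NULL, age_scale = NULL,
                       period_center = NULL, period_scale = NULL) {
  for (d in c(age_degree, period_degree)) {
    if (length(d) != 1 || !is.finite(d) || d < 0 || d != round(d)) {
      stop("polynomial degrees must be non-negative integers")
    }
  }
  if (!is.null(table)) {
    stopifnot(inherits(table, "age_period_table"))
    age_center <- age_center %||% mean(table$age)
    age_scale <- age_scale %||% stats::sd(table$age)
    period_center <- period_center %||% mean(table$period)
    period_scale <- period_scale %||% stats::sd(table$period)
  }
  age_center <- age_center %||% 0
  age_scale <- age_scale %||% 1
  period_center <- period_center %||% 0
  period_scale <- period_scale %||% 1
  consts <- c(age_center, age_scale, period_center, period_scale)
  if (any(!is.finite(consts))) stop("scaling constants must be finite")
  if (age_scale == 0 || period_scale == 0) {
    stop("scale factors must be nonzero (degenerate age or period spread)")
  }
  structure(
    list(age_degree = as.integer(age_degree),
         period_degree = as.integer(period_degree),
         age_center = age_center, age_scale = age_scale,
         period_center = period_center, period_scale = period_scale),
    class = "basis_spec")
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf(
    "Polynomial basis: age degree %d x period degree %d (%d terms)\n",
    x$age_degree, x$period_degree, basis_dim(x)))
  cat(sprintf("  age standardized as (a - %.4g)/%.4g, period as (p - %.4g)/%.4g\n",
              x$age_center, x$age_scale, x$period_center, x$period_scale))
  invisible(x)
}

#' Basis dimension m
#' @param spec a [basis_spec].
#' @return Integer `(age_degree + 1) * (period_degree + 1)`.
#' @export
basis_dim <- function(spec) {
  (spec$age_degree + 1L) * (spec$period_degree + 1L)
}

#' Term names, ordered as the design columns: for each period power j
#' (outermost) and age power i, the term a^i p^j.
#' @noRd
basis_term_names <- function(spec) {
  nm <- character(0)
  for (j in 0:spec$period_degree) {
    for (i in 0:spec$age_degree) {
      if (i == 0 && j == 0) {
        nm <- c(nm, "(Intercept)")
      } else {
        a_part <- if (i == 0) "" else if (i == 1) "a" else paste0("a", i)
        p_part <- if (j == 0) "" else if (j == 1) "p" else paste0("p", j)
        nm <- c(nm, paste0(a_part, p_part))
      }
    }
  }
  nm
}

#' Gaussian cohort bump
#'
#' The pair (mu, sigma) defining the Gaussian basis on the birth-cohort
#' diagonal: its value at a cell is the normal density with mean `mu` and
#' standard deviation `sigma` evaluated at the cell's birth year
#' `period - age`. `mu` is the center of the affected cohort and `sigma` its
#' width, both in calendar years.
#'
#' @param mu center birth year.
#' @param sigma width in years; must be positive.
#' @return An object of class `cohort_bump`.
#' @export
cohort_bump <- function(mu, sigma) {
  if (length(mu) != 1 || !is.finite(mu)) stop("mu must be a finite birth year")
  if (length(sigma) != 1 || !is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive width in years")
  }
  structure(list(mu = mu, sigma = sigma), class = "cohort_bump")
}

#' @export
print.cohort_bump <- function(x, ...) {
  cat(sprintf("Cohort bump: center %g, width %g years\n", x$mu, x$sigma))
  invisible(x)
}

#' Evaluate one polynomial basis row
#'
#' Returns the vector `(a~^i * p~^j)` over `i = 0..age_degree` (inner index)
#' and `j = 0..period_degree` (outer index), where `a~`, `p~` are the
#' standardized age and period. The first element is always 1 and the order
#' for the cubic case is (1, a, a2, a3, p, ap, a2p, a3p, p2, ..., a3p3).
#'
#' @param a age (years), scalar.
#' @param p period (calendar year), scalar.
#' @param spec a [basis_spec].
#' @return Named numeric vector of length `basis_dim(spec)`.
#' @export
polynomial_row <- function(a, p, spec) {
  stopifnot(inherits(spec, "basis_spec"))
  if (length(a) != 1 || length(p) != 1 || !is.finite(a) || !is.finite(p)) {
    stop("a and p must be finite scalars")
  }
  drop(polynomial_design(a, p, spec))
}

# Vectorized basis evaluation: n x m matrix for vectors a, p.
polynomial_design <- function(a, p, spec) {
  at <- (a - spec$age_center) / spec$age_scale
  pt <- (p - spec$period_center) / spec$period_scale
  A <- outer(at, 0:spec$age_degree, `^`)
  P <- outer(pt, 0:spec$period_degree, `^`)
  m <- basis_dim(spec)
  X <- matrix(NA_real_, nrow = length(a), ncol = m)
  k <- 0L
  for (j in seq_len(spec$period_degree + 1L)) {
    for (i in seq_len(spec$age_degree + 1L)) {
      k <- k + 1L
      X[, k] <- A[, i] * P[, j]
    }
  }
  colnames(X) <- basis_term_names(spec)
  X
}

#' Gaussian cohort basis value at a cell
#'
#' The normal density with mean `mu` and standard deviation `sigma` evaluated
#' at the cell's birth year `p - a`, in raw calendar years (no
#' standardization, so `mu` and `sigma` are interpretable as years). The
#' maximum over cells is `1/(sigma * sqrt(2*pi))`, attained on the diagonal
#' `p - a = mu`.
#'
#' @param a age (years); vectorized.
#' @param p period (calendar year); vectorized.
#' @param bump a [cohort_bump].
#' @return Numeric vector of non-negative density values.
#' @export
cohort_density <- function(a, p, bump) {
  stopifnot(inherits(bump, "cohort_bump"))
  stats::dnorm(p - a, mean = bump$mu, sd = bump$sigma)
}

#' Design matrix for an age-period table
#'
#' Row j is the polynomial basis row at cell j; when a bump is supplied the
#' Gaussian cohort basis value is appended as the last column (named
#' `"cohort"`), so the coefficient order is (theta..., beta_c).
#'
#' @param table an [age_period_table].
#' @param spec a [basis_spec].
#' @param bump a [cohort_bump], or `NULL` for the polynomial-only design.
#' @return Numeric matrix, n cells by m (or m + 1) columns.
#' @export
design_matrix <- function(table, spec, bump = NULL) {
  stopifnot(inherits(table, "age_period_table"), inherits(spec, "basis_spec"))
  if (nrow(table) == 0) stop("empty table")
  X <- polynomial_design(table$age, table$period, spec)
  if (!is.null(bump)) {
    X <- cbind(X, cohort = cohort_density(table$age, table$period, bump))
  }
  X
}
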