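#' Age-period mortality table
#'
#' Constructs a validated age-period table: one row per (age, period) cell
#' holding the observed death count and the person-years of exposure. Ages and
#' periods are the real-valued representative points of their categories
#' (midpoints by convention, e.g. the 5-year age group 40-44 is 42.5). The
#' birth cohort of a cell is `period - age`, the diagonal of the Lexis surface.
#'
#' Cells with zero exposure are dropped with a message (empty strata carry no
#' information under a Poisson model with a person-years offset); negative
#' exposure or negative/non-integer deaths are errors.
#'
#' @param x data frame with numeric columns `age`, `period`, `deaths`,
#'   `person_years`.
#' @param age_width width in years of an age category (default 5).
#' @param period_width width in years of a period category (default 5).
#' @return An object of class `age_period_table` (a data frame with
#'   attributes `age_width` and `period_width`), rows ordered by period then
#'   age.
#' @examples
#' tab <- age_period_table(data.frame(
#'   age = c(42.5, 47.5), period = 1992.5,
#'   deaths = c(10L, 14L), person_years = c(2e5, 1.8e5)
#' ))
#' birth_years(tab)$years
#' @export
age_period_table <- function(x, age_width = 5, period_width = 5) {
  required <- c("age", "period", "deaths", "person_years")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[required]
  for (col in required) {
    if (!is.numeric(x[[col]])) {
      stop("column '", col, "' must be numeric")
    }
    if (anyNA(x[[col]]) || any(!is.finite(x[[col]]))) {
      stop("column '", col, "' contains missing or non-finite values")
    }
  }
  bad <- which(x$deaths < 0 | x$deaths != round(x$deaths))
  if (length(bad) > 0) {
    stop("deaths must be non-negative integers; offending cell(s): ",
         cell_label(x, bad))
  }
  bad <- which(x$person_years < 0)
  if (length(bad) > 0) {
    stop("person_years must be non-negative; offending cell(s): ",
         cell_label(x, bad))
  }
  zero <- x$person_years == 0
  if (any(zero)) {
    message("Dropped ", sum(zero), " cell(s) with zero person-years exposure")
    x <- x[!zero, , drop = FALSE]
  }
  if (nrow(x) == 0) {
    stop("table has no cells with positive exposure")
  }
  if (anyDuplicated(x[c("age", "period")])) {
    dup <- which(duplicated(x[c("age", "period")]))
    stop("duplicated (age, period) cell(s): ", cell_label(x, dup))
  }
  x$deaths <- as.integer(round(x$deaths))
  x <- x[order(x$period, x$age), , drop = FALSE]
  rownames(x) <- NULL
  structure(x,
            age_width = age_width, period_width = period_width,
            class = c("age_period_table", "data.frame"))
}

cell_label <- function(x, idx) {
  paste(sprintf("(age=%g, period=%g)", x$age[idx], x$period[idx]),
        collapse = ", ")
}

#' @export
print.age_period_table <- function(x, ...) {
  cat(sprintf(
    "Age-period table: %d cells, %d age group(s) x %d period(s)\n",
    nrow(x), length(unique(x$age)), length(unique(x$period))))
  cat(sprintf("  ages %g-%g (width %g), periods %g-%g (width %g)\n",
              min(x$age), max(x$age), attr(x, "age_width"),
              min(x$period), max(x$period), attr(x, "period_width")))
  cat(sprintf("  total deaths %d over %.4g person-years\n",
              sum(x$deaths), sum(x$person_years)))
  by <- range(x$period - x$age)
  cat(sprintf("  birth cohorts %g-%g (span %g years)\n",
              by[1], by[2], diff(by)))
  invisible(x)
}

#' Read an age-period table from a delimited text file
#'
#' Reads a long-format CSV/TSV with one row per (age, period) cell. Column
#' names can be remapped through `dialect`. Grouped category labels such as
#' `"40-44"` (or `"85+"`) are converted to representative points according to
#' `label_convention`.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named character vector mapping canonical names to the file's
#'   column names, e.g. `c(deaths = "n_deaths")`. Unmapped canonical names
#'   (`age`, `period`, `deaths`, `person_years`) are looked up verbatim.
#' @param sep field separator; by default `","` unless the file extension is
#'   `.tsv`/`.txt`, then tab.
#' @param label_convention how to convert an interval label `"L-U"` to a
#'   point: `"interval"` (default) treats it as the category `[L, U + 1)` of
#'   integer years and returns `L + width/2` (so `"40-44"` gives 42.5);
#'   `"endpoint"` returns the label midpoint `(L + U)/2` (42.0). Open upper
#'   groups `"L+"` map to `L + width/2` under both conventions.
#' @param age_width,period_width category widths in years; inferred from the
#'   labels or from the spacing of distinct values when `NULL`.
#' @return An [age_period_table].
#' @export
read_age_period_table <- function(path, dialect = NULL, sep = NULL,
                                  label_convention = c("interval", "endpoint"),
                                  age_width = NULL, period_width = NULL) {
  label_convention <- match.arg(label_convention)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("age", "period", "deaths", "person_years")
  cols <- stats::setNames(canonical, canonical)
  if (!is.null(dialect)) cols[names(dialect)] <- dialect
  missing_cols <- cols[!cols %in% names(raw)]
  if (length(missing_cols) > 0) {
    stop("column(s) not found in ", path, ": ",
         paste(sprintf("'%s' (for %s)", missing_cols, names(missing_cols)),
               collapse = ", "))
  }
  out <- data.frame(
    age = raw[[cols[["age"]]]], period = raw[[cols[["period"]]]],
    deaths = raw[[cols[["deaths"]]]],
    person_years = raw[[cols[["person_years"]]]]
  )
  age_parsed <- parse_category_labels(out$age, label_convention)
  period_parsed <- parse_category_labels(out$period, label_convention)
  out$age <- age_parsed$values
  out$period <- period_parsed$values
  age_period_table(
    out,
    age_width = age_width %||% age_parsed$width %||% infer_width(out$age),
    period_width = period_width %||% period_parsed$width %||%
      infer_width(out$period)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# "40-44" / "40–44" / "85+" / plain numbers -> representative points.
parse_category_labels <- function(x, convention) {
  if (is.numeric(x)) return(list(values = x, width = NULL))
  x <- trimws(as.character(x))
  range_re <- "^([0-9]+(\\.[0-9]+)?)\\s*[-–—]\\s*([0-9]+(\\.[0-9]+)?)$"
  open_re <- "^([0-9]+(\\.[0-9]+)?)\\s*\\+$"
  num_re <- "^[0-9]+(\\.[0-9]+)?$"
  is_range <- grepl(range_re, x)
  is_open <- grepl(open_re, x)
  is_num <- grepl(num_re, x)
  bad <- !(is_range | is_open | is_num)
  if (any(bad)) {
    stop("cannot parse category label(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  lower <- upper <- rep(NA_real_, length(x))
  lower[is_range] <- as.numeric(sub(range_re, "\\1", x[is_range]))
  upper[is_range] <- as.numeric(sub(range_re, "\\3", x[is_range]))
  width <- if (any(is_range)) {
    w <- upper[is_range] - lower[is_range] + 1
    stats::median(w)
  } else NULL
  values <- rep(NA_real_, length(x))
  values[is_num] <- as.numeric(x[is_num])
  if (any(is_range)) {
    values[is_range] <- switch(convention,
      interval = lower[is_range] + width / 2,
      endpoint = (lower[is_range] + upper[is_range]) / 2
    )
  }
  if (any(is_open)) {
    lo <- as.numeric(sub(open_re, "\\1", x[is_open]))
    values[is_open] <- lo + (width %||% 5) / 2
  }
  list(values = values, width = width)
}

infer_width <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(1)
  min(diff(u))
}

#' Write an age-period table to CSV
#'
#' The inverse of [read_age_period_table()]: writing then re-reading a valid
#' table reproduces its cells exactly (integer deaths bit-exact, real fields
#' via full-precision decimal representation).
#'
#' @param table an [age_period_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_age_period_table <- function(table, path) {
  stopifnot(inherits(table, "age_period_table"))
  df <- as.data.frame(table)
  for (col in c("age", "period", "person_years")) {
    df[[col]] <- format(df[[col]], digits = 17, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide age x period matrix and melt it to long form
#'
#' Convenience reader for matrix-shaped extracts: rows are age groups (first
#' column holds the age labels), remaining columns are periods with the period
#' labels in the header. Returns a long data frame of (age, period, value); if
#' a companion exposure matrix of identical shape is supplied, the two are
#' combined into a validated [age_period_table] with the first matrix read as
#' death counts.
#'
#' @param path path to the value (e.g. deaths or rate) matrix CSV.
#' @param exposure_path optional path to a person-years matrix of the same
#'   shape.
#' @param label_convention see [read_age_period_table()].
#' @return A long data frame `(age, period, value)`, or an
#'   [age_period_table] when `exposure_path` is given.
#' @export
read_age_period_matrix <- function(path, exposure_path = NULL,
                                   label_convention = c("interval", "endpoint")) {
  label_convention <- match.arg(label_convention)
  melt_one <- function(p) {
    m <- utils::read.csv(p, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
    ages <- parse_category_labels(m[[1]], label_convention)$values
    periods <- parse_category_labels(names(m)[-1], label_convention)$values
    vals <- as.matrix(m[, -1, drop = FALSE])
    data.frame(
      age = rep(ages, times = length(periods)),
      period = rep(periods, each = length(ages)),
      value = as.vector(vals)
    )
  }
  long <- melt_one(path)
  if (is.null(exposure_path)) return(long)
  expo <- melt_one(exposure_path)
  if (!identical(dim(long), dim(expo))) {
    stop("value and exposure matrices have different shapes")
  }
  age_period_table(data.frame(
    age = long$age, period = long$period,
    deaths = long$value, person_years = expo$value
  ))
}

#' Birth years represented in a table
#'
#' Each cell lies on the birth-cohort diagonal `c = period - age`. Returns the
#' distinct birth years, their range, and the span `max - min` used by the
#' local-effect classification rule.
#'
#' @param table an [age_period_table].
#' @return List with components `years` (sorted unique birth years), `range`
#'   (length-2 numeric) and `span` (years).
#' @export
birth_years <- function(table) {
  stopifnot(inherits(table, "age_period_table"))
  if (nrow(table) == 0) stop("empty table")
  by <- sort(unique(table$period - table$age))
  list(years = by, range = range(by), span = max(by) - min(by))
}
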