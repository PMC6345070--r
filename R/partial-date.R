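#' Publication dates of variable granularity
#'
#' Publisher portals report publication dates at different precisions: some give
#' a full year-month-day, some only year and month, some only the year. A
#' `partial_date` keeps whatever granularity was delivered instead of inventing
#' missing components. Comparison happens at the coarsest common granularity: a
#' year-only date neither precedes nor follows a fully specified date within the
#' same year, which makes range filtering behave sensibly on mixed-precision
#' input (see [partial_date_overlaps()]).
#'
#' @param year Integer CE year.
#' @param month Optional integer month (1-12).
#' @param day Optional integer day (1-31); only allowed when `month` is given,
#'   and must form a valid calendar date with `year` and `month`.
#'
#' @return An object of class `partial_date`.
#' @examples
#' partial_date(2016)
#' partial_date(2016, 3)
#' partial_date(2016, 2, 29)  # leap day, valid
#' @export
partial_date <- function(year, month = NULL, day = NULL) {
  if (length(year) != 1L || is.na(suppressWarnings(as.integer(year))))
    stop("partial_date: 'year' must be a single integer", call. = FALSE)
  year <- as.integer(year)
  if (!is.null(day) && is.null(month))
    stop("partial_date: 'day' requires 'month'", call. = FALSE)
  if (!is.null(month)) {
    month <- as.integer(month)
    if (is.na(month) || month < 1L || month > 12L)
      stop("partial_date: 'month' must be in 1..12", call. = FALSE)
  }
  if (!is.null(day)) {
    day <- as.integer(day)
    if (is.na(day) || day < 1L || day > 31L)
      stop("partial_date: 'day' must be in 1..31", call. = FALSE)
    # must form a real calendar date when fully specified
    probe <- as.Date(sprintf("%04d-%02d-%02d", year, month, day), format = "%Y-%m-%d")
    if (is.na(probe))
      stop(sprintf("partial_date: %04d-%02d-%02d is not a valid calendar date",
                   year, month, day), call. = FALSE)
  }
  structure(list(year = year, month = month, day = day), class = "partial_date")
}

#' @export
format.partial_date <- function(x, ...) {
  if (!is.null(x$day)) sprintf("%04d-%02d-%02d", x$year, x$month, x$day)
  else if (!is.null(x$month)) sprintf("%04d-%02d", x$year, x$month)
  else sprintf("%04d", x$year)
}

#' @export
print.partial_date <- function(x, ...) {
  cat("<partial_date> ", format(x), "\n", sep = "")
  invisible(x)
}

is_partial_date <- function(x) inherits(x, "partial_date")

#' Parse a partial date from its string form
#'
#' Accepts `"YYYY"`, `"YYYY-MM"` or `"YYYY-MM-DD"`.
#'
#' @param x A string (or `NULL`/`NA`, returning `NULL`).
#' @return A [partial_date()] or `NULL`.
#' @export
parse_partial_date <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x) || !nzchar(x)) return(NULL)
  if (is_partial_date(x)) return(x)
  parts <- strsplit(as.character(x), "-", fixed = TRUE)[[1]]
  if (length(parts) < 1L || length(parts) > 3L)
    stop("parse_partial_date: expected YYYY[-MM[-DD]], got ", x, call. = FALSE)
  do.call(partial_date, as.list(as.integer(parts)))
}

# Numeric bounds of the calendar interval a partial date covers, as yyyymmdd.
partial_date_bounds <- function(x) {
  stopifnot(is_partial_date(x))
  m_lo <- if (is.null(x$month)) 1L else x$month
  m_hi <- if (is.null(x$month)) 12L else x$month
  d_lo <- if (is.null(x$day)) 1L else x$day
  d_hi <- if (is.null(x$day)) 31L else x$day
  c(lo = x$year * 10000 + m_lo * 100 + d_lo,
    hi = x$year * 10000 + m_hi * 100 + d_hi)
}

#' Do two partial dates overlap?
#'
#' Each partial date denotes the calendar interval it covers (a year-only date
#' covers the whole year). Two dates overlap when those intervals intersect;
#' boundaries are inclusive. This is the comparison used for range filters.
#'
#' @param a,b [partial_date()] objects.
#' @return `TRUE` or `FALSE`.
#' @examples
#' partial_date_overlaps(partial_date(2016), partial_date(2016, 6, 1))  # TRUE
#' partial_date_overlaps(partial_date(2015, 6), partial_date(2016))     # FALSE
#' @export
partial_date_overlaps <- function(a, b) {
  ba <- partial_date_bounds(a)
  bb <- partial_date_bounds(b)
  ba["lo"] <= bb["hi"] && bb["lo"] <= ba["hi"]
}

#' Does a partial date fall within a range?
#'
#' The range endpoints are themselves partial dates; a hit is retained when its
#' covered interval intersects the interval spanned from the start of `from` to
#' the end of `to` (overlap semantics, endpoints inclusive).
#'
#' @param x A [partial_date()].
#' @param from,to Range endpoints as [partial_date()]s; either may be `NULL`
#'   for an open end.
#' @return `TRUE` or `FALSE`.
#' @export
partial_date_in_range <- function(x, from = NULL, to = NULL) {
  bx <- partial_date_bounds(x)
  if (!is.null(from) && bx["hi"] < partial_date_bounds(from)["lo"]) return(FALSE)
  if (!is.null(to) && bx["lo"] > partial_date_bounds(to)["hi"]) return(FALSE)
  TRUE
}

# Scalar sort key: earliest covered day, NA-safe (records without a date sort
# first so they are never silently dropped from sorted listings).
partial_date_sort_key <- function(x) {
  if (is.null(x)) return(-Inf)
  unname(partial_date_bounds(x)["lo"])
}

# JSON-facing representations.
partial_date_to_list <- function(x) {
  if (is.null(x)) return(NULL)
  out <- list(year = x$year)
  if (!is.null(x$month)) out$month <- x$month
  if (!is.null(x$day)) out$day <- x$day
  out
}

partial_date_from_list <- function(x) {
  if (is.null(x) || is.null(x$year)) return(NULL)
  partial_date(x$year, x$month, x$day)
}
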