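#' Create a monthly time series
#'
#' The atom of the pipeline: a calendar-indexed series of monthly values for
#' one variable at one location. Missing values (`NA`/`NaN`) are allowed and
#' are propagated by every downstream operator, never silently filled.
#'
#' @param values Numeric vector, one value per month.
#' @param start Integer vector `c(year, month)` of the first value.
#' @param units Free-text units tag (e.g. `"mm"`, `"degC"`, `"index"`).
#' @return An object of class `monthly_series`.
#' @examples
#' pr <- monthly_series(rgamma(120, 2, scale = 40), start = c(1990, 1), units = "mm")
#' calendar_months(pr)[1:14]
#' @export
monthly_series <- function(values, start = c(1982L, 1L), units = "") {
  if (!is.numeric(values) || length(values) < 1L)
    stop("`values` must be a numeric vector of length >= 1")
  start <- as.integer(start)
  if (length(start) != 2L || is.na(start[1]) || start[2] < 1L || start[2] > 12L)
    stop("`start` must be c(year, month) with month in 1..12")
  structure(list(values = as.numeric(values), start = start, units = units),
            class = "monthly_series")
}

#' @export
length.monthly_series <- function(x) length(x$values)

#' Calendar month (1-12) of each entry
#' @param x A `monthly_series`.
#' @return Integer vector of calendar months, same length as the series.
#' @export
calendar_months <- function(x) {
  stopifnot(inherits(x, "monthly_series"))
  ((x$start[2] - 1L + seq_len(length(x$values)) - 1L) %% 12L) + 1L
}

#' Calendar year of each entry
#' @param x A `monthly_series`.
#' @return Integer vector of calendar years.
#' @export
calendar_years <- function(x) {
  stopifnot(inherits(x, "monthly_series"))
  x$start[1] + ((x$start[2] - 1L + seq_len(length(x$values)) - 1L) %/% 12L)
}

#' @export
print.monthly_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<monthly_series> %d months from %d-%02d%s\n", n,
              x$start[1], x$start[2],
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  print(utils::head(x$values, 12))
  invisible(x)
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  data.frame(year = calendar_years(x), month = calendar_months(x),
             value = x$values)
}

#' Read a monthly series from CSV
#'
#' Expects columns `year`, `month`, `value` (or `date` as `YYYY-MM`); rows must
#' be consecutive calendar months.
#'
#' @param path Path to a CSV file.
#' @param units Units tag attached to the result.
#' @return A `monthly_series`.
#' @export
read_monthly_csv <- function(path, units = "") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("date" %in% names(d) && !all(c("year", "month") %in% names(d))) {
    ym <- strsplit(as.character(d$date), "-", fixed = TRUE)
    d$year <- as.integer(vapply(ym, `[`, "", 1L))
    d$month <- as.integer(vapply(ym, `[`, "", 2L))
  }
  if (!all(c("year", "month", "value") %in% names(d)))
    stop("CSV must have columns year, month, value (or date, value)")
  idx <- d$year * 12L + (d$month - 1L)
  if (any(diff(idx) != 1L)) stop("rows are not consecutive calendar months")
  monthly_series(d$value, start = c(d$year[1], d$month[1]), units = units)
}

#' Write a monthly series to CSV
#' @param x A `monthly_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monthly_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
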