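#' Accumulate precipitation over a backward-looking window
#'
#' Value at month *t* is the sum of months *t - scale + 1* through *t*; the
#' first `scale - 1` entries are `NA`. Any missing month inside a window makes
#' that window's sum `NA` (missing data propagate, they are never filled).
#'
#' @param precip A `monthly_series` of precipitation (must be non-negative
#'   where observed).
#' @param scale Accumulation window in months (default 3, the SPI-3 scale).
#' @return A `monthly_series` of accumulated precipitation.
#' @export
spi_accumulate <- function(precip, scale = 3L) {
  stopifnot(inherits(precip, "monthly_series"))
  scale <- as.integer(scale)
  if (scale < 1L) stop("`scale` must be >= 1")
  n <- length(precip$values)
  if (scale > n) stop("`scale` exceeds the series length")
  x <- precip$values
  if (any(x < 0, na.rm = TRUE)) stop("precipitation cannot be negative")
  acc <- as.numeric(stats::filter(x, rep(1, scale), sides = 1))
  monthly_series(acc, start = precip$start, units = precip$units)
}

# Thom's approximation for the gamma MLE; used as a starting point and as a
# fallback when the likelihood optimization fails on near-degenerate samples.
.gamma_thom <- function(x) {
  a <- log(mean(x)) - mean(log(x))
  shape <- if (a <= 0) 100 else (1 + sqrt(1 + 4 * a / 3)) / (4 * a)
  c(shape = shape, scale = mean(x) / shape)
}

.gamma_mle <- function(x) {
  st <- .gamma_thom(x)
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(x, "gamma",
                                    start = list(shape = st[["shape"]],
                                                 rate = 1 / st[["scale"]]),
                                    lower = c(1e-8, 1e-10))),
    error = function(e) NULL)
  if (is.null(fit)) return(st)
  c(shape = unname(fit$estimate["shape"]),
    scale = 1 / unname(fit$estimate["rate"]))
}

#' Fit per-calendar-month gamma parameters for the SPI
#'
#' For each calendar month the zero-precipitation probability `q` is the
#' fraction of zeros among the reference values, and the gamma shape/scale are
#' fitted by maximum likelihood on the strictly positive values (McKee-type
#' mixed distribution). A calendar month whose positive reference values are
#' (numerically) all equal has no usable spread; it is flagged as degenerate
#' with a warning and transforms to `NA`.
#'
#' @param acc Accumulated precipitation (`spi_accumulate` output).
#' @param ref_years Optional integer vector `c(first, last)` restricting the
#'   calibration to a reference period; default is the full record.
#' @return An object of class `spi_params`: a list of 12 elements with
#'   `shape`, `scale`, `q`, `n` and `degenerate`.
#' @export
fit_spi_params <- function(acc, ref_years = NULL) {
  stopifnot(inherits(acc, "monthly_series"))
  mo <- calendar_months(acc)
  yr <- calendar_years(acc)
  keep <- !is.na(acc$values)
  if (!is.null(ref_years)) keep <- keep & yr >= ref_years[1] & yr <= ref_years[2]
  params <- vector("list", 12L)
  for (m in 1:12) {
    x <- acc$values[keep & mo == m]
    if (length(x) < 20L)
      stop(sprintf("calendar month %d has only %d reference values (need >= 20)",
                   m, length(x)))
    if (length(x) < 30L)
      warning(sprintf("calendar month %d has only %d reference values; the fit may be unstable",
                      m, length(x)))
    q <- mean(x == 0)
    pos <- x[x > 0]
    if (length(pos) == 0L)
      stop(sprintf("calendar month %d is all zeros; SPI is undefined", m))
    degenerate <- stats::sd(pos) < 1e-12 * max(abs(pos), 1)
    if (degenerate) {
      warning(sprintf("calendar month %d has zero variance; fit flagged degenerate", m))
      est <- c(shape = NA_real_, scale = NA_real_)
    } else {
      est <- .gamma_mle(pos)
    }
    params[[m]] <- list(shape = unname(est["shape"]), scale = unname(est["scale"]),
                        q = q, n = length(x), degenerate = degenerate)
  }
  structure(params, class = "spi_params", ref_years = ref_years)
}

#' Transform accumulated precipitation to SPI
#'
#' Applies the fitted mixed gamma law month by month:
#' `SPI(t) = qnorm(q + (1 - q) * pgamma(x_t))` for positive totals and
#' `qnorm(q / 2)` (midpoint of the zero mass) for zero totals, then clamps to
#' `[-3.09, 3.09]` to guard against tail extrapolation of the fit. `NA`
#' propagates; degenerate calendar months yield `NA`.
#'
#' @param acc Accumulated precipitation (`spi_accumulate` output).
#' @param params `spi_params` from [fit_spi_params()].
#' @return A `monthly_series` of SPI values (dimensionless).
#' @export
spi_transform <- function(acc, params) {
  stopifnot(inherits(acc, "monthly_series"), inherits(params, "spi_params"))
  if (any(acc$values < 0, na.rm = TRUE)) stop("precipitation cannot be negative")
  mo <- calendar_months(acc)
  out <- rep(NA_real_, length(acc$values))
  for (m in 1:12) {
    p <- params[[m]]
    i <- which(mo == m & !is.na(acc$values))
    if (length(i) == 0L || p$degenerate) next
    x <- acc$values[i]
    u <- ifelse(x == 0, p$q / 2,
                p$q + (1 - p$q) * stats::pgamma(x, shape = p$shape, scale = p$scale))
    out[i] <- pmin(pmax(stats::qnorm(u), -3.09), 3.09)
  }
  monthly_series(out, start = acc$start, units = "SPI")
}

#' Standardized Precipitation Index (SPI)
#'
#' Convenience wrapper: accumulate, fit the per-calendar-month gamma law on the
#' reference period, and transform. SPI-3 (`scale = 3`) is the default working
#' index of the event detector.
#'
#' @inheritParams spi_accumulate
#' @inheritParams fit_spi_params
#' @return A `monthly_series` of SPI values with the fitted `spi_params`
#'   attached as attribute `"params"`.
#' @export
spi <- function(precip, scale = 3L, ref_years = NULL) {
  acc <- spi_accumulate(precip, scale)
  params <- fit_spi_params(acc, ref_years)
  out <- spi_transform(acc, params)
  attr(out, "params") <- params
  out
}

#' Serialize SPI parameters to JSON
#' @param params An `spi_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spi_params <- function(params, path) {
  stopifnot(inherits(params, "spi_params"))
  jsonlite::write_json(lapply(unclass(params), function(p) p[c("shape", "scale", "q", "n")]),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
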