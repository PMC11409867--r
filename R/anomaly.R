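# Seasonal Theil-Sen slope: median of pairwise slopes restricted to pairs of
# the same calendar month, so the seasonal cycle never enters and the
# estimator is exactly equivariant to adding a linear function of time.
# Robust to sparse contamination (an event touching k of n months perturbs
# a minority of the pairs).
.seasonal_theil_sen <- function(t, y, mo) {
  slopes <- unlist(lapply(1:12, function(m) {
    i <- which(mo == m & !is.na(y))
    if (length(i) < 2L) return(numeric(0))
    dy <- outer(y[i], y[i], "-")
    dt <- outer(t[i], t[i], "-")
    up <- upper.tri(dt)
    dy[up] / dt[up]
  }))
  if (!length(slopes)) return(0)
  stats::median(slopes)
}

#' Deseasonalize, detrend and standardize a monthly series
#'
#' Converts a raw vegetation (or climate-factor) series into anomalies in SD
#' units: the per-calendar-month climatological level and a linear trend in
#' time are removed, and the residual is divided by its standard deviation —
#' per calendar month by default (`sd_mode = "monthly"`), so a fixed SD
#' threshold has the same meaning in every season, or one whole-series SD
#' (`sd_mode = "global"`), which preserves the within-year shape of an
#' excursion exactly and is the right choice for strictly noise-free input
#' (where per-month scales would be set by the events themselves).
#'
#' Baseline estimation is robust by default (`method = "robust"`): a seasonal
#' Theil-Sen trend (median of pairwise slopes within each calendar month)
#' followed by per-calendar-month medians. A least-squares baseline
#' absorbs part of any deep, long excursion and leaks a tilted residual of
#' opposite sign into event-free months; the median/Theil-Sen baseline is
#' unmoved by sparse contamination, so a planted excursion appears in the
#' anomalies exactly where (and only where) it was planted. The classical
#' mean/OLS baseline is available via `method = "ols"` (a joint projection on
#' month indicators and time).
#'
#' Removal and rescaling are iterated to their joint fixed point, making the
#' operator idempotent: feeding its output back in changes values by less
#' than the convergence tolerance. Adding any linear function of time to the
#' input leaves the output unchanged. `NA` propagates.
#'
#' Degenerate inputs: a residual that is numerically zero relative to the
#' scale of the input (a pure seasonal cycle plus trend, or — in monthly
#' mode — a calendar month never touched by noise or events) carries no
#' anomaly information and maps to anomaly 0; standardizing it would only
#' amplify floating-point leftovers.
#'
#' @param x A `monthly_series` with at least 10 years of data and at least 8
#'   non-missing values per calendar month.
#' @param sd_mode `"monthly"` (default) or `"global"`.
#' @param method `"robust"` (default) or `"ols"`.
#' @param tol Convergence tolerance of the fixed-point iteration, in SD units.
#' @return An `anomaly_series` (also a `monthly_series`) in SD units, with
#'   the seasonal levels, trend slope and scale(s) of the first pass stored
#'   as attributes.
#' @examples
#' t <- 1:480
#' x <- monthly_series(10 + 2 * cos(2 * pi * t / 12) + 0.001 * t + rnorm(480, 0, 0.5))
#' a <- deseasonalize_detrend(x)
#' round(mean(a$values), 3); round(sd(a$values), 3)
#' @export
deseasonalize_detrend <- function(x, sd_mode = c("monthly", "global"),
                                  method = c("robust", "ols"), tol = 1e-9) {
  stopifnot(inherits(x, "monthly_series"))
  sd_mode <- match.arg(sd_mode)
  method <- match.arg(method)
  v <- x$values
  n <- length(v)
  if (n < 120L) stop("need at least 10 years (120 months) of data")
  mo <- calendar_months(x)
  ok <- !is.na(v)
  per_month_n <- tabulate(mo[ok], nbins = 12L)
  if (any(per_month_n[unique(mo)] < 8L))
    stop("need at least 8 non-missing values per calendar month")
  tt <- seq_len(n)
  eps <- max(1e-10 * stats::sd(v[ok]), 1e-12)
  X <- if (method == "ols")
    cbind(stats::model.matrix(~ 0 + factor(mo, levels = 1:12)), tt)

  finish <- function(r, seasonal, slope, scales) {
    out <- monthly_series(r, start = x$start, units = "SD")
    attr(out, "seasonal_level") <- seasonal
    attr(out, "trend_slope") <- slope
    attr(out, "scale") <- scales
    attr(out, "sd_mode") <- sd_mode
    attr(out, "method") <- method
    class(out) <- c("anomaly_series", class(out))
    out
  }

  r <- v
  seasonal <- NULL; slope <- NULL; scales <- NULL
  for (iter in 1:50) {
    if (method == "ols") {
      fit <- stats::lm.fit(X[ok, , drop = FALSE], r[ok])
      res <- rep(NA_real_, n)
      res[ok] <- fit$residuals
      lev <- unname(fit$coefficients[1:12] + fit$coefficients[13] * mean(tt[ok]))
      b <- unname(fit$coefficients[13])
    } else {
      b <- .seasonal_theil_sen(tt, r, mo)
      r1 <- r - b * tt
      lev0 <- vapply(1:12, function(m) stats::median(r1[ok & mo == m]), 0)
      res <- r1 - lev0[mo]
      lev <- lev0 + b * mean(tt[ok])
    }
    if (iter == 1L) { seasonal <- lev; slope <- b }
    if (stats::sd(res[ok]) < eps)
      return(finish(ifelse(ok, 0, NA_real_), seasonal, slope,
                    if (sd_mode == "monthly") rep(NA_real_, 12) else NA_real_))
    if (sd_mode == "monthly") {
      s <- vapply(1:12, function(m) stats::sd(res[ok & mo == m]), 0)
      s[is.na(s) | s < eps] <- Inf # no-information months map to anomaly 0
      r_new <- res / s[mo]
      s[!is.finite(s)] <- NA_real_
    } else {
      s <- stats::sd(res[ok])
      r_new <- res / s
    }
    if (iter == 1L) scales <- s
    delta <- max(abs(r_new - r)[ok])
    r <- r_new
    if (delta < tol) break
  }
  finish(r, seasonal, slope, scales)
}
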