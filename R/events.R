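#' Detect dry spells from an SPI series
#'
#' A dry spell is a maximal run of consecutive months with SPI strictly below
#' `threshold` lasting at least `min_len` months. A missing SPI value breaks a
#' run (no bridging across gaps).
#'
#' @param spi_series A `monthly_series` of SPI values.
#' @param threshold Dryness threshold (default -1).
#' @param min_len Minimum spell length in months (default 2).
#' @return A data frame with columns `onset` and `end` (month indices into the
#'   series, inclusive); zero rows if no spell qualifies.
#' @examples
#' s <- monthly_series(c(-1.2, -1.5, 0.3, -1.1, -1.3, -1.2))
#' detect_dry_spells(s)
#' @export
detect_dry_spells <- function(spi_series, threshold = -1, min_len = 2L) {
  stopifnot(inherits(spi_series, "monthly_series"))
  v <- spi_series$values
  below <- !is.na(v) & v < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  onsets <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(onset = onsets[keep], end = ends[keep])
}

# 2-consecutive-month temperature means and, for a window starting at month t,
# the 90th percentile of the same calendar month-pair's means across all years.
.pair_means <- function(temp) {
  v <- temp$values
  n <- length(v)
  (v[-n] + v[-1]) / 2
}

#' Hot criterion for a dry spell
#'
#' TRUE iff any 2-consecutive-month window that overlaps the spell by at least
#' one month has a mean temperature strictly above the `pct`-th percentile of
#' that same calendar month-pair's 2-month means across all years of the
#' record. The percentile is relative, so adding a constant to the whole
#' temperature series cannot change the outcome.
#'
#' @param temp A `monthly_series` of temperature covering the spell and the
#'   climatological baseline.
#' @param onset,end Month indices of the spell (inclusive).
#' @param window Length of the hot window in months (default 2).
#' @param pct Percentile threshold (default 90).
#' @return Logical flag.
#' @export
hot_criterion <- function(temp, onset, end, window = 2L, pct = 90) {
  stopifnot(inherits(temp, "monthly_series"), onset >= 1, end >= onset)
  n <- length(temp$values)
  if (end > n) stop("spell runs past the temperature record")
  n_years <- n / 12
  if (n_years < 20) warning("fewer than 20 years of temperature baseline; percentile is noisy")
  v <- temp$values
  mo <- calendar_months(temp)
  starts <- seq.int(max(1L, onset - (window - 1L)), min(end, n - window + 1L))
  for (t in starts) {
    wmean <- mean(v[t:(t + window - 1L)])
    if (is.na(wmean)) next
    same_pair <- which(mo == mo[t] & seq_len(n) <= n - window + 1L)
    base <- vapply(same_pair, function(s) mean(v[s:(s + window - 1L)]), 0)
    thr <- stats::quantile(base, pct / 100, na.rm = TRUE, names = FALSE)
    if (!is.na(thr) && wmean > thr) return(TRUE)
  }
  FALSE
}

#' Vegetation impact filter for a dry spell
#'
#' Searches the window from spell onset to `end + horizon` for the minimum
#' vegetation anomaly. The spell is retained only if that minimum is strictly
#' below `threshold` (default -0.1 SD; -0.5 SD is the standard sensitivity
#' variant). Ties are broken toward the earliest month. If the search window
#' runs past the record end it is truncated and the event is flagged censored.
#'
#' @param anom An `anomaly_series` (SD units).
#' @param onset,end Month indices of the spell.
#' @param threshold Impact threshold in SD units (default -0.1).
#' @param horizon Months past spell end to search for the maximum loss
#'   (default 6; vegetation response lags the precipitation deficit).
#' @return A list with `keep`, `min_anomaly`, `max_loss_month` (index of the
#'   minimum; earliest on ties) and `censored`.
#' @export
impact_filter <- function(anom, onset, end, threshold = -0.1, horizon = 6L) {
  stopifnot(inherits(anom, "monthly_series"), onset >= 1, end >= onset)
  n <- length(anom$values)
  w_end <- end + horizon
  censored <- w_end > n
  w_end <- min(w_end, n)
  w <- anom$values[onset:w_end]
  if (all(is.na(w)))
    return(list(keep = FALSE, min_anomaly = NA_real_,
                max_loss_month = NA_integer_, censored = censored))
  min_anom <- min(w, na.rm = TRUE)
  max_loss_month <- onset + which(w == min_anom)[1] - 1L
  list(keep = min_anom < threshold, min_anomaly = min_anom,
       max_loss_month = max_loss_month, censored = censored)
}

#' Detect and classify drought events
#'
#' Composition of the three event criteria: (i) a dry spell (SPI below the
#' dryness threshold for at least `min_len` months), (ii) the hot criterion
#' (2-month mean temperature above the 90th percentile of the same calendar
#' month-pair, overlapping the spell) deciding hot-dry vs dry, and (iii) the
#' vegetation impact filter (minimum detrended anomaly below
#' `impact_threshold` within the spell-plus-horizon window). Every retained
#' spell is exactly one of `hot_dry` / `dry`.
#'
#' @param spi_series SPI `monthly_series`.
#' @param temp Temperature `monthly_series`, calendar-aligned with `spi_series`.
#' @param anom Vegetation `anomaly_series`, calendar-aligned.
#' @param spi_threshold,min_len Dry-spell criteria (defaults -1, 2).
#' @param hot_window,hot_pct Hot criteria (defaults 2 months, 90th percentile).
#' @param impact_threshold,horizon Impact criteria (defaults -0.1 SD, 6 months).
#' @return A data frame of events: `onset`, `end`, `duration`, `type`
#'   (`"hot_dry"` or `"dry"`), `ds` (drought severity, negated SPI sum),
#'   `min_anomaly`, `max_loss_month`, `censored`.
#' @export
classify_events <- function(spi_series, temp, anom,
                            spi_threshold = -1, min_len = 2L,
                            hot_window = 2L, hot_pct = 90,
                            impact_threshold = -0.1, horizon = 6L) {
  if (length(spi_series) != length(temp) || length(spi_series) != length(anom) ||
      any(spi_series$start != temp$start) || any(spi_series$start != anom$start))
    stop("SPI, temperature and anomaly series must be calendar-aligned")
  spells <- detect_dry_spells(spi_series, spi_threshold, min_len)
  out <- list()
  for (i in seq_len(nrow(spells))) {
    onset <- spells$onset[i]; end <- spells$end[i]
    imp <- impact_filter(anom, onset, end, impact_threshold, horizon)
    if (!imp$keep) next
    hot <- hot_criterion(temp, onset, end, hot_window, hot_pct)
    out[[length(out) + 1L]] <- data.frame(
      onset = onset, end = end, duration = end - onset + 1L,
      type = if (hot) "hot_dry" else "dry",
      ds = drought_severity(spi_series, onset, end),
      min_anomaly = imp$min_anomaly, max_loss_month = imp$max_loss_month,
      censored = imp$censored)
  }
  if (length(out) == 0L)
    return(data.frame(onset = integer(), end = integer(), duration = integer(),
                      type = character(), ds = numeric(), min_anomaly = numeric(),
                      max_loss_month = integer(), censored = logical()))
  do.call(rbind, out)
}
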