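#' Recovery time of one event
#'
#' Months from the month of maximum vegetation loss to the first subsequent
#' month whose anomaly is at or above `normal_level` (0 SD by default — the
#' climatological expectation of a standardized anomaly). The count excludes
#' the max-loss month and includes the crossing month, so an anomaly path of
#' `c(-0.4, -0.2, -0.05, 0.1)` starting at the max-loss month recovers in 3
#' months. The event is censored — recovery time undefined, not clamped — if
#' no crossing occurs within `max_horizon` months, if the record ends first,
#' or if another detected event begins first.
#'
#' @param anom An `anomaly_series` (SD units).
#' @param max_loss_month Month index of the maximum loss.
#' @param normal_level Recovery endpoint in SD units (default 0).
#' @param max_horizon Maximum months searched (default 24).
#' @param later_onsets Optional month indices at which other detected events
#'   begin; reaching one before recovery censors the event.
#' @return A list with `rt` (months, or `NA`), `censored` and `reason`
#'   (`"recovered"`, `"horizon"`, `"record_end"`, `"next_event"`).
#' @export
recovery_time <- function(anom, max_loss_month, normal_level = 0,
                          max_horizon = 24L, later_onsets = integer(0)) {
  stopifnot(inherits(anom, "monthly_series"))
  if (is.na(max_loss_month)) stop("`max_loss_month` is missing")
  n <- length(anom$values)
  later_onsets <- later_onsets[later_onsets > max_loss_month]
  for (k in seq_len(max_horizon)) {
    t <- max_loss_month + k
    if (t > n) return(list(rt = NA_real_, censored = TRUE, reason = "record_end"))
    if (length(later_onsets) && t >= min(later_onsets))
      return(list(rt = NA_real_, censored = TRUE, reason = "next_event"))
    a <- anom$values[t]
    if (!is.na(a) && a >= normal_level)
      return(list(rt = as.numeric(k), censored = FALSE, reason = "recovered"))
  }
  list(rt = NA_real_, censored = TRUE, reason = "horizon")
}

#' Per-pixel mean recovery times and their difference
#'
#' Arithmetic mean recovery time per event type over uncensored events, and
#' `delta_rt = mean RT (hot-dry) - mean RT (dry)`; `NA` when either type has
#' no uncensored event.
#'
#' @param events A data frame with columns `type`, `rt` and `censored` (one
#'   row per event on the pixel).
#' @return A one-row data frame: `rt_hot_dry`, `rt_dry`, `delta_rt`,
#'   `n_hot_dry`, `n_dry`.
#' @export
pixel_delta_rt <- function(events) {
  ok <- !events$censored & !is.na(events$rt)
  hd <- events$rt[ok & events$type == "hot_dry"]
  dr <- events$rt[ok & events$type == "dry"]
  rt_hd <- if (length(hd)) mean(hd) else NA_real_
  rt_dr <- if (length(dr)) mean(dr) else NA_real_
  data.frame(rt_hot_dry = rt_hd, rt_dry = rt_dr,
             delta_rt = rt_hd - rt_dr,
             n_hot_dry = length(hd), n_dry = length(dr))
}

#' Aridity index and dryland classification
#'
#' Aridity index AI = mean annual precipitation / mean annual potential
#' evapotranspiration. Drylands are AI < 0.65 (UNEP convention); the boundary
#' value itself is humid.
#'
#' @param p_mean Mean annual precipitation (same units as `pet_mean`).
#' @param pet_mean Mean annual potential evapotranspiration (> 0).
#' @return A list with `ai` and `class` (`"dryland"` or `"humid"`).
#' @export
aridity_classify <- function(p_mean, pet_mean) {
  if (any(pet_mean <= 0)) stop("potential evapotranspiration must be positive")
  ai <- p_mean / pet_mean
  list(ai = ai, class = ifelse(ai < 0.65, "dryland", "humid"))
}

#' Slope of delta-RT against the aridity index
#'
#' Bins pixels by aridity index, averages delta-RT within each bin, and fits
#' an ordinary-least-squares line of bin-mean delta-RT on bin-center AI.
#'
#' @param ai Aridity index per pixel.
#' @param delta_rt Delta-RT per pixel (months); `NA` rows dropped.
#' @param n_bins Number of equal-width AI bins (default 15).
#' @return A list with `slope`, `intercept`, `bin_centers`, `bin_means`,
#'   `n_bins_used`.
#' @export
rt_vs_aridity_slope <- function(ai, delta_rt, n_bins = 15L) {
  ok <- !is.na(ai) & !is.na(delta_rt)
  if (!any(ok)) stop("all delta-RT values are missing")
  ai <- ai[ok]; delta_rt <- delta_rt[ok]
  breaks <- seq(min(ai), max(ai), length.out = n_bins + 1L)
  if (length(unique(breaks)) < 4L)
    stop("need at least 3 populated aridity bins")
  bin <- cut(ai, breaks, include.lowest = TRUE, labels = FALSE)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  means <- vapply(seq_len(n_bins), function(b) {
    v <- delta_rt[bin == b]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  used <- !is.na(means)
  if (sum(used) < 3L) stop("need at least 3 populated aridity bins")
  fit <- stats::lm(means[used] ~ centers[used])
  list(slope = unname(stats::coef(fit)[2]), intercept = unname(stats::coef(fit)[1]),
       bin_centers = centers[used], bin_means = means[used],
       n_bins_used = sum(used))
}
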