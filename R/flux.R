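# Physical constants shared by the conductance inversion and the synthetic
# forward model (the inversion is the exact algebraic inverse of the forward
# model only if both use the same values).
.flux_const <- list(
  gamma_psy = 0.0662,  # psychrometric constant, kPa K^-1
  rho_air   = 1.204,   # dry-air density at ~20 degC, kg m^-3
  cp_air    = 1010     # specific heat of air, J kg^-1 K^-1
)

#' Half-hourly filters for conductance inversion
#'
#' Standard hygiene for inverting canopy conductance from eddy-covariance
#' records: daytime only (PPFD > 100 umol m-2 s-1), VPD of at least 0.1 kPa
#' (the inversion divides by VPD), and the 24 hours after any rain excluded
#' (wet-canopy evaporation is not transpiration).
#'
#' @param rec Data frame with columns `ppfd`, `vpd`, `precip` and a strictly
#'   increasing `timestamp` (POSIXct) at a fixed step.
#' @return Logical vector of retained rows.
#' @export
flux_filter <- function(rec) {
  ok <- !is.na(rec$ppfd) & rec$ppfd > 100 & !is.na(rec$vpd) & rec$vpd >= 0.1
  rain <- which(!is.na(rec$precip) & rec$precip > 0)
  if (length(rain)) {
    ts <- as.numeric(rec$timestamp)
    wet <- rep(FALSE, nrow(rec))
    for (r in rain) wet <- wet | (ts >= ts[r] & ts < ts[r] + 86400)
    ok <- ok & !wet
  }
  ok
}

#' Canopy conductance from latent heat flux and VPD
#'
#' The well-coupled ("imposed evaporation") inversion
#' `G_c = gamma * LE / (rho * c_p * VPD)` with `LE` in W m-2, `VPD` in kPa and
#' the psychrometric constant `gamma` in kPa K-1, giving `G_c` in m s-1.
#' Aerodynamic decoupling is neglected; the full Penman-Monteith inversion is
#' a straightforward extension hook. Observations are filtered with
#' [flux_filter()] and the daily value is the median over retained
#' observations; days with fewer than `min_obs` retained observations are
#' `NA`.
#'
#' @param rec Half-hourly (or sub-daily) data frame with columns `timestamp`,
#'   `le` (W m-2), `vpd` (kPa), `ppfd`, `precip`.
#' @param min_obs Minimum retained observations per day (default 5).
#' @return Data frame with columns `date`, `gc` (m s-1), `n_obs`.
#' @export
canopy_conductance <- function(rec, min_obs = 5L) {
  k <- .flux_const
  ok <- flux_filter(rec)
  gc_obs <- k$gamma_psy * rec$le / (k$rho_air * k$cp_air * rec$vpd)
  day <- as.Date(rec$timestamp)
  out <- do.call(rbind, lapply(split(seq_along(day), day), function(i) {
    use <- i[ok[i]]
    data.frame(date = day[i[1]],
               gc = if (length(use) >= min_obs) stats::median(gc_obs[use]) else NA_real_,
               n_obs = length(use))
  }))
  rownames(out) <- NULL
  out
}

#' Light-saturated assimilation from a daily light response
#'
#' Nonlinear least-squares fit of the rectangular hyperbola
#' `GPP = alpha * PPFD * A_max / (alpha * PPFD + A_max)` to one day's
#' daytime observations; `A_max` is the light-saturated asymptote (no
#' dark-respiration term: GPP inputs are assumed respiration-partitioned).
#' Non-convergence or a non-positive asymptote returns `NA` with a flag; a
#' flat response (GPP independent of light) fits with a very large `alpha`
#' and is flagged as weak curvature.
#'
#' Estimating the apparent quantum yield and the asymptote jointly from a
#' single day's data leaves `A_max` weakly identified (the two parameters
#' trade off along the saturation shoulder). Because the quantum yield is
#' physiologically conservative from day to day, it can instead be fixed at a
#' value estimated once from the pooled record (`alpha` argument, the default
#' route taken by [daily_physiology()]), which roughly halves the day-to-day
#' scatter of `A_max`.
#'
#' @param ppfd,gpp Numeric vectors for one day (daytime observations).
#' @param min_obs Minimum observations (default 10).
#' @param alpha Optional fixed quantum yield; when `NULL` (default), fitted
#'   jointly with the asymptote.
#' @return List with `amax`, `alpha`, `converged`, `weak_curvature`,
#'   `resid_sd`, `n_obs`.
#' @export
amax_fit <- function(ppfd, gpp, min_obs = 10L, alpha = NULL) {
  ok <- !is.na(ppfd) & !is.na(gpp) & ppfd > 0
  ppfd <- ppfd[ok]; gpp <- gpp[ok]
  fail <- list(amax = NA_real_, alpha = NA_real_, converged = FALSE,
               weak_curvature = NA, resid_sd = NA_real_, n_obs = length(gpp))
  if (length(gpp) < min_obs) return(fail)
  a0 <- max(stats::quantile(gpp, 0.9), 1e-3)
  s0 <- max(stats::median(gpp / ppfd), 1e-5)
  fit <- tryCatch(
    if (is.null(alpha))
      minpack.lm::nlsLM(gpp ~ (alpha * ppfd * amax) / (alpha * ppfd + amax),
                        start = list(alpha = s0, amax = a0),
                        lower = c(1e-8, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(gpp ~ (alpha * ppfd * amax) / (alpha * ppfd + amax),
                        start = list(amax = a0), lower = 1e-6,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  if (!is.null(alpha)) cf[["alpha"]] <- alpha
  if (cf[["amax"]] <= 0) return(fail)
  # alpha*PPFD >> A_max everywhere means the hyperbola degenerates to a
  # constant and the asymptote is weakly identified
  weak <- cf[["alpha"]] * stats::median(ppfd) > 50 * cf[["amax"]]
  list(amax = unname(cf[["amax"]]), alpha = unname(cf[["alpha"]]),
       converged = TRUE, weak_curvature = weak,
       resid_sd = stats::sd(stats::residuals(fit)), n_obs = length(gpp))
}

#' Daily stomatal and non-stomatal physiology
#'
#' Per-day canopy conductance (median of the algebraic inversion) and
#' light-saturated assimilation (per-day light-response fit) from a
#' FLUXNET-style sub-daily record.
#'
#' @param rec Data frame with columns `timestamp`, `gpp`, `le`, `vpd`,
#'   `ppfd`, `precip`.
#' @param min_obs_gc,min_obs_amax Minimum observations per day for each
#'   quantity.
#' @param alpha_mode `"shared"` (default): the quantum yield is estimated
#'   once from the pooled daytime record and held fixed in the per-day
#'   asymptote fits; `"per_day"`: both parameters fitted per day.
#' @return Data frame with `date`, `gc`, `amax`, `n_obs`, `amax_converged`.
#' @export
daily_physiology <- function(rec, min_obs_gc = 5L, min_obs_amax = 10L,
                             alpha_mode = c("shared", "per_day")) {
  alpha_mode <- match.arg(alpha_mode)
  gc_daily <- canopy_conductance(rec, min_obs = min_obs_gc)
  day <- as.Date(rec$timestamp)
  daylight <- !is.na(rec$ppfd) & rec$ppfd > 100
  alpha0 <- NULL
  if (alpha_mode == "shared") {
    pool <- amax_fit(rec$ppfd[daylight], rec$gpp[daylight],
                     min_obs = min_obs_amax)
    if (pool$converged) alpha0 <- pool$alpha
  }
  am <- do.call(rbind, lapply(split(seq_along(day), day), function(i) {
    use <- i[daylight[i]]
    f <- amax_fit(rec$ppfd[use], rec$gpp[use], min_obs = min_obs_amax,
                  alpha = alpha0)
    data.frame(date = day[i[1]], amax = f$amax, amax_converged = f$converged)
  }))
  out <- merge(gc_daily, am, by = "date", all = TRUE)
  out[order(out$date), c("date", "gc", "amax", "n_obs", "amax_converged")]
}

#' Event anomalies of G_c and A_max and the hot-dry / dry ratio
#'
#' Aggregates the daily physiology to monthly means, standardizes each with
#' the same deseasonalize/detrend operator as the vegetation series, averages
#' the anomalies over each event's months, and contrasts event types:
#' `ratio = |mean anomaly, hot-dry| / |mean anomaly, dry|`.
#'
#' @param daily Output of [daily_physiology()] (or an equivalent data frame).
#' @param events Data frame with `type` and month indices `onset`, `end`
#'   referring to the monthly aggregation of `daily`.
#' @param sd_mode Passed to [deseasonalize_detrend()].
#' @return List with per-event anomalies (`events` data frame gains
#'   `gc_anom`, `amax_anom`), group means, and `gc_ratio`, `amax_ratio`.
#' @export
event_anomalies <- function(daily, events, sd_mode = "monthly") {
  mon <- aggregate_monthly(daily)
  gc_a <- deseasonalize_detrend(mon$gc, sd_mode = sd_mode)
  am_a <- deseasonalize_detrend(mon$amax, sd_mode = sd_mode)
  win_mean <- function(a, onset, end) mean(a$values[onset:end], na.rm = TRUE)
  events$gc_anom <- mapply(win_mean, onset = events$onset, end = events$end,
                           MoreArgs = list(a = gc_a))
  events$amax_anom <- mapply(win_mean, onset = events$onset, end = events$end,
                             MoreArgs = list(a = am_a))
  gmean <- function(col, type) {
    v <- events[[col]][events$type == type]
    if (length(v)) mean(v, na.rm = TRUE) else NA_real_
  }
  means <- c(gc_hot_dry = gmean("gc_anom", "hot_dry"),
             gc_dry = gmean("gc_anom", "dry"),
             amax_hot_dry = gmean("amax_anom", "hot_dry"),
             amax_dry = gmean("amax_anom", "dry"))
  list(events = events, means = means,
       gc_ratio = abs(means[["gc_hot_dry"]]) / abs(means[["gc_dry"]]),
       amax_ratio = abs(means[["amax_hot_dry"]]) / abs(means[["amax_dry"]]))
}

#' Aggregate daily physiology to monthly series
#'
#' @param daily Data frame with `date`, `gc`, `amax`.
#' @return List of two `monthly_series` (`gc`, `amax`), means over available
#'   days per month.
#' @export
aggregate_monthly <- function(daily) {
  y <- as.integer(format(daily$date, "%Y"))
  m <- as.integer(format(daily$date, "%m"))
  idx <- y * 12L + (m - 1L)
  rng <- seq(min(idx), max(idx))
  agg <- function(col) {
    v <- vapply(rng, function(i) {
      z <- daily[[col]][idx == i]
      if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
    }, 0)
    monthly_series(v, start = c(min(idx) %/% 12L, (min(idx) %% 12L) + 1L))
  }
  list(gc = agg("gc"), amax = agg("amax"))
}

#' Binned response curves of physiology anomalies to a driver
#'
#' Bins the anomalies by percentile of the driver (VPD or soil moisture) and
#' returns bin centers with mean and standard error per bin for both
#' quantities; empty bins are `NA`.
#'
#' @param driver Numeric driver values (e.g. daily or monthly VPD).
#' @param gc_anom,amax_anom Anomaly values aligned with `driver`.
#' @param n_bins Number of percentile bins (default 10; at least 5 must be
#'   populated).
#' @return Data frame with `bin_center`, `gc_mean`, `gc_se`, `amax_mean`,
#'   `amax_se`, `n`.
#' @export
response_curves <- function(driver, gc_anom, amax_anom, n_bins = 10L) {
  ok <- !is.na(driver)
  breaks <- unique(stats::quantile(driver[ok], seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(driver, breaks, include.lowest = TRUE, labels = FALSE)
  stat <- function(v, b) {
    z <- v[which(bin == b)]
    z <- z[!is.na(z)]
    if (!length(z)) return(c(NA_real_, NA_real_, 0))
    c(mean(z), stats::sd(z) / sqrt(length(z)), length(z))
  }
  rows <- t(vapply(seq_len(length(breaks) - 1L), function(b) {
    c(center = mean(driver[which(bin == b)], na.rm = TRUE),
      g = stat(gc_anom, b), a = stat(amax_anom, b))
  }, numeric(7)))
  out <- data.frame(bin_center = rows[, 1],
                    gc_mean = rows[, 2], gc_se = rows[, 3],
                    amax_mean = rows[, 5], amax_se = rows[, 6],
                    n = rows[, 4])
  if (sum(!is.na(out$gc_mean)) < 5L)
    warning("fewer than 5 populated bins; the response curve is unreliable")
  out
}
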