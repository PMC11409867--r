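#' Flux scenario configuration
#'
#' Daily true values of canopy conductance and light-saturated assimilation
#' plus the diurnal forcing used to forward-simulate half-hourly records. The
#' forward model is the exact algebraic counterpart of the inversion
#' operators: GPP follows the rectangular-hyperbola light response with the
#' day's true `A_max`, and latent heat flux follows
#' `LE = G_c * rho * c_p * VPD / gamma` with the day's true `G_c`.
#'
#' @param n_days Number of simulated days.
#' @param seed Integer seed.
#' @param gc True canopy conductance per day, m s-1 (recycled).
#' @param amax True light-saturated assimilation per day, umol m-2 s-1
#'   (recycled).
#' @param alpha Apparent quantum yield of the light response.
#' @param ppfd_max Midday PPFD, umol m-2 s-1.
#' @param vpd_base,vpd_amp Nighttime VPD floor and diurnal amplitude, kPa.
#' @param noise_sd Multiplicative observation noise fraction on GPP and LE
#'   (0 = noiseless).
#' @param start_date First day.
#' @return A `flux_config` list.
#' @export
flux_config <- function(n_days = 30L, seed = 1L, gc = 0.008, amax = 20,
                        alpha = 0.05, ppfd_max = 1800,
                        vpd_base = 0.3, vpd_amp = 1.2, noise_sd = 0,
                        start_date = as.Date("2001-06-01")) {
  cfg <- as.list(environment())
  if (n_days < 1L) stop("`n_days` must be >= 1")
  if (any(gc <= 0) || any(amax <= 0) || alpha <= 0 || ppfd_max <= 0)
    stop("gc, amax, alpha and ppfd_max must be strictly positive")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  cfg$gc <- rep_len(gc, n_days)
  cfg$amax <- rep_len(amax, n_days)
  structure(cfg, class = "flux_config")
}

#' Forward-simulate half-hourly flux records
#'
#' Half-hourly PPFD is a clipped sinusoid (daylight 06:00-18:00), air
#' temperature and VPD follow smooth diurnal cycles, GPP comes from the
#' rectangular-hyperbola light response with the day's true `A_max`, and LE
#' from the conductance relation with the day's true `G_c`. Optional
#' multiplicative Gaussian noise on GPP and LE. Deterministic given the seed.
#'
#' @param config A `flux_config`.
#' @return A list: `rec` (data frame `timestamp`, `gpp`, `le`, `tair`,
#'   `vpd`, `ppfd`, `precip`) and `truth` (data frame `date`, `gc`, `amax`).
#' @export
gen_flux <- function(config) {
  stopifnot(inherits(config, "flux_config"))
  set.seed((config$seed + 3L) %% .Machine$integer.max)
  k <- .flux_const
  hours <- seq(0, 23.5, by = 0.5)
  nh <- length(hours)
  ppfd_d <- config$ppfd_max * pmax(0, sin(pi * (hours - 6) / 12))
  tair_d <- 18 + 7 * pmax(0, sin(pi * (hours - 7) / 13))
  vpd_d <- config$vpd_base + config$vpd_amp * pmax(0, sin(pi * (hours - 7) / 13))
  rows <- lapply(seq_len(config$n_days), function(d) {
    gpp <- (config$alpha * ppfd_d * config$amax[d]) /
      (config$alpha * ppfd_d + config$amax[d])
    le <- config$gc[d] * k$rho_air * k$cp_air * vpd_d / k$gamma_psy
    if (config$noise_sd > 0) {
      gpp <- gpp * (1 + stats::rnorm(nh, 0, config$noise_sd))
      le <- le * (1 + stats::rnorm(nh, 0, config$noise_sd))
    }
    data.frame(
      timestamp = as.POSIXct(config$start_date + (d - 1L), tz = "UTC") + hours * 3600,
      gpp = gpp, le = le, tair = tair_d, vpd = vpd_d, ppfd = ppfd_d, precip = 0)
  })
  list(rec = do.call(rbind, rows),
       truth = data.frame(date = config$start_date + seq_len(config$n_days) - 1L,
                          gc = config$gc, amax = config$amax))
}

#' Synthetic multi-year daily physiology with planted event suppressions
#'
#' Generates daily canopy-conductance and light-saturated-assimilation series
#' whose anomalies respond linearly (and negatively) to a monthly VPD anomaly
#' — with the conductance twice as sensitive as the assimilation rate by
#' default — plus planted suppressions during hot-dry and dry event windows
#' (hot-dry suppressions twice as deep by default) and daily observation
#' noise. Used to exercise the event-anomaly contrast and the binned response
#' curves with known ground truth.
#'
#' @param seed Integer seed.
#' @param n_years Record length in years.
#' @param n_per_type Number of planted events of each type.
#' @param duration Event length in months.
#' @param gc_suppression,amax_suppression Named vectors `c(hot_dry =, dry =)`
#'   of suppression depths in pre-standardization SD units (negative).
#' @param gc_vpd_sens,amax_vpd_sens Sensitivity of the anomalies to the VPD
#'   anomaly (SD per SD; applied with a negative sign).
#' @param noise_sd Daily observation noise, pre-standardization SD units.
#' @param gc_base,amax_base Baseline levels (m s-1; umol m-2 s-1).
#' @param start_year First calendar year.
#' @return A list: `daily` (date, gc, amax), `events` (type, onset, end in
#'   month indices), `vpd_monthly` (a `monthly_series` of the VPD driver) and
#'   the planted parameters.
#' @export
flux_event_scenario <- function(seed = 1L, n_years = 30L, n_per_type = 15L,
                                duration = 3L,
                                gc_suppression = c(hot_dry = -2, dry = -1),
                                amax_suppression = c(hot_dry = -1.5, dry = -1),
                                gc_vpd_sens = 0.3, amax_vpd_sens = 0.15,
                                noise_sd = 0.15,
                                gc_base = 0.008, amax_base = 20,
                                start_year = 1996L) {
  set.seed((seed + 4L) %% .Machine$integer.max)
  n <- n_years * 12L
  mo <- rep(1:12, n_years)
  vpd_anom <- stats::rnorm(n)
  # non-overlapping event windows in random months
  slots <- seq(13L, n - duration - 12L, by = duration + 6L)
  slots <- slots[sample.int(length(slots))]
  n_ev <- 2L * n_per_type
  if (length(slots) < n_ev) stop("record too short for the requested events")
  onsets <- sort(slots[seq_len(n_ev)])
  types <- sample(rep(c("hot_dry", "dry"), n_per_type))
  events <- data.frame(type = types, onset = onsets, end = onsets + duration - 1L)
  sup_gc <- rep(0, n); sup_am <- rep(0, n)
  for (i in seq_len(n_ev)) {
    w <- events$onset[i]:events$end[i]
    sup_gc[w] <- gc_suppression[[events$type[i]]]
    sup_am[w] <- amax_suppression[[events$type[i]]]
  }
  seas <- 0.3 * cos(2 * pi * (mo - 7) / 12)
  gc_mon <- gc_base * (1 + seas + 0.1 * (-gc_vpd_sens * vpd_anom + sup_gc))
  am_mon <- amax_base * (1 + seas + 0.1 * (-amax_vpd_sens * vpd_anom + sup_am))
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + n_years - 1L)), by = "day")
  midx <- (as.integer(format(dates, "%Y")) - start_year) * 12L +
    as.integer(format(dates, "%m"))
  nd <- length(dates)
  daily <- data.frame(
    date = dates,
    gc = gc_mon[midx] * (1 + 0.1 * noise_sd * stats::rnorm(nd)),
    amax = am_mon[midx] * (1 + 0.1 * noise_sd * stats::rnorm(nd)))
  list(daily = daily, events = events,
       vpd_monthly = monthly_series(1.2 + 0.3 * vpd_anom,
                                    start = c(start_year, 1L), units = "kPa"),
       gc_suppression = gc_suppression, amax_suppression = amax_suppression,
       gc_vpd_sens = gc_vpd_sens, amax_vpd_sens = amax_vpd_sens)
}
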