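# Tetens saturation vapor pressure, kPa, T in degC
.esat <- function(t_c) 0.6108 * exp(17.27 * t_c / (t_c + 237.3))

#' Planted drought events for a synthetic scenario
#'
#' One row per event. `depth` is the maximum-loss depth in anomaly SD units
#' (negative; depths shallower than -0.1 SD will not pass the default impact
#' filter and are allowed precisely to test that exclusion). `rt` is the true
#' recovery time: the planted vegetation excursion first returns to a
#' non-negative anomaly exactly `rt` months after the max-loss month.
#'
#' @param pixel Pixel id (1-based).
#' @param onset Onset month index of the dry window.
#' @param duration Dry-window length in months (>= 2).
#' @param is_hot Logical: plant a co-occurring hot excursion?
#' @param depth Max-loss depth, SD units (< 0).
#' @param months_to_max Months from onset to maximum loss (>= 0).
#' @param rt True recovery time in months (>= 1).
#' @return A validated data frame of planted events.
#' @export
planted_events <- function(pixel, onset, duration, is_hot, depth,
                           months_to_max, rt) {
  ev <- data.frame(pixel = as.integer(pixel), onset = as.integer(onset),
                   duration = as.integer(duration), is_hot = as.logical(is_hot),
                   depth = as.numeric(depth),
                   months_to_max = as.integer(months_to_max), rt = as.integer(rt))
  if (any(ev$duration < 2L)) stop("planted dry windows must last >= 2 months")
  if (any(ev$depth >= 0)) stop("planted depths must be negative (SD units)")
  if (any(ev$months_to_max < 0L)) stop("months_to_max must be >= 0")
  if (any(ev$rt < 1L)) stop("true recovery time must be >= 1 month")
  ev
}

# full footprint of one event, including guard bands
.event_span <- function(ev, guard_before, guard_after) {
  rec_end <- ev$onset + ev$months_to_max + ev$rt
  cbind(lo = ev$onset - guard_before, hi = rec_end + guard_after)
}

#' Synthetic scenario configuration
#'
#' Defines the statistical structure of the synthetic monthly climate and
#' vegetation fields: per-calendar-month gamma precipitation, a seasonal +
#' trend + AR(1) temperature, VPD rising monotonically with temperature via
#' saturation vapor pressure, a single-bucket soil-moisture balance, seasonal
#' shortwave radiation, temperature-driven potential evapotranspiration, and
#' seasonal vegetation with a long-term trend, Gaussian noise and planted
#' drawdown-recovery excursions.
#'
#' Around every planted event a guard band pins precipitation to its
#' per-calendar-month median and keeps temperature noise non-positive for
#' planted non-hot events, so the planted ground truth corresponds one-to-one
#' with what the detector can see; outside guard bands the fields are fully
#' stochastic.
#'
#' @param n_years Record length in years (>= 30; 40 gives stable per-month
#'   gamma fits and percentiles).
#' @param n_pixels Number of independent pixels.
#' @param seed Integer seed; all generation is deterministic given it.
#' @param start_year First calendar year.
#' @param precip_shape,precip_scale Per-calendar-month gamma parameters
#'   (length 12, strictly positive; scale in mm).
#' @param temp_mean,temp_seasonal_amplitude Annual mean and seasonal
#'   amplitude, degC.
#' @param temp_trend Warming trend, degC per decade.
#' @param temp_ar1 AR(1) coefficient of the temperature noise, in [0, 1).
#' @param temp_noise_sd Stationary SD of the temperature noise, degC.
#' @param hot_excursion Additive heat anomaly in planted hot windows, degC.
#' @param drought_factor Multiplier (< 1) on the precipitation gamma scale
#'   inside planted dry windows.
#' @param rh_mean,rh_seasonal_amplitude Relative-humidity seasonality used to
#'   derive VPD from temperature.
#' @param pet_coef PET per unit saturation vapor pressure, mm month-1 kPa-1.
#' @param sm_capacity Soil-moisture bucket capacity, mm.
#' @param srad_mean,srad_seasonal_amplitude,srad_noise_sd Shortwave radiation
#'   parameters, W m-2.
#' @param veg_baseline,veg_seasonal_amplitude Vegetation index level and
#'   seasonal amplitude (index units, LAI-like).
#' @param veg_trend Vegetation trend, index units per decade.
#' @param veg_noise_sd Observation noise SD, index units.
#' @param anomaly_scale Index units per anomaly SD: planted depths are
#'   multiplied by this to convert SD-space excursions into index units.
#' @param events A `planted_events` data frame (or `NULL`).
#' @param hot_only Optional data frame (`pixel`, `onset`, `duration`) of hot
#'   windows without drought, to verify that heat alone is never an event.
#' @param guard_before,guard_after Guard-band extent in months before onset
#'   and after the end of the planted recovery.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(n_years = 40L, n_pixels = 1L, seed = 1L,
                            start_year = 1981L,
                            precip_shape = rep(2, 12),
                            precip_scale = 25 + 10 * cos(2 * pi * ((1:12) - 7) / 12),
                            temp_mean = 15, temp_seasonal_amplitude = 10,
                            temp_trend = 0.3, temp_ar1 = 0.5, temp_noise_sd = 0.5,
                            hot_excursion = 4, drought_factor = 0.05,
                            rh_mean = 0.55, rh_seasonal_amplitude = 0.1,
                            pet_coef = 50, sm_capacity = 150,
                            srad_mean = 180, srad_seasonal_amplitude = 80,
                            srad_noise_sd = 10,
                            veg_baseline = 3, veg_seasonal_amplitude = 1.2,
                            veg_trend = 0.05, veg_noise_sd = 0.05,
                            anomaly_scale = 0.05,
                            events = NULL, hot_only = NULL,
                            guard_before = 9L, guard_after = 8L) {
  cfg <- as.list(environment())
  if (n_years < 30L) stop("`n_years` must be >= 30")
  if (n_pixels < 1L) stop("`n_pixels` must be >= 1")
  if (length(precip_shape) != 12L || length(precip_scale) != 12L ||
      any(precip_shape <= 0) || any(precip_scale <= 0))
    stop("precip_shape/scale must be 12 strictly positive values")
  if (temp_ar1 < 0 || temp_ar1 >= 1) stop("`temp_ar1` must be in [0, 1)")
  if (temp_noise_sd <= 0 || srad_noise_sd <= 0 || anomaly_scale <= 0)
    stop("variance/scale parameters must be strictly positive")
  if (veg_noise_sd < 0) stop("`veg_noise_sd` must be >= 0")
  if (drought_factor <= 0 || drought_factor > 1)
    stop("`drought_factor` must be in (0, 1]")
  n <- n_years * 12L
  if (!is.null(events) && nrow(events)) {
    span <- .event_span(events, guard_before, guard_after)
    if (any(span[, "lo"] < 1L) || any(span[, "hi"] > n))
      stop("a planted event (with guard band) falls outside the record")
    for (px in unique(events$pixel)) {
      s <- span[events$pixel == px, , drop = FALSE]
      s <- s[order(s[, "lo"]), , drop = FALSE]
      if (nrow(s) > 1L && any(s[-1, "lo"] <= s[-nrow(s), "hi"]))
        stop("planted events overlap on pixel ", px)
    }
  }
  structure(cfg, class = "scenario_config")
}

# months covered by a planted dry window
.dry_months <- function(ev) seq.int(ev$onset, ev$onset + ev$duration - 1L)

#' Generate synthetic monthly climate fields
#'
#' Draws, per pixel: gamma precipitation (scale multiplied by
#' `drought_factor` inside planted dry windows; pinned to the monthly median
#' inside guard bands), seasonal + trend + AR(1) temperature (a
#' `hot_excursion` added over planted hot windows; noise clipped to
#' non-positive around planted non-hot windows), VPD from saturation vapor
#' pressure and seasonal relative humidity (monotone in temperature), PET
#' proportional to saturation vapor pressure, shortwave radiation, and a
#' single-bucket soil-moisture balance (carryover + precipitation minus
#' PET-limited loss, clamped to [0, capacity]). Deterministic given the seed.
#'
#' @param config A `scenario_config`.
#' @return A `climate_fields` list of matrices (months x pixels): `precip`,
#'   `temp`, `vpd`, `sm`, `srad`, `pet`, with the start date and config
#'   attached.
#' @export
gen_climate <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed %% .Machine$integer.max)
  n <- config$n_years * 12L
  npx <- config$n_pixels
  mo <- rep(1:12, config$n_years)
  tt <- seq_len(n)
  seas_t <- config$temp_mean +
    config$temp_seasonal_amplitude * cos(2 * pi * (mo - 7) / 12)
  trend_t <- config$temp_trend / 120 * (tt - 1)
  rh <- pmin(pmax(config$rh_mean +
                    config$rh_seasonal_amplitude * cos(2 * pi * (mo - 1) / 12),
                  0.05), 0.95)
  seas_srad <- config$srad_mean +
    config$srad_seasonal_amplitude * cos(2 * pi * (mo - 6.5) / 12)
  med_p <- stats::qgamma(0.5, shape = config$precip_shape,
                         scale = config$precip_scale)

  mats <- lapply(1:6, function(i) matrix(NA_real_, n, npx))
  names(mats) <- c("precip", "temp", "vpd", "sm", "srad", "pet")
  innov_sd <- config$temp_noise_sd * sqrt(1 - config$temp_ar1^2)

  for (px in seq_len(npx)) {
    ev <- config$events[config$events$pixel == px, , drop = FALSE]
    ho <- config$hot_only[config$hot_only$pixel == px, , drop = FALSE]

    # precipitation
    u <- stats::runif(n)
    scale_eff <- config$precip_scale[mo]
    guard <- rep(FALSE, n)
    suppressed <- rep(FALSE, n)
    if (!is.null(ev) && nrow(ev)) {
      span <- .event_span(ev, config$guard_before, config$guard_after)
      for (i in seq_len(nrow(ev))) {
        guard[span[i, "lo"]:span[i, "hi"]] <- TRUE
        suppressed[.dry_months(ev[i, ])] <- TRUE
      }
    }
    scale_eff[suppressed] <- scale_eff[suppressed] * config$drought_factor
    p <- stats::qgamma(u, shape = config$precip_shape[mo], scale = scale_eff)
    p[guard & !suppressed] <- med_p[mo[guard & !suppressed]]
    mats$precip[, px] <- p

    # temperature
    e <- stats::rnorm(n, 0, innov_sd)
    for (t in 2:n) e[t] <- config$temp_ar1 * e[t - 1] + e[t]
    exc <- rep(0, n)
    if (!is.null(ev) && nrow(ev)) {
      for (i in seq_len(nrow(ev))) {
        w_hot <- seq.int(ev$onset[i], min(n, ev$onset[i] + ev$duration[i] + 1L))
        if (ev$is_hot[i]) {
          exc[w_hot] <- exc[w_hot] + config$hot_excursion
        } else {
          w_cool <- seq.int(max(1L, ev$onset[i] - 2L),
                            min(n, ev$onset[i] + ev$duration[i] + 3L))
          e[w_cool] <- pmin(e[w_cool], 0)
        }
      }
    }
    if (!is.null(ho) && nrow(ho)) {
      for (i in seq_len(nrow(ho))) {
        w <- seq.int(ho$onset[i], min(n, ho$onset[i] + ho$duration[i] - 1L))
        exc[w] <- exc[w] + config$hot_excursion
      }
    }
    tem <- seas_t + trend_t + e + exc
    mats$temp[, px] <- tem

    mats$vpd[, px] <- .esat(tem) * (1 - rh)
    pet <- config$pet_coef * .esat(tem)
    mats$pet[, px] <- pet
    mats$srad[, px] <- seas_srad + stats::rnorm(n, 0, config$srad_noise_sd)

    sm <- numeric(n)
    prev <- config$sm_capacity / 2
    for (t in seq_len(n)) {
      avail <- prev + p[t]
      loss <- min(pet[t], avail)
      sm[t] <- min(max(avail - loss, 0), config$sm_capacity)
      prev <- sm[t]
    }
    mats$sm[, px] <- sm
  }
  structure(mats, class = "climate_fields",
            start = c(config$start_year, 1L), config = config)
}

#' Extract one pixel of one climate field as a monthly series
#'
#' @param climate A `climate_fields` object.
#' @param var One of `"precip"`, `"temp"`, `"vpd"`, `"sm"`, `"srad"`, `"pet"`.
#' @param pixel Pixel index.
#' @return A `monthly_series`.
#' @export
field_series <- function(climate, var, pixel = 1L) {
  stopifnot(inherits(climate, "climate_fields"), var %in% names(climate))
  units <- c(precip = "mm", temp = "degC", vpd = "kPa", sm = "mm",
             srad = "W m-2", pet = "mm")[[var]]
  monthly_series(climate[[var]][, pixel], start = attr(climate, "start"),
                 units = units)
}

# planted excursion trajectory in SD units: linear drawdown from 0 at onset to
# `depth` at the max-loss month, fast-then-slow recovery that first reaches a
# non-negative value exactly `rt` months after max loss (with a margin of
# 0.2|depth| on both sides of the crossing), then a brief regrowth overshoot
# decaying to zero
.excursion <- function(n, onset, months_to_max, rt, depth) {
  exc <- rep(0, n)
  m_max <- onset + months_to_max
  if (months_to_max > 0)
    for (j in seq_len(months_to_max))
      exc[onset + j] <- depth * j / months_to_max
  else
    exc[onset] <- depth
  if (rt == 1L) {
    rec <- -0.2 * depth
  } else if (rt == 2L) {
    rec <- c(0.2 * depth, -0.2 * depth)
  } else {
    mid <- seq(0.55, 0.2, length.out = rt - 1L) * depth
    rec <- c(mid, -0.2 * depth)
  }
  rec <- c(rec, -0.1 * depth) # one month of decaying overshoot
  idx <- m_max + seq_along(rec)
  keep <- idx <= n
  exc[idx[keep]] <- rec[keep]
  exc
}

#' Generate synthetic vegetation with planted events and ground truth
#'
#' Vegetation = seasonal cycle + linear trend + Gaussian observation noise +
#' planted event excursions. Excursions are built in anomaly (SD) space and
#' rescaled into index units by `anomaly_scale`, so planted depths are exact
#' in the units of the detection threshold. Each excursion draws down linearly
#' from zero at onset to `depth` at the max-loss month, recovers quickly at
#' first and more slowly near the end, and first reaches a non-negative
#' anomaly exactly `rt` months after the max-loss month (followed by a brief
#' regrowth overshoot decaying to zero).
#'
#' @param climate Output of [gen_climate()] with the same config.
#' @param config The same `scenario_config`.
#' @return A list: `veg` (months x pixels matrix), `truth` (one row per
#'   planted event: `pixel`, `onset`, `duration`, `is_hot`, `type`, `depth`,
#'   `max_loss_month`, `rt`), and `start`.
#' @export
gen_vegetation <- function(climate, config) {
  stopifnot(inherits(climate, "climate_fields"), inherits(config, "scenario_config"))
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  n <- config$n_years * 12L
  npx <- config$n_pixels
  mo <- rep(1:12, config$n_years)
  tt <- seq_len(n)
  base <- config$veg_baseline +
    config$veg_seasonal_amplitude * cos(2 * pi * (mo - 7) / 12) +
    config$veg_trend / 120 * (tt - 1)
  veg <- matrix(NA_real_, n, npx)
  for (px in seq_len(npx)) {
    x <- base + stats::rnorm(n, 0, config$veg_noise_sd)
    ev <- config$events[config$events$pixel == px, , drop = FALSE]
    if (!is.null(ev) && nrow(ev))
      for (i in seq_len(nrow(ev)))
        x <- x + config$anomaly_scale *
          .excursion(n, ev$onset[i], ev$months_to_max[i], ev$rt[i], ev$depth[i])
    veg[, px] <- x
  }
  truth <- config$events
  if (!is.null(truth) && nrow(truth)) {
    truth$type <- ifelse(truth$is_hot, "hot_dry", "dry")
    truth$max_loss_month <- truth$onset + truth$months_to_max
    truth <- truth[, c("pixel", "onset", "duration", "is_hot", "type",
                       "depth", "max_loss_month", "rt")]
  } else {
    truth <- data.frame(pixel = integer(), onset = integer(), duration = integer(),
                        is_hot = logical(), type = character(), depth = numeric(),
                        max_loss_month = integer(), rt = integer())
  }
  list(veg = veg, truth = truth, start = attr(climate, "start"))
}

#' Default study scenario
#'
#' 200 pixels, 40 years. Fifty pixels carry one hot-dry and one dry event
#' each (order randomized), so 50 planted events of each type; the remaining
#' pixels are event-free and exercise the false-alarm behavior of the
#' detector. Planted true recovery times average 5.4 months (hot-dry) and 4.2
#' months (dry); hot-dry events are deeper than dry events, so the planted
#' vegetation-loss difference is positive.
#'
#' @param seed Integer seed.
#' @param n_pixels,n_years Scenario size.
#' @param n_event_pixels Number of pixels carrying one event of each type.
#' @param rt_hot_dry,rt_dry True recovery times to allocate across event
#'   pixels (recycled/shuffled; defaults average 5.4 and 4.2 months).
#' @param depth_hot_dry,depth_dry Planted depths, SD units.
#' @param duration Dry-window length, months.
#' @param months_to_max Months from onset to maximum loss.
#' @param veg_noise_sd Vegetation observation noise, index units.
#' @param ... Further arguments passed to [scenario_config()].
#' @return A `scenario_config`.
#' @export
default_scenario <- function(seed = 1L, n_pixels = 200L, n_years = 40L,
                             n_event_pixels = 50L,
                             rt_hot_dry = c(rep(5L, 30L), rep(6L, 20L)),
                             rt_dry = c(rep(4L, 40L), rep(5L, 10L)),
                             depth_hot_dry = -12, depth_dry = -9,
                             duration = 4L, months_to_max = 2L,
                             veg_noise_sd = 0.05, ...) {
  if (n_event_pixels > n_pixels)
    stop("`n_event_pixels` cannot exceed `n_pixels`")
  set.seed((seed + 2L) %% .Machine$integer.max)
  px <- sample(n_pixels, n_event_pixels)
  shuffle <- function(x) x[sample.int(length(x))] # length-1 safe
  rt_hd <- shuffle(rep_len(rt_hot_dry, n_event_pixels))
  rt_dr <- shuffle(rep_len(rt_dry, n_event_pixels))
  onset1 <- (sample(5:14, n_event_pixels, replace = TRUE)) * 12L +
    sample(1:12, n_event_pixels, replace = TRUE)
  onset2 <- (sample(21:30, n_event_pixels, replace = TRUE)) * 12L +
    sample(1:12, n_event_pixels, replace = TRUE)
  hot_first <- sample(c(TRUE, FALSE), n_event_pixels, replace = TRUE)
  ev <- rbind(
    planted_events(pixel = px, onset = ifelse(hot_first, onset1, onset2),
                   duration = duration, is_hot = TRUE, depth = depth_hot_dry,
                   months_to_max = months_to_max, rt = rt_hd),
    planted_events(pixel = px, onset = ifelse(hot_first, onset2, onset1),
                   duration = duration, is_hot = FALSE, depth = depth_dry,
                   months_to_max = months_to_max, rt = rt_dr))
  scenario_config(n_years = n_years, n_pixels = n_pixels, seed = seed,
                  veg_noise_sd = veg_noise_sd, events = ev, ...)
}

#' Match detected events to planted ground truth
#'
#' A detected event matches a planted event when it is on the same pixel and
#' its SPI spell overlaps the planted dry window (allowing the one-month
#' smearing of the accumulation window). Used to score detection and
#' recovery-time estimates against the truth table.
#'
#' @param events Detected events with columns `pixel`, `onset`, `end`.
#' @param truth Truth table from [gen_vegetation()].
#' @return Integer vector, one entry per truth row: the matching row index in
#'   `events`, or `NA` if unmatched (or ambiguous).
#' @export
match_events <- function(events, truth) {
  same_pixel <- function(i) {
    if ("pixel" %in% names(events)) events$pixel == truth$pixel[i]
    else rep(TRUE, nrow(events)) # single-pixel event table
  }
  vapply(seq_len(nrow(truth)), function(i) {
    j <- which(same_pixel(i) &
                 events$onset <= truth$onset[i] + truth$duration[i] &
                 events$end >= truth$onset[i])
    if (length(j) == 1L) j else NA_integer_
  }, 1L)
}
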