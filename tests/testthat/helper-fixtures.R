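# Shared fixture builders: everything is generated in code at test time.

# monthly series of seasonal + trend + noise
mk_series <- function(n = 480, noise_sd = 0.5, trend = 0.002, seed = 1,
                      amp = 2, level = 10) {
  set.seed(seed)
  t <- seq_len(n)
  monthly_series(level + amp * cos(2 * pi * t / 12) + trend * t +
                   rnorm(n, 0, noise_sd))
}

# stationary per-calendar-month gamma precipitation
mk_precip <- function(n_years = 40, shape = 2, scale = 40, seed = 1) {
  set.seed(seed)
  monthly_series(rgamma(n_years * 12, shape, scale = scale),
                 start = c(1981, 1), units = "mm")
}

# factor table with a planted dominant driver (or pure noise)
mk_factor_table <- function(seed, n = 500, planted = TRUE) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * 7), n, 7))
  names(d) <- c("d_vpd", "d_ds", "d_loss", "d_sm", "d_pre", "d_srad", "d_tem")
  d$delta_rt <- if (planted) 3 * d$d_vpd + 0.3 * rnorm(n) else rnorm(n)
  class(d) <- c("factor_table", class(d))
  d
}

# one-pixel scenario with a single planted event
mk_one_event_scenario <- function(seed = 42, is_hot = TRUE, depth = -12,
                                  rt = 5, months_to_max = 2, duration = 4,
                                  veg_noise_sd = 0.05, onset = 121, ...) {
  ev <- planted_events(pixel = 1, onset = onset, duration = duration,
                       is_hot = is_hot, depth = depth,
                       months_to_max = months_to_max, rt = rt)
  scenario_config(n_pixels = 1, seed = seed, events = ev,
                  veg_noise_sd = veg_noise_sd, ...)
}

# run detector + recovery for one pixel of a generated scenario
detect_pixel <- function(climate, vegetation, px = 1, sd_mode = "monthly", ...) {
  spi_px <- spi(field_series(climate, "precip", px))
  an <- deseasonalize_detrend(
    monthly_series(vegetation$veg[, px], start = vegetation$start),
    sd_mode = sd_mode)
  list(events = classify_events(spi_px, field_series(climate, "temp", px), an, ...),
       anom = an, spi = spi_px)
}
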