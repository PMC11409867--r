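test_that("the conductance inversion is the exact inverse of the forward model", {
  g <- gen_flux(flux_config(n_days = 3, gc = 0.01, amax = 25, noise_sd = 0))
  dp <- daily_physiology(g$rec)
  expect_lt(max(abs(dp$gc - 0.01) / 0.01), 1e-10)
  expect_lt(max(abs(dp$amax - 25)), 1e-6)
  # doubling LE at fixed VPD doubles the conductance
  rec2 <- g$rec
  rec2$le <- rec2$le * 2
  expect_equal(canopy_conductance(rec2)$gc, dp$gc * 2, tolerance = 1e-12)
})

test_that("observation filters drop night, low-VPD and post-rain periods", {
  g <- gen_flux(flux_config(n_days = 2, noise_sd = 0))
  rec <- g$rec
  keep0 <- flux_filter(rec)
  expect_true(all(rec$ppfd[keep0] > 100))
  rec$vpd[rec$vpd < 0.9] <- 0.05
  keep <- flux_filter(rec)
  expect_true(all(rec$vpd[keep] >= 0.1))
  # rain wipes out the following 24 h
  rec2 <- g$rec
  dawn1 <- 11 # 05:00 on day 1, before any daylight observation
  rec2$precip[dawn1] <- 2
  keep2 <- flux_filter(rec2)
  ts <- as.numeric(rec2$timestamp)
  in_shadow <- ts >= ts[dawn1] & ts < ts[dawn1] + 86400
  expect_false(any(keep2[in_shadow]))
  # the washed-out day has too few observations: NA, day still reported
  gc_d <- canopy_conductance(rec2)
  expect_true(is.na(gc_d$gc[1]))
  expect_false(is.na(gc_d$gc[2]))
})

test_that("the light-response fit degrades gracefully on flat input", {
  set.seed(10)
  ppfd <- runif(24, 200, 1800)
  f <- amax_fit(ppfd, rep(8, 24) + rnorm(24, 0, 0.01))
  expect_true(f$converged)
  expect_true(f$weak_curvature)
  expect_lt(abs(f$amax - 8) / 8, 0.15)
  expect_false(amax_fit(ppfd[1:5], rep(8, 5))$converged)
})

test_that("A_max is recovered within 5% RMSE at 10% observation noise", {
  g <- gen_flux(flux_config(n_days = 30, seed = 2, gc = 0.008, amax = 20,
                            noise_sd = 0.10))
  dp <- daily_physiology(g$rec)
  expect_lt(100 * sqrt(mean((dp$amax - 20)^2)) / 20, 5)
  expect_lt(100 * sqrt(mean((dp$gc - 0.008)^2)) / 0.008, 5)
  # unit sanity: conductance positive and physically plausible
  expect_true(all(dp$gc > 0 & dp$gc < 0.1))
})

test_that("event anomalies contrast the types with the planted depth ratio", {
  fs <- flux_event_scenario(seed = 3)
  ea <- event_anomalies(fs$daily, fs$events)
  expect_true(all(ea$means < 0)) # suppressions push both metrics down
  expect_lt(abs(ea$gc_ratio - 2), 0.3)
  expect_gt(ea$gc_ratio, ea$amax_ratio)
  # identical planted distributions give a ratio near one
  fs_eq <- flux_event_scenario(seed = 3,
                               gc_suppression = c(hot_dry = -1.5, dry = -1.5),
                               amax_suppression = c(hot_dry = -1, dry = -1))
  ea_eq <- event_anomalies(fs_eq$daily, fs_eq$events)
  expect_lt(abs(ea_eq$gc_ratio - 1), 0.2)
})

test_that("response curves are steeper for conductance than for assimilation", {
  fs <- flux_event_scenario(seed = 4)
  mon <- aggregate_monthly(fs$daily)
  gca <- deseasonalize_detrend(mon$gc)$values
  ama <- deseasonalize_detrend(mon$amax)$values
  rc <- response_curves(fs$vpd_monthly$values, gca, ama)
  expect_gte(sum(!is.na(rc$gc_mean)), 5)
  s_gc <- stats::coef(stats::lm(gc_mean ~ bin_center, rc))[2]
  s_am <- stats::coef(stats::lm(amax_mean ~ bin_center, rc))[2]
  expect_lt(s_gc, 0)
  expect_gt(abs(s_gc), abs(s_am))
  # constant anomalies give flat curves
  rc_flat <- response_curves(fs$vpd_monthly$values,
                             rep(0.3, length(gca)), rep(-0.2, length(ama)))
  expect_lt(diff(range(rc_flat$gc_mean, na.rm = TRUE)), 1e-10)
})
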