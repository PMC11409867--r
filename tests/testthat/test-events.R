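test_that("dry spells are maximal sub-threshold runs; NA breaks a run", {
  s <- monthly_series(c(-1.2, -1.5, 0.3, -1.1))
  expect_equal(detect_dry_spells(s), data.frame(onset = 1L, end = 2L))
  expect_equal(nrow(detect_dry_spells(monthly_series(c(0, -0.5, 1)))), 0L)
  s2 <- monthly_series(c(-1.2, NA, -1.3, -1.1))
  expect_equal(detect_dry_spells(s2), data.frame(onset = 3L, end = 4L))
  # threshold is strict: exactly -1 is not dry
  expect_equal(nrow(detect_dry_spells(monthly_series(c(-1, -1, -1)))), 0L)
})

test_that("hot criterion requires a window overlapping the spell above the 90th percentile", {
  set.seed(21)
  n <- 480
  mo <- rep(1:12, 40)
  # climatologically average temperatures: pure seasonal cycle, so every
  # 2-month mean equals its month-pair percentile and nothing is strictly hot
  base <- 15 + 10 * cos(2 * pi * (mo - 7) / 12)
  tm <- monthly_series(base)
  expect_false(hot_criterion(tm, 201, 204))
  hot <- base
  hot[200:205] <- hot[200:205] + 4
  tm_hot <- monthly_series(hot)
  expect_true(hot_criterion(tm_hot, 201, 204))
  # heat entirely outside the spell does not count
  expect_false(hot_criterion(tm_hot, 200 - 13, 200 - 10))
  # percentile is relative: a constant shift changes nothing
  expect_true(hot_criterion(monthly_series(hot + 11.3), 201, 204))
  expect_false(hot_criterion(monthly_series(base + 11.3), 201, 204))
  # with realistic noise the planted +4 degC excursion is still decisive
  noisy <- base + rnorm(n, 0, 0.5)
  noisy[200:205] <- noisy[200:205] + 4
  expect_true(hot_criterion(monthly_series(noisy), 201, 204))
  expect_warning(hot_criterion(monthly_series(base[1:180]), 10, 12), "20 years")
})

test_that("impact filter applies the threshold, tie rule and censoring", {
  v <- rep(0, 100)
  v[20:24] <- c(-0.02, -0.05, -0.03, 0, 0)
  a <- monthly_series(v)
  class(a) <- c("anomaly_series", class(a))
  r <- impact_filter(a, 20, 22)
  expect_false(r$keep) # -0.05 is above the -0.1 threshold
  expect_equal(r$min_anomaly, -0.05)
  v[21] <- -0.6
  a$values <- v
  expect_true(impact_filter(a, 20, 22, threshold = -0.5)$keep)
  # ties break to the earliest month
  v[22] <- -0.6
  a$values <- v
  expect_equal(impact_filter(a, 20, 22)$max_loss_month, 21L)
  # window past the record end flags censoring
  expect_true(impact_filter(a, 97, 98)$censored)
})

test_that("classification is an exclusive, exhaustive partition of retained spells", {
  sc <- mk_one_event_scenario(seed = 8, is_hot = TRUE)
  cl <- gen_climate(sc)
  vg <- gen_vegetation(cl, sc)
  d <- detect_pixel(cl, vg)
  expect_true(all(d$events$type %in% c("hot_dry", "dry")))
  m <- match_events(d$events, vg$truth)
  expect_false(any(is.na(m)))
  expect_equal(d$events$type[m], "hot_dry")

  sc2 <- mk_one_event_scenario(seed = 8, is_hot = FALSE, depth = -9)
  cl2 <- gen_climate(sc2)
  vg2 <- gen_vegetation(cl2, sc2)
  d2 <- detect_pixel(cl2, vg2)
  m2 <- match_events(d2$events, vg2$truth)
  expect_equal(d2$events$type[m2], "dry")
})

test_that("a shallow vegetation dip is excluded and heat alone is never an event", {
  # real dry spell, controlled anomaly: a -0.05 SD dip fails criterion iii,
  # a -0.5 SD dip at the same month passes and classifies as dry
  sc <- mk_one_event_scenario(seed = 15, is_hot = FALSE, depth = -8,
                              veg_noise_sd = 0)
  cl <- gen_climate(sc)
  spi1 <- spi(field_series(cl, "precip", 1))
  tm <- field_series(cl, "temp", 1)
  anom <- monthly_series(rep(0, length(spi1)), start = spi1$start, units = "SD")
  anom$values[123] <- -0.05
  expect_equal(nrow(classify_events(spi1, tm, anom)), 0L)
  anom$values[123] <- -0.5
  ev <- classify_events(spi1, tm, anom)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$type, "dry")
  expect_equal(ev$max_loss_month, 123L)
  # hot window with no drought and no impact: no event
  sc2 <- scenario_config(n_pixels = 1, seed = 16, veg_noise_sd = 0,
                         hot_only = data.frame(pixel = 1, onset = 200,
                                               duration = 4))
  cl2 <- gen_climate(sc2)
  vg2 <- gen_vegetation(cl2, sc2)
  d2 <- detect_pixel(cl2, vg2, sd_mode = "global")
  expect_equal(nrow(d2$events), 0L)
})

test_that("tightening the impact threshold never increases the event count", {
  sc <- mk_one_event_scenario(seed = 30, depth = -6)
  cl <- gen_climate(sc)
  vg <- gen_vegetation(cl, sc)
  n_default <- nrow(detect_pixel(cl, vg, impact_threshold = -0.1)$events)
  n_strict <- nrow(detect_pixel(cl, vg, impact_threshold = -0.5)$events)
  expect_lte(n_strict, n_default)
})
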