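test_that("generation is bit-identical under the same config and seed", {
  sc <- mk_one_event_scenario(seed = 12)
  c1 <- gen_climate(sc)
  c2 <- gen_climate(sc)
  expect_identical(c1, c2)
  v1 <- gen_vegetation(c1, sc)
  v2 <- gen_vegetation(c2, sc)
  expect_identical(v1, v2)
  f1 <- gen_flux(flux_config(n_days = 5, seed = 3, noise_sd = 0.1))
  f2 <- gen_flux(flux_config(n_days = 5, seed = 3, noise_sd = 0.1))
  expect_identical(f1, f2)
})

test_that("invalid configurations are rejected", {
  expect_error(scenario_config(n_years = 10), "n_years")
  expect_error(scenario_config(temp_ar1 = 1), "ar1")
  expect_error(scenario_config(precip_shape = rep(-1, 12)), "positive")
  expect_error(scenario_config(drought_factor = 0), "drought_factor")
  expect_error(planted_events(1, 100, 1, TRUE, -5, 2, 5), ">= 2 months")
  expect_error(planted_events(1, 100, 4, TRUE, 0.5, 2, 5), "negative")
  # overlapping events on one pixel are a configuration error
  ev <- rbind(planted_events(1, 120, 4, TRUE, -5, 2, 5),
              planted_events(1, 126, 4, FALSE, -5, 2, 5))
  expect_error(scenario_config(events = ev), "overlap")
  # events (plus guard) must fall inside the record
  expect_error(scenario_config(events = planted_events(1, 3, 4, TRUE, -5, 2, 5)),
               "outside")
})

test_that("bucket soil moisture stays within [0, capacity]", {
  sc <- scenario_config(n_pixels = 3, seed = 5)
  cl <- gen_climate(sc)
  expect_true(all(cl$sm >= 0 & cl$sm <= sc$sm_capacity))
})

test_that("VPD rises monotonically with the planted heat excursion", {
  sc_hot <- mk_one_event_scenario(seed = 9, is_hot = TRUE)
  sc_cold <- mk_one_event_scenario(seed = 9, is_hot = FALSE)
  hot <- gen_climate(sc_hot)
  cold <- gen_climate(sc_cold)
  w <- 121:125
  expect_true(all(hot$vpd[w, 1] > cold$vpd[w, 1]))
  expect_true(all(hot$temp[w, 1] > cold$temp[w, 1]))
})

test_that("a unit drought factor leaves planted windows statistically background", {
  sc <- mk_one_event_scenario(seed = 14, drought_factor = 1, guard_before = 0,
                              guard_after = 0)
  # guard bands suppressed so the window is a plain gamma draw
  cl <- gen_climate(sc)
  w <- 121:124
  mo <- rep(1:12, 40)
  pooled <- unlist(lapply(w, function(t) {
    same <- which(mo == mo[t])
    cl$precip[setdiff(same, w), 1]
  }))
  p <- suppressWarnings(stats::ks.test(cl$precip[w, 1], pooled)$p.value)
  expect_gt(p, 0.01)
})

test_that("the planted excursion first returns to normal exactly at the true RT", {
  for (rt in c(1, 2, 3, 6, 10)) {
    sc <- mk_one_event_scenario(seed = 20, rt = rt, veg_noise_sd = 0,
                                is_hot = FALSE, depth = -8)
    base <- scenario_config(n_pixels = 1, seed = 20, veg_noise_sd = 0)
    cl <- gen_climate(sc)
    exc <- gen_vegetation(cl, sc)$veg[, 1] -
      gen_vegetation(gen_climate(base), base)$veg[, 1]
    m_max <- 121 + 2
    expect_lt(exc[m_max + rt - 1], 0)
    expect_gte(exc[m_max + rt], 0)
    expect_equal(exc[m_max], min(exc))
  }
})

test_that("truth-table events satisfy the detection criteria by construction", {
  sc <- default_scenario(seed = 6, n_pixels = 40, n_event_pixels = 10,
                         veg_noise_sd = 0)
  cl <- gen_climate(sc)
  vg <- gen_vegetation(cl, sc)
  for (px in unique(vg$truth$pixel)) {
    d <- detect_pixel(cl, vg, px, sd_mode = "global")
    m <- match_events(d$events, vg$truth[vg$truth$pixel == px, ])
    expect_false(any(is.na(m)))
    expect_equal(d$events$type[m], vg$truth$type[vg$truth$pixel == px])
  }
})

test_that("background dry spells occur near the chance rate implied by SPI", {
  # no planted events: spells of >= 2 months below -1 arise at the rate set
  # by P(SPI < -1)^2 per month pair, reduced by the 3-month-sum correlation
  sc <- scenario_config(n_pixels = 25, seed = 31)
  cl <- gen_climate(sc)
  frac_dry <- 0
  spell_rate <- 0
  for (px in 1:25) {
    s <- spi(field_series(cl, "precip", px))
    v <- s$values[!is.na(s$values)]
    frac_dry <- frac_dry + mean(v < -1) / 25
    spell_rate <- spell_rate + nrow(detect_dry_spells(s)) / length(v) / 25
  }
  expect_lt(abs(frac_dry - stats::pnorm(-1)), 0.02)
  # between pure independence (0.159^2) and full persistence (0.159)
  expect_gt(spell_rate, stats::pnorm(-1)^2 / 2)
  expect_lt(spell_rate, stats::pnorm(-1) / 2)
})
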