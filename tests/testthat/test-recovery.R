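anom_from <- function(v) monthly_series(v)

test_that("recovery time counts months from max loss to the first crossing", {
  v <- c(rep(0.5, 10), -0.4, -0.2, -0.05, 0.1, rep(0.5, 10))
  expect_equal(recovery_time(anom_from(v), 11)$rt, 3)
  v2 <- c(rep(0.5, 10), -0.4, 0.2, rep(0.5, 10))
  expect_equal(recovery_time(anom_from(v2), 11)$rt, 1)
  expect_error(recovery_time(anom_from(v), NA), "missing")
})

test_that("recovery is censored at the horizon, the record end and the next event", {
  v <- c(rep(0.5, 5), rep(-0.5, 40))
  r <- recovery_time(anom_from(v), 6, max_horizon = 24)
  expect_true(r$censored)
  expect_equal(r$reason, "horizon")
  r2 <- recovery_time(anom_from(v[1:20]), 18)
  expect_equal(r2$reason, "record_end")
  v3 <- c(rep(0.5, 5), rep(-0.5, 10), rep(0.5, 10))
  r3 <- recovery_time(anom_from(v3), 6, later_onsets = 10L)
  expect_equal(r3$reason, "next_event")
  # censoring monotonicity: shrinking the horizon never un-censors
  for (h in c(24, 12, 6, 3)) {
    long <- recovery_time(anom_from(v3), 6, max_horizon = h + 1)
    short <- recovery_time(anom_from(v3), 6, max_horizon = h)
    expect_true(short$censored >= long$censored)
  }
})

test_that("per-pixel means and delta-RT follow the uncensored events", {
  ev <- data.frame(type = c("hot_dry", "hot_dry", "dry"),
                   rt = c(6, 6, 4), censored = FALSE)
  r <- pixel_delta_rt(ev)
  expect_equal(r$delta_rt, 2)
  expect_equal(r$rt_hot_dry, 6)
  only_dry <- pixel_delta_rt(data.frame(type = "dry", rt = 4, censored = FALSE))
  expect_true(is.na(only_dry$delta_rt))
  # censored events never enter the means
  ev2 <- rbind(ev, data.frame(type = "hot_dry", rt = 20, censored = TRUE))
  expect_equal(pixel_delta_rt(ev2)$rt_hot_dry, 6)
})

test_that("aridity classification uses AI = P/PET with the 0.65 dryland bound", {
  expect_equal(aridity_classify(1000, 1000)$class, "humid")
  expect_equal(aridity_classify(650, 1000)$class, "humid") # boundary is humid
  r <- aridity_classify(300, 1000)
  expect_equal(r$ai, 0.3)
  expect_equal(r$class, "dryland")
  expect_error(aridity_classify(300, 0), "positive")
})

test_that("the delta-RT vs aridity regression recovers a planted slope", {
  set.seed(19)
  ai <- runif(2000, 0.1, 1.5)
  drt <- 2.0 - 1.2 * ai + rnorm(2000, 0, 0.3)
  fit <- rt_vs_aridity_slope(ai, drt)
  expect_lt(abs(fit$slope + 1.2), 0.1)
  # constant delta-RT gives slope zero
  flat <- rt_vs_aridity_slope(ai, rep(1.5, 2000))
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_error(rt_vs_aridity_slope(rep(0.5, 100), rnorm(100), n_bins = 1),
               "3 populated")
  expect_error(rt_vs_aridity_slope(ai, rep(NA_real_, 2000)), "missing")
})

test_that("recovery estimates are exact without noise and accurate with noise", {
  # a small population with true RT spanning 3..8 months
  set.seed(33)
  npx <- 30
  ev <- planted_events(pixel = 1:npx, onset = 120 + sample(0:11, npx, TRUE),
                       duration = 4, is_hot = sample(c(TRUE, FALSE), npx, TRUE),
                       depth = -10, months_to_max = 2,
                       rt = sample(3:8, npx, TRUE))
  for (noise in c(0, 0.05)) {
    sc <- scenario_config(n_pixels = npx, seed = 77, events = ev,
                          veg_noise_sd = noise)
    cl <- gen_climate(sc)
    vg <- gen_vegetation(cl, sc)
    errs <- vapply(seq_len(npx), function(px) {
      d <- detect_pixel(cl, vg, px,
                        sd_mode = if (noise == 0) "global" else "monthly")
      m <- match_events(d$events, vg$truth[vg$truth$pixel == px, ])
      rt <- recovery_time(d$anom, d$events$max_loss_month[m])$rt
      rt - vg$truth$rt[vg$truth$pixel == px]
    }, 0)
    if (noise == 0) expect_true(all(errs == 0))
    else expect_lte(mean(abs(errs)), 0.5)
  }
})
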