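test_that("drought severity is the negated SPI sum and grows with duration", {
  s <- monthly_series(c(-1.5, -1.5, -1.2, -1.2))
  expect_equal(drought_severity(s, 1, 2), 3.0)
  expect_gt(drought_severity(s, 1, 4), drought_severity(s, 1, 2))
  expect_equal(vegetation_loss(-0.4), 0.4)
})

test_that("recovery-period anomalies average the post-max-loss window", {
  v <- rep(0, 240)
  a <- monthly_series(v)
  expect_equal(recovery_period_anomaly(a, 100, 5), 0)
  v[101:105] <- 2
  a$values <- v
  expect_equal(recovery_period_anomaly(a, 100, 5), 2)
  expect_equal(recovery_period_anomaly(a, 100, 1), 2) # single-month window
  expect_true(is.na(recovery_period_anomaly(a, 238, 5))) # past record end
})

test_that("importance scores are percentages that sum to 100 and are seeded", {
  tb <- mk_factor_table(1)
  r <- fit_rf_importance(tb, seed = 9)
  expect_equal(sum(r$importance), 100, tolerance = 1e-6)
  expect_true(all(r$importance >= 0))
  r2 <- fit_rf_importance(tb, seed = 9)
  expect_identical(r$importance, r2$importance)
  expect_error(fit_rf_importance(tb[1:20, ]), "50")
  tb$delta_rt <- 1
  expect_error(fit_rf_importance(tb), "constant")
})

test_that("a planted dominant driver is ranked first with most of the importance", {
  for (s in c(2, 5, 12)) {
    r <- fit_rf_importance(mk_factor_table(s), seed = s)
    expect_equal(names(which.max(r$importance)), "d_vpd")
    expect_gt(r$importance[["d_vpd"]], 60)
  }
})

test_that("partial dependence tracks a planted linear effect and is flat for ignored inputs", {
  tb <- mk_factor_table(4, n = 800)
  r <- fit_rf_importance(tb, seed = 4)
  pd <- partial_dependence(r$model, tb, "d_vpd")
  # monotone increasing and with roughly the planted slope of 3
  expect_true(all(diff(pd$pd) > -1e-8))
  slope <- stats::coef(stats::lm(pd ~ grid, pd))[2]
  expect_lt(abs(slope - 3) / 3, 0.35) # forests flatten extremes
  pd_noise <- partial_dependence(r$model, tb, "d_srad")
  expect_lt(diff(range(pd_noise$pd)), 0.15 * diff(range(pd$pd)))
  expect_warning(partial_dependence(r$model, tb, "d_vpd", grid = c(-50, 50)),
                 "outside")
})

test_that("partial correlation controls for the other predictors", {
  set.seed(6)
  n <- 400
  z <- rnorm(n)
  tb <- data.frame(d_vpd = z + rnorm(n, 0, 0.3), d_ds = rnorm(n),
                   d_loss = rnorm(n), d_sm = rnorm(n), d_pre = rnorm(n),
                   d_srad = rnorm(n), d_tem = rnorm(n))
  tb$delta_rt <- 2 * tb$d_vpd - 1 * tb$d_sm + rnorm(n, 0, 0.2)
  r <- partial_correlation(tb, x = "d_sm", y = "delta_rt")
  expect_lt(r$estimate, -0.8)
  expect_lt(r$p_value, 1e-6)
})

test_that("the factor table contrasts hot-dry and dry events per pixel", {
  # two pixels, each with one event of each type; constant factor anomalies
  mk_anom <- function(val) {
    a <- monthly_series(rep(val, 240))
    a
  }
  events <- data.frame(
    pixel = c(1, 1, 2, 2),
    type = c("hot_dry", "dry", "hot_dry", "dry"),
    rt = c(6, 4, 5, 4), censored = FALSE,
    ds = c(5, 3, 6, 3), min_anomaly = c(-0.5, -0.3, -0.6, -0.3),
    max_loss_month = c(50, 150, 60, 160))
  anoms <- list(vpd = list(mk_anom(2), mk_anom(1)),
                sm = list(mk_anom(-1), mk_anom(0)),
                pre = list(mk_anom(0), mk_anom(0)),
                srad = list(mk_anom(0.5), mk_anom(0)),
                tem = list(mk_anom(1), mk_anom(0)))
  tb <- build_factor_table(events, anoms)
  expect_equal(nrow(tb), 2)
  expect_equal(tb$delta_rt, c(2, 1))
  expect_equal(tb$d_ds, c(2, 3))
  expect_equal(tb$d_loss, c(0.2, 0.3))
  expect_equal(tb$d_vpd, c(0, 0)) # constant anomaly cancels in the contrast
})
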