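#' Drought severity of a spell
#'
#' The negated sum of SPI over the spell months, so that larger values mean
#' more severe droughts (every month in a spell has SPI < -1, so the sum is
#' negative and the severity positive).
#'
#' @param spi_series SPI `monthly_series`.
#' @param onset,end Month indices of the spell (inclusive).
#' @return Drought severity (dimensionless, positive).
#' @export
drought_severity <- function(spi_series, onset, end) {
  stopifnot(inherits(spi_series, "monthly_series"), onset >= 1,
            end >= onset, end <= length(spi_series$values))
  -sum(spi_series$values[onset:end])
}

#' Vegetation loss of an event
#'
#' Magnitude of the minimum vegetation anomaly over the event's impact window
#' (SD units).
#'
#' @param min_anomaly Minimum anomaly returned by [impact_filter()].
#' @return `abs(min_anomaly)`.
#' @export
vegetation_loss <- function(min_anomaly) abs(min_anomaly)

#' Mean factor anomaly over an event's recovery period
#'
#' Mean standardized anomaly of a climatic factor (VPD, soil moisture,
#' precipitation, shortwave radiation or temperature) over the months
#' `max_loss_month + 1` through `max_loss_month + rt`. The factor series must
#' be standardized with the same deseasonalize/detrend operator as the
#' vegetation series so that values are comparable across factors and pixels.
#'
#' @param anom Factor `anomaly_series` (SD units).
#' @param max_loss_month Month index of the event's maximum vegetation loss.
#' @param rt Uncensored recovery time in months (>= 1).
#' @return Mean anomaly, or `NA` if the window runs past the record.
#' @export
recovery_period_anomaly <- function(anom, max_loss_month, rt) {
  stopifnot(inherits(anom, "monthly_series"))
  if (is.na(rt) || rt < 1) return(NA_real_)
  n <- length(anom$values)
  w <- (max_loss_month + 1L):(max_loss_month + rt)
  if (max(w) > n) return(NA_real_)
  mean(anom$values[w], na.rm = TRUE)
}

#' Build the per-pixel factor table
#'
#' One row per pixel with both event types: the response `delta_rt` and the
#' seven predictors `d_vpd`, `d_ds`, `d_loss`, `d_sm`, `d_pre`, `d_srad`,
#' `d_tem`. Each delta is (pixel mean over hot-dry events) minus (pixel mean
#' over dry events): recovery-period anomaly differences for the five climatic
#' factors, severity difference for `d_ds`, and vegetation-loss difference for
#' `d_loss`. Rows with a missing response are dropped.
#'
#' @param events A data frame of events across pixels with columns `pixel`,
#'   `type`, `rt`, `censored`, `ds`, `min_anomaly`, `max_loss_month`.
#' @param factor_anoms A named list of lists of `anomaly_series`
#'   (`vpd`, `sm`, `pre`, `srad`, `tem`), each indexed by pixel.
#' @return A `factor_table` data frame.
#' @export
build_factor_table <- function(events, factor_anoms) {
  req <- c("vpd", "sm", "pre", "srad", "tem")
  if (!all(req %in% names(factor_anoms)))
    stop("`factor_anoms` must contain: ", paste(req, collapse = ", "))
  rows <- lapply(unique(events$pixel), function(px) {
    ev <- events[events$pixel == px & !events$censored & !is.na(events$rt), ]
    if (!all(c("hot_dry", "dry") %in% ev$type)) return(NULL)
    grp <- function(type) ev[ev$type == type, , drop = FALSE]
    diff_of <- function(f) mean(f(grp("hot_dry"))) - mean(f(grp("dry")))
    fac <- vapply(req, function(v) {
      a <- factor_anoms[[v]][[px]]
      diff_of(function(g) mapply(recovery_period_anomaly,
                                 max_loss_month = g$max_loss_month, rt = g$rt,
                                 MoreArgs = list(anom = a)))
    }, 0)
    data.frame(pixel = px,
               delta_rt = diff_of(function(g) g$rt),
               d_vpd = fac[["vpd"]],
               d_ds = diff_of(function(g) g$ds),
               d_loss = diff_of(function(g) vegetation_loss(g$min_anomaly)),
               d_sm = fac[["sm"]], d_pre = fac[["pre"]],
               d_srad = fac[["srad"]], d_tem = fac[["tem"]])
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$delta_rt), , drop = FALSE]
  class(out) <- c("factor_table", class(out))
  out
}

.predictor_cols <- c("d_vpd", "d_ds", "d_loss", "d_sm", "d_pre", "d_srad", "d_tem")

#' Random-forest importance of the delta-RT factors
#'
#' Fits a random-forest regression of `delta_rt` on the seven factor
#' differences and reports permutation importance (out-of-bag mean increase in
#' MSE when a predictor is permuted — model-agnostic, unlike impurity
#' importance, which is biased toward high-cardinality features), normalized
#' to percentages summing to 100. Negative raw importances (pure-noise
#' predictors) are floored at zero before normalization.
#'
#' @param table A `factor_table` with at least 50 rows.
#' @param n_trees Number of trees (default 500).
#' @param seed RNG seed; the fit is deterministic given the seed.
#' @return A list with `importance` (named percentages), `raw` (raw
#'   permutation importances) and `model` (the `randomForest` fit).
#' @export
fit_rf_importance <- function(table, n_trees = 500L, seed = 1L) {
  cols <- intersect(.predictor_cols, names(table))
  if (length(cols) < 2L) stop("factor table lacks predictor columns")
  d <- table[stats::complete.cases(table[, c("delta_rt", cols)]), , drop = FALSE]
  if (nrow(d) < 50L) stop("need at least 50 complete rows")
  if (stats::sd(d$delta_rt) < 1e-12) stop("constant response; importance undefined")
  set.seed(seed)
  fit <- randomForest::randomForest(x = d[, cols, drop = FALSE], y = d$delta_rt,
                                    ntree = n_trees, importance = TRUE)
  raw <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  pos <- pmax(raw, 0)
  imp <- if (sum(pos) > 0) 100 * pos / sum(pos) else rep(100 / length(pos), length(pos))
  names(imp) <- cols
  list(importance = imp, raw = raw, model = fit)
}

#' Partial dependence of the model prediction on one predictor
#'
#' `PD(g)` is the mean prediction over all rows with the chosen predictor set
#' to `g` and every other column left untouched.
#'
#' @param model A fitted `randomForest` model (from [fit_rf_importance()]).
#' @param table The `factor_table` the model was fitted on.
#' @param var Predictor name.
#' @param grid Ordered grid of values; default 20 quantile-spaced points over
#'   the observed range. Values outside the observed range trigger a warning
#'   but are still evaluated.
#' @return A data frame with columns `grid` and `pd`.
#' @export
partial_dependence <- function(model, table, var, grid = NULL) {
  if (!var %in% names(table)) stop("unknown predictor: ", var)
  cols <- intersect(.predictor_cols, names(table))
  d <- table[stats::complete.cases(table[, c("delta_rt", cols)]), cols, drop = FALSE]
  obs <- d[[var]]
  if (is.null(grid))
    grid <- unname(stats::quantile(obs, seq(0.05, 0.95, length.out = 20)))
  if (any(grid < min(obs)) || any(grid > max(obs)))
    warning("grid extends outside the observed range of ", var)
  pd <- vapply(grid, function(g) {
    d2 <- d
    d2[[var]] <- g
    mean(stats::predict(model, d2))
  }, 0)
  data.frame(grid = grid, pd = pd)
}

#' Partial Pearson correlation controlling for the remaining predictors
#'
#' Residualizes both `x` and `y` on the control columns by ordinary least
#' squares and correlates the residuals (used for the delta-RT vs delta-SM
#' check alongside the forest importances).
#'
#' @param table A `factor_table`.
#' @param x,y Column names to correlate.
#' @param controls Column names to control for; default all remaining
#'   predictors.
#' @return A list with `estimate` and `p_value`.
#' @export
partial_correlation <- function(table, x = "d_sm", y = "delta_rt",
                                controls = NULL) {
  if (is.null(controls))
    controls <- setdiff(intersect(.predictor_cols, names(table)), x)
  d <- table[stats::complete.cases(table[, c(x, y, controls)]), , drop = FALSE]
  Z <- as.matrix(d[, controls, drop = FALSE])
  rx <- stats::lm.fit(cbind(1, Z), d[[x]])$residuals
  ry <- stats::lm.fit(cbind(1, Z), d[[y]])$residuals
  ct <- stats::cor.test(rx, ry)
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}
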