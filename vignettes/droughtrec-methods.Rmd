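---
title: "Methods: detecting hot-dry and dry events and measuring ecosystem recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting hot-dry and dry events and measuring ecosystem recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtrec)
```

## The question and the quantities

Compound hot-dry events — droughts that co-occur with unusual heat — damage
vegetation more than plain droughts, and ecosystems take longer to regrow
afterwards. This package implements the full measurement chain for that
contrast on monthly climate and vegetation series:

1. **Dryness** is measured by the 3-month Standardized Precipitation Index
   (SPI-3). A *dry spell* is a maximal run of months with SPI below -1
   lasting at least 2 months.
2. A spell is a **hot-dry event** if any two consecutive months overlapping
   it have a mean temperature strictly above the 90th percentile of the same
   calendar month-pair across all years; otherwise it is a **dry event**.
3. A spell only counts as an event at all if it has a **vegetation impact**:
   the detrended, deseasonalized vegetation anomaly drops below -0.1 SD
   within the spell or the following 6 months.
4. **Recovery time (RT)** is the number of months from the month of maximum
   vegetation loss to the first month whose anomaly is back at the normal
   level (0 SD). The per-pixel contrast is
   `delta-RT = mean RT(hot-dry) - mean RT(dry)`.
5. delta-RT is related to the **aridity index** (AI = P/PET; drylands are
   AI < 0.65) by a binned linear regression, and attributed to factor
   differences (`dVPD`, `dDS`, `dloss`, `dSM`, `dPRE`, `dSrad`, `dTEM`) with
   a random-forest regression, permutation importances and partial-dependence
   curves.
6. At flux-tower scale, stomatal limitation is proxied by canopy conductance
   `G_c = gamma * LE / (rho * c_p * VPD)` (the well-coupled inversion of the
   transpiration equation) and non-stomatal limitation by the light-saturated
   assimilation rate `A_max`, the asymptote of the rectangular-hyperbola
   light response `GPP = alpha * PPFD * A_max / (alpha * PPFD + A_max)`.

Because the global satellite and flux archives behind such analyses are not
shippable, every stage is validated against a synthetic generator that plants
events with known type, timing, depth and true recovery time, and the
acceptance script measures how exactly the pipeline recovers that truth.

## The SPI implementation

SPI follows the standard McKee-type construction: accumulate precipitation
over 3 months (configurable), fit a gamma distribution per calendar month by
maximum likelihood on the positive values with a point mass `q` at zero, and
map each total through `qnorm(q + (1 - q) * pgamma(x))`. Zero totals use
`q / 2` — the midpoint of the zero mass — so that dry-season zeros are not
all assigned the wettest point of the zero class. Values are clamped to
±3.09 (the 0.001/0.999 normal quantiles) to guard against tail extrapolation
of a finite-sample fit. The reference period defaults to the full record and
is configurable; MLE starts from Thom's closed-form approximation and falls
back to it if the optimizer fails. By construction SPI is invariant to
rescaling precipitation by any positive constant and is approximately
standard normal over its reference period, so `P(SPI < -1)` is about 0.159.

## The anomaly operator

Vegetation (and each climatic factor used in attribution — one
implementation, several call sites) is converted to SD-unit anomalies by
removing a per-calendar-month climatological level and a linear trend, then
dividing by the residual standard deviation per calendar month. Numerical
choices that matter:

* **Robust baseline by default.** The trend is a *seasonal Theil-Sen* slope
  (median of pairwise slopes within each calendar month) and the
  climatology is the per-month median. A least-squares baseline absorbs part
  of any deep excursion and leaks a tilted residual of opposite sign into
  event-free months (about 0.1-0.2 SD for the default planted depths), which
  both distorts measured depths and creates spurious sub-threshold dips. The
  median/Theil-Sen baseline is unmoved by sparse contamination: an event
  appears in the anomalies exactly where it was planted and nowhere else.
  The classical mean/OLS baseline is retained via `method = "ols"`.
* **Fixed-point iteration.** Removal and rescaling are iterated until they
  stop changing (tolerance 1e-9 SD), which makes the operator idempotent and
  exactly invariant to adding any linear function of time.
* **Degenerate input maps to zero.** A residual that is numerically zero
  relative to the input scale (pure seasonal cycle plus trend; or a calendar
  month untouched by noise in noise-free simulations) carries no anomaly
  information; standardizing it would only amplify floating-point leftovers
  to unit variance. Such residuals are mapped to anomaly 0.
* **SD mode.** Per-calendar-month scaling (`sd_mode = "monthly"`) is the
  default so that the -0.1 SD impact threshold means the same thing in every
  season. For *strictly noise-free* input the per-month scales are set
  entirely by the events themselves (every touched month standardizes to the
  same value, destroying the trajectory shape and the max-loss month), so
  noise-free runs use `sd_mode = "global"`, which rescales with one constant
  and preserves the shape exactly.

## Event detection conventions

All three thresholds are strict inequalities (SPI < -1, 2-month mean
temperature > P90, anomaly < -0.1 SD); ties at a continuous threshold are
measure-zero, and strictness is documented for reproducibility. "The same
period" for the temperature percentile is read as the same calendar
month-pair across years (all Jun-Jul means, say): a whole-record percentile
would make every summer "hot". The hot window must overlap the dry spell by
at least one month. The impact search window extends 6 months past spell end
(configurable), since vegetation response lags the precipitation deficit; a
window truncated by the record end flags the event as censored. A missing
SPI month breaks a run rather than bridging it.

Recovery time counts from the max-loss month (exclusive) to the crossing
month (inclusive): the anomaly path `-0.4, -0.2, -0.05, 0.1` starting at the
max-loss month has RT 3. The normal level defaults to 0 SD — the
climatological expectation of a standardized anomaly — and is configurable
(`normal_level`). Events are censored (excluded from means, never clamped,
which would bias RT downward) when no crossing occurs within 24 months, when
the record ends, or when another detected event begins first. The dryland
boundary AI < 0.65 follows the standard UNEP classification, with the
boundary itself assigned to humid.

## Attribution conventions

Drought severity is the negated SPI sum over the spell, so larger means more
severe. Vegetation loss is the magnitude of the minimum anomaly in the
impact window. Climatic factor contrasts are means over each event's
recovery period (`max_loss + 1 … max_loss + RT`) of the factor's
standardized anomaly, averaged per pixel and differenced hot-dry minus dry,
mirroring delta-RT. The forest uses permutation importance on out-of-bag
predictions rather than impurity importance (which is biased toward
high-cardinality features), floored at zero and normalized to percentages;
partial dependence sweeps one predictor over a quantile grid with all other
columns untouched. A partial Pearson correlation (residual-on-residual)
backs up the forest for the delta-RT vs delta-SM relation. Forest
hyperparameters (500 trees, default mtry) and the seed are explicit
arguments.

## Flux physiology conventions

`G_c` uses the "well-coupled" inversion `gamma * LE / (rho * c_p * VPD)`
with gamma = 0.0662 kPa/K, rho = 1.204 kg/m3, c_p = 1010 J/kg/K — the same
constants the forward simulator uses, so the noise-free round trip is exact
to machine precision. Aerodynamic conductance is neglected (an extension
hook, not a default). Inversion hygiene: daytime only (PPFD > 100
umol/m2/s), VPD at least 0.1 kPa, the 24 h after any rain excluded, daily
value the median over at least 5 retained observations.

`A_max` comes from the rectangular hyperbola without a dark-respiration term
(GPP inputs are assumed respiration-partitioned). The apparent quantum yield
is estimated **once from the pooled record and held fixed in the per-day
asymptote fits** (`alpha_mode = "shared"`): the yield is physiologically
conservative from day to day, and estimating it per day leaves the asymptote
weakly identified — per-day joint fits roughly double the day-to-day scatter
of `A_max` (about 5-6% RMSE versus about 3% at 10% observation noise). The
per-day joint fit remains available (`alpha_mode = "per_day"`). A flat light
response is fitted but flagged as weak curvature.

Event contrasts standardize monthly-aggregated `G_c` and `A_max` with the
same anomaly operator as vegetation and report the ratio of mean
hot-dry to mean dry anomaly magnitudes; response curves bin the anomalies by
driver percentile.

## What the synthetic generator emulates — and what it does not

`gen_climate()`/`gen_vegetation()` produce, per pixel: per-calendar-month
gamma precipitation; temperature as seasonal cycle + 0.3 °C/decade trend +
AR(1) noise (coefficient 0.5, SD 0.5 °C); VPD from saturation vapor pressure
and seasonal relative humidity, hence monotone in temperature; PET
proportional to saturation vapor pressure; a single-bucket soil-moisture
balance clamped to [0, 150 mm]; seasonal shortwave radiation; and an
LAI-like vegetation index (baseline 3, seasonal amplitude 1.2, trend
0.05/decade) with Gaussian observation noise (default 0.05 index units).

Planted events suppress the precipitation gamma scale by a factor 0.05 over
the dry window (so SPI-3 is deep below -1 throughout), add a +4 °C excursion
over planted hot windows (guaranteeing the month-pair percentile exceedance),
and clip temperature noise to non-positive around planted *non-hot* windows
(so a planted dry event cannot be hot by chance — the truth table must
satisfy the definitions by construction). Optional hot-only windows verify
that heat without drought is never an event.

Vegetation excursions are built in anomaly SD space and rescaled by
`anomaly_scale` (0.05 index units per SD, equal to the default noise SD so
planted depths are exact in threshold units). The trajectory draws down
linearly to the planted depth, then recovers **fast-then-slow**, reaching
-0.2 |depth| one month before the true RT and +0.2 |depth| at the true RT,
followed by a one-month decaying overshoot — the anomaly first becomes
non-negative exactly RT months after maximum loss. The margin on both sides
of the crossing is what makes RT estimable to within a fraction of a month
under observation noise; a trajectory that merely touches zero would leave
the crossing month a coin flip at any noise level. Ecologically this is a
post-drought regrowth flush; numerically it is what makes the planted RT a
well-defined, recoverable quantity.

Default depths are -12 SD (hot-dry) and -9 SD (dry) of the *observation
noise* scale — i.e. drawdowns of 0.6 and 0.45 index units against 0.05 noise,
severe but realistic losses for an LAI-like index. In this synthetic world
the only background variability is observation noise, so severe events sit
many noise-SDs deep; the shallow-threshold logic (-0.1 SD) is exercised by
dedicated shallow-dip tests rather than by the default events.

**Guard bands.** Around every planted event (9 months before onset to 8
months after recovery) precipitation is pinned to its per-month median.
Background dry spells still arise everywhere else at the chance rate implied
by SPI < -1 — and are discarded by the impact filter when vegetation is
clean — but no random spell can overlap a planted excursion's impact window.
This is what makes the planted truth correspond one-to-one with what the
detector can see, so detection accuracy and false-event counts are exact,
not statistical, statements.

The default study scenario is 200 pixels x 40 years; 50 pixels carry one
hot-dry and one dry event each (order randomized), with planted true RTs
averaging exactly 5.4 months (hot-dry: thirty 5s, twenty 6s) and 4.2 months
(dry: forty 4s, ten 5s). Pixels are independent: no attempt is made to
reproduce the spatial covariance of real vegetation fields, nor sub-monthly
timing, land-use change, or disturbance agents other than drought and heat.
Passing tests therefore demonstrate correctness of the measurement chain on
data with the assumed statistical structure, not robustness to everything
real satellite records contain.

The flux generator forward-simulates half-hourly PPFD (clipped sinusoid),
diurnal VPD and temperature, GPP from the light response and LE from the
conductance relation, with optional multiplicative noise — the exact forward
model of the inversions. A separate multi-year daily scenario
(`flux_event_scenario()`) plants G_c suppressions twice as deep under
hot-dry as under dry events (-2 vs -1 pre-scale SD) and a VPD sensitivity
twice as steep for G_c as for A_max, to exercise the anomaly-ratio and
response-curve analyses.

## Problem sizes and runtimes

The test suite and the acceptance script run the full 200-pixel, 40-year
scenario twice (noise-free and noisy; roughly 10 and 20 seconds each), 40
random-forest fits of 500 trees on 500-row tables (about half a minute), and
the flux simulations (seconds). These sizes were chosen to give exact
detection counts and sub-0.1-month standard errors on mean RT while keeping
a full run comfortably under two minutes.

## Known limitations

* The anomaly operator assumes a linear long-term trend; curvature in the
  trend will alias into anomalies (harmonic or STL-style decompositions are
  a possible extension, not a default).
* The conductance inversion omits aerodynamic conductance; at poorly coupled
  (smooth, wet) canopies the simple inversion underestimates stomatal
  control.
* Censoring treats an interrupting event as ending observation; if real
  recoveries are systematically interrupted by new droughts, mean RT is
  estimated on the observable (shorter) recoveries.
* The -0.1 SD impact filter passes essentially any dry spell when vegetation
  noise is present (a minimum over a ~10-month window of unit-SD noise is
  almost always below -0.1); on noisy data the detector's value lies in the
  typing and RT measurement of real impacts, and truth-matched scoring is
  the honest way to evaluate it.
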