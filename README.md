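# droughtrec

Ecosystems hit by a **compound hot–dry event** — a drought co-occurring with
unusual heat — lose more canopy than ecosystems hit by a plain drought, and
they take longer to grow back. `droughtrec` implements the full measurement
chain for that contrast on monthly climate and vegetation series, for
ecohydrologists and ecosystem-resilience researchers who want a tested,
reproducible pipeline rather than one-off analysis scripts.

The chain, in the field's standard notation:

* **SPI-3** — 3-month precipitation totals mapped through a per-calendar-month
  gamma fit to a standard-normal scale (McKee construction with a point mass
  at zero). A *dry spell* is SPI < −1 for ≥ 2 consecutive months.
* **Event typing** — a spell is *hot–dry* when some 2-consecutive-month mean
  temperature overlapping it exceeds the 90th percentile of the same calendar
  month-pair across years, and *dry* otherwise; either way it must have a
  vegetation impact: detrended, deseasonalized vegetation anomaly < −0.1 SD
  within the spell + 6 months.
* **Recovery time** — RT = months from the maximum-loss month until the
  anomaly first returns to its normal level (0 SD);
  ΔRT = mean RT<sub>hot–dry</sub> − mean RT<sub>dry</sub> per pixel, related
  to the aridity index AI = P/PET by a binned regression.
* **Attribution** — random-forest regression of ΔRT on ΔVPD, ΔDS, Δloss,
  ΔSM, ΔPRE, ΔSrad, ΔTEM with permutation importances and partial-dependence
  curves.
* **Physiology** — stomatal limitation via canopy conductance
  G<sub>c</sub> = γ·LE/(ρ·c<sub>p</sub>·VPD) and non-stomatal limitation via
  A<sub>max</sub>, the asymptote of the rectangular-hyperbola light response
  GPP = α·PPFD·A<sub>max</sub>/(α·PPFD + A<sub>max</sub>), contrasted between
  event types.

Because the global satellite/flux archives such analyses run on cannot be
shipped, the package includes a first-class synthetic generator that plants
events with known type, timing, depth and true recovery time — every stage is
validated against that ground truth.

## Worked example

Run the default study scenario (200 pixels × 40 years, 50 planted hot–dry +
50 planted dry events, observation noise 0.05 index units) end to end and
score it against the planted truth:

```r
library(droughtrec)

sc  <- default_scenario(seed = 1)
res <- run_pipeline(pipeline_config(sc))

m <- match_events(res$events, res$truth)
cat("detected", nrow(res$events), "events;", sum(!is.na(m)), "of",
    nrow(res$truth), "planted events matched\n")
#> detected 3635 events; 100 of 100 planted events matched

acc <- 100 * mean(res$events$type[m] == res$truth$type, na.rm = TRUE)
mae <- mean(abs(res$events$rt[m] - res$truth$rt), na.rm = TRUE)
cat(sprintf("type accuracy %.0f%%; recovery-time MAE %.2f months\n", acc, mae))
#> type accuracy 100%; recovery-time MAE 0.13 months

rt_hd <- mean(res$events$rt[m][res$truth$type == "hot_dry"], na.rm = TRUE)
rt_dr <- mean(res$events$rt[m][res$truth$type == "dry"],    na.rm = TRUE)
cat(sprintf("mean RT: hot-dry %.2f, dry %.2f, delta-RT %.2f months\n",
            rt_hd, rt_dr, rt_hd - rt_dr))
#> mean RT: hot-dry 5.38, dry 4.12, delta-RT 1.26 months
```

The planted means are 5.4 and 4.2 months, so the pipeline recovers the
hot-dry prolongation to within a few hundredths of a month. The ~3,500 other
"events" are background dry spells whose unit-variance vegetation noise dips
below the −0.1 SD impact threshold — expected on noisy data (see the methods
vignette), which is why scoring is done against matched planted events. On
the noise-free variant (`default_scenario(seed = 1, veg_noise_sd = 0)` with
`pipeline_config(sc, sd_mode = "global")`) detection is exact: 100 events,
zero false alarms, every recovery time equal to its planted value.

`res$importance` holds the forest's importance percentages for the factor
differences and `res$partial_dependence` the curves for the three most
important ones. The flux side works the same way from half-hourly records:

```r
g  <- gen_flux(flux_config(n_days = 30, seed = 1, gc = 0.008, amax = 20, noise_sd = 0.1))
dp <- daily_physiology(g$rec)   # G_c by inversion, A_max by light-response fit
```

A thin command-line wrapper lives at `inst/cli/droughtrec.R`
(`simulate` and `run-all` subcommands).

## Vignette

`vignettes/droughtrec-methods.Rmd` documents the model and its assumptions,
every threshold and default with units, the synthetic generator's design
(what it emulates about real records and what it deliberately does not), and
the numerical decisions (robust seasonal-Theil-Sen baseline, SD-scaling
modes, shared quantum yield, censoring rules).
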