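# turbidr

Fixed-vial optical-density calibration and turbidostat control for
long-term experimental evolution of microbial cultures.

## The problem

Multiplexed continuous-culture platforms (eVOLVER-style "smart sleeves")
hold each evolving population between a low and a high optical-density
threshold: when the culture reaches the high threshold HT, fresh medium is
pumped in until it falls back to the low threshold LT, while an efflux
pump keeps the volume constant. Everything downstream — dilution timing,
generation-time estimates, cross-vial comparisons — rests on converting a
raw light-scattering reading into an OD through a per-sleeve calibration
curve.

Two instrument effects corrupt that conversion over months-long assays:

1. **Glass-vial signatures.** Each glass vial adds a large, essentially
   constant offset to the raw scattering signal, and even rotating a vial
   a few degrees shifts it. Calibrations assembled from many vials, and
   experiments run in yet another vial, inherit this spread.
2. **Mid-run vial swaps.** When a position fails (contamination, leak) and
   its vial is replaced, the new glass shifts all raw readings and the old
   calibration misreads the OD.

`turbidr` implements a calibration and OD-computation scheme that removes
both effects, plus the controller, servicing and monitoring machinery
around it, and a **virtual rig** — a ground-truth simulator of optics,
vials, cultures and pumps — so that the whole pipeline can be validated
end-to-end without hardware.

## The method

**Fixed-vial calibration.** All calibration points for a sleeve are
acquired in one fixed vial: a PBS-only measurement first (its raw value is
the anchor `raw_0_cal`), then increasing inoculations from a concentrated
stock. Because the stock's own OD is hard to measure, it is
*back-calculated*: the endpoint OD of each vial is measured on a bench
spectrophotometer and divided by the final cumulative dilution fraction,
`S = OD_final / f_final`, after which every point's OD is rescaled to
`S · f_i`. A 4-parameter monotone logistic `raw = base + amp / (1 +
exp(steep · (OD − mid)))` is fit to the corrected points; the OD lookup
`OD = f(raw)` is its analytic inverse.

**Δraw OD computation.** At experiment time the culture OD is *not*
computed as `f(raw_t) − f(raw_blank)` (the legacy path, which pushes the
vial offset through the curve's nonlinearity). Instead the engine forms

    Δraw = raw_t − raw_blank        (same vial: the glass offset cancels)
    OD   = f(raw_0_cal + Δraw)      (transposed onto the calibration anchor)

which is *exactly* invariant to any constant added to both raws. A vial
swap therefore needs no recalibration — resetting the medium blank on the
new vial restores accuracy, because different vials shift a sleeve's curve
by a raw offset only.

**Controller.** Dilution volume follows the bolus mass balance
`v = V (OD/LT − 1)` (capped per round; the rounds needed to reach LT are
logged as a pump-health diagnostic). Growth rate is the OLS slope of
ln(OD) vs time between successive dilutions, `T_d = ln 2 / μ`, smoothed
with a 10-point sliding window. Bottle ledgers, scale-series forecasting
and edge-triggered alerts (pause > 10 min, low medium, power loss,
dilution failure) cover experiment surveillance.

## Worked example

```r
library(turbidr)
set.seed(11)

optics <- true_optics("sleeve01", led_power = 2)   # virtual sleeve
vial   <- true_vial("v01")                         # random glass offset
curve  <- calibrate_sleeve(optics, vial)           # fixed-vial protocol
round(curve$params, 2)
#>     base      amp      mid    steep
#> 28341.13 14793.28     0.30     6.13

blank <- record_blank("v01", measure_raw(optics, vial, NULL, n = 5))
cfg <- controller_config(ht = 0.5, lt = 0.3)
run <- run_turbidostat(new_rig(optics, vial, true_culture(0.35)),
                       blank, curve, cfg, hours = 12)
gs <- estimate_growth_series(run$trace, run$events, cfg)
head(gs[, c("t_mid_h", "mu_per_h", "doubling_time_h", "r_squared")], 3)
#>   t_mid_h mu_per_h doubling_time_h r_squared
#> 1  0.6378   0.2783          2.4910    0.9963
#> 2  2.2022   0.2765          2.5066    0.9980
#> 3  4.0511   0.2769          2.5036    0.9979
mean(gs$doubling_time_h)          # true value: 2.5 h
#> 2.503
median(abs(run$trace$od - run$trace$od_true))
#> 0.0016
```

The 12-hour closed loop produced 2655 samples and 6 dilution events; the
estimated generation time recovers the simulated 2.5 h doubling time and
the Δraw engine tracks the true OD to ~0.002 despite a 50-raw-unit sensor
noise and a random glass offset. Feeding the dilution events into a
bottle ledger and forecasting from the implied scale weights:

```r
led <- bottle_ledger(data.frame(bottle_id = "b1", medium = "EMM",
                                start_weight_g = 2000, low_limit_g = 100))
led <- assign_bottle(led, "b1", "v01")
led <- record_consumption(led, run$events)
fc  <- forecast_empty(ledger_weight_series(led, "b1", seq(0, 12, 0.5)), 100)
c(fc$rate_ml_per_h, fc$eta_h)
#> 8.2 221.9        # mL/h consumed; hours until the 100 g low limit
```

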