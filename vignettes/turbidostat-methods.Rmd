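---
title: "Models and methods behind turbidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind turbidr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbidr)
```

`turbidr` packages the computational side of long-term turbidostat
experiments: calibration, OD computation, dilution control, vial
servicing and media monitoring, validated against a built-in virtual rig.
This vignette explains the models, the defaults and why they were chosen,
and what the validation does and does not establish.

## The virtual rig

The rig is the ground truth every other module is tested against.

**Optics.** A sleeve's raw scattering signal is modelled as a strictly
monotone saturating map of OD,
$$\mathrm{raw} = g(\mathrm{OD}) = \mathrm{base} +
\frac{\mathrm{amp}}{1 + e^{\,\mathrm{steep}\,(\mathrm{OD} - \mathrm{mid})}},$$
with additive Gaussian sensor noise. Real photodiode geometries may make
raw rise or fall with OD; the rig uses the falling direction
(`steep > 0`) and every downstream component assumes only monotonicity,
never the sign, so nothing in the pipeline depends on that unverifiable
hardware detail. Defaults (amplitude `7500 × led_power`,
`mid` 0.30, `steep` 6, noise SD 50 raw units) put the
blank reading near 41,000 raw units — the scale of a 16-bit scattering
ADC — and keep the noise-equivalent OD below ~0.005 across the working
range at the default LED power (`base` 28400, default amplitude 15000). The amplitude scaling makes the
worst-case slope over OD 0.2–0.5 strictly increasing in LED power, which
is the construction the LED-power selector is tested against.

**Vials.** Each glass vial adds a constant offset to the raw signal,
drawn once from Normal(0, 250 raw units); rotating a vial perturbs the
offset by an independent Normal(0, 100) step per rotation, steps
accumulating over successive acquisitions. These magnitudes make
fixed-vial read SDs fall in the few-tens-of-raw-units range while
vial-to-vial spread dominates sensor noise — the regime the fixed-vial
protocol exists for. With only 5 rotated reads against 447 fixed ones, a
per-seed two-sample variance test detects the inflation in a majority of
seeds but cannot do so near-certainly (4 numerator df); the test suite
asserts the detection rate and the mean variance ratio rather than
near-certainty.

**Cultures and pumps.** Growth is pure exponential between pump events,
`od' = od · 2^(dt · stress/T_d)`, with default doubling time
`T_d = 2.5 h` (fission yeast in minimal medium at 32 °C) and a
`stress_factor` multiplier in (0, 1] for scripted stress scenarios.
Dilution is an instantaneous bolus followed by efflux
(`od · V/(V+v)`, volume conserved); a continuous co-flow model
(`od · e^{−v/V}`) is available via `bolus_dilute(model = "coflow")` for
comparison. At the 16-s sampling cadence the bolus model matches the
threshold-crossing behaviour of a real dilution; the cadence (447 points
in roughly 2 h) is configurable.

What the rig does *not* emulate: wall growth and biofilms, fluid
dynamics, cell-shape effects on scattering, evolutionary dynamics
(mutation/selection). Multi-week adaptation can only be scripted as a
time-varying `stress_factor`; passing tests therefore demonstrate the
correctness of the measurement and control arithmetic under the stated
noise model, not the behaviour of real populations.

## Fixed-vial calibration

`plan_inoculation()` solves the dilution algebra: for cumulative stock
volume $v$ in a vial of volume $V$, the nominal OD is $S\,v/(V+v)$, so
targets translate into per-step added volumes in closed form. The stock
must be ≥ 20× the largest target (error otherwise), which bounds the
total added volume at roughly 5% of the vial volume so the inoculations
barely perturb the optical path length.

`backcalculate_stock()` replaces the error-prone direct measurement of
the concentrated stock: the endpoint ODs of all vials sharing a stock are
averaged (mean, matching standard practice of averaging replicate
spectrophotometer reads) and divided by the final cumulative fraction.
The operation is exactly scale-consistent: multiplying the measurements
by $k$ multiplies the stock estimate and every corrected point OD by $k$.

`correct_calibration()` swaps nominal for corrected ODs without touching
the raw values. Under the fixed-vial protocol every sleeve acquires its
points in the same order, so the measurement reordering required by the
legacy rotational-permutation layout degenerates to an identity map; it
is kept explicit (`order_map`) so file layouts from the legacy tooling
can still be read. Monotonicity violations beyond a 150-raw-unit gate
(3× the default noise SD) warn rather than error — a single noisy point
should not abort a 1.5 h calibration run.

`fit_curve()` fits the 4-parameter logistic by Levenberg–Marquardt
(`minpack.lm::nlsLM`), which converges cleanly even on the zero-residual
noise-free case. Initial values are deterministic functions of data
quantiles (asymptotes from the raw range, midpoint from the half-range
crossing, slope sign from the OD–raw correlation), so refitting the same
points gives bit-identical parameters; there are no random restarts. The
OD lookup is the analytic inverse of the fitted logistic — monotone and
single-valued by construction, which is why the forward form is fitted
rather than a logistic in raw (whose inverse would not be available in
closed form against the forward simulator family). Ten points spaced over
OD 0–0.8 are the default targets: dense at the bottom where the blank
anchor matters, sparse at the top, and few enough that a full run with
five reads per point stays within a realistic bench session. A fitted
curve whose `f(raw_0_cal)` strays beyond ±0.02 OD from zero triggers a
warning, as the anchor is the linchpin of the Δraw method.

**LED selection.** `select_led_power()` scores each candidate curve by
`min |d raw/d OD|` on a 201-point grid over the OD 0.2–0.5 window and
returns the argmax, breaking ties toward the lower power (less
photothermal load for equal dynamic range). The unit tests check the
choice against a finite-difference brute-force oracle on a denser grid.

**Temperature.** The three-point plan uses RT, RT+6 and RT+12 °C:
moderate elevations stay reachable in warm rooms and inside the
physiological range of yeast growth, unlike the larger elevations of
older protocols. The surface→culture map is an OLS line (slope must be
positive). If an immersed reference shows a persistent constant offset —
cultures commonly equilibrate a tenth of a degree or so below target —
`commanded_temp_target(requested, offset_c)` simply adds it to the
commanded setpoint.

## The Δraw OD engine

The blank is the median of the medium-only reads (median for outlier
robustness), gated on a read dispersion (range) of 300 raw units — twice
the monotonicity gate — beyond which the vial is assumed badly seated.
The OD of a reading is
$$\mathrm{OD} = f(\mathrm{raw}_{0,\mathrm{cal}} + \mathrm{raw}_t -
\mathrm{raw}_\mathrm{blank}),$$
which is algebraically invariant to any constant added to both raw
values — the property that makes the method immune to glass-vial offsets,
and which the test suite asserts as exact equality, not approximate.
Negative ODs are reported (flagged below −0.02) rather than clamped:
clamping would bias the controller and hide drift from QC. Readings whose
transposed raw leaves the calibrated range carry an `extrapolated` flag;
raws outside the invertible domain of the logistic are an error. The
legacy difference-of-ODs path is retained (`legacy_od()`) purely for
comparison studies.

## Controller

The trigger is inclusive at HT. The commanded bolus follows the mass
balance `v = V(OD/LT − 1)`, capped per round at 40% of the vial volume so
pump actuation per cycle stays bounded; large corrections complete over
multiple rounds, and the round count is itself the dilution-efficiency
diagnostic (a healthy noise-free dilution takes one uncapped round; a
weak pump takes more; `max_rounds`, default 6, raises a
`dilution_failure` alert — the signature of a blocked line or leak).
Termination requires the measured OD to come within `lt_tolerance`
(default 0.01 OD) of LT, preventing endless micro-dilutions against the
noise floor.

Growth fits use ln(OD)-vs-time OLS between successive dilutions,
excluding readings within 120 s of a dilution (mixing transient) and
requiring at least 5 positive-OD points; non-positive ODs are excluded
with their count reported. The generation time is `ln 2 / μ`, undefined
for `μ ≤ 0`. A trailing 10-point sliding window smooths the per-interval
rates; a shorter prefix averages over what exists.

## Vial replacement

The replacement workflow displays `f(raw_0_cal + raw_live −
raw_blank_old)` — referenced to the *medium* blank, not the calibration
blank — while the new medium-filled vial is rotated toward zero. The
auto-accept gate defaults to |OD| < 0.01, a threshold that is genuinely
assay-specific and therefore exposed as configuration. When equilibration
fails, `reset_blank()` re-records the blank on the new vial and leaves
the curve untouched: vial changes shift a sleeve's curve by a raw offset
only, so moving the blank cancels the change exactly (an algebraic
identity the tests check across an offset grid) and a curve refit would
require a full recalibration for no benefit. Each session records exactly
one decision and appends to a JSON-lines audit log.

## Monitoring

The bottle ledger enforces one bottle per vial at a time and accumulates
the *commanded* dilution volumes, so ledger totals equal controller
output exactly (conservation is asserted to the last bit in the tests).
Scale forecasting fits weight vs time by OLS over a trailing 6-h window —
long enough to average over several dilution cycles, short enough to
track a consumption change within a workday; the window length is
configuration. Plain OLS (rather than a robust estimator) keeps the rate
arithmetic transparent, and the simulated scale series it is validated
against contain no outliers; a real deployment with jumpy scales may want
a longer window. The default medium density is 1.0 g/mL with per-bottle
override. Alerts are edge-triggered per episode (pause > 10 min, weight
below limit, missing scale heartbeat, dilution failure, code error) and
dispatched to a pluggable notifier function; stdout and JSON-lines file
notifiers ship with the package, and notifier failures are logged, never
fatal.

## Validation scale

The test suite and acceptance script run entirely on the virtual rig:
closed-loop soaks of 12 and 72 simulated hours at 16-s cadence, 100
independent 8-hour runs for the growth-recovery benchmark, 200-seed Monte
Carlo for the rotation-variance property, and 40 replicate noisy
calibrations. These sizes give sub-percent Monte-Carlo error on the
benchmarked means while keeping a full run in the tens of seconds on one
core.

## Known limitations

* The logistic curve family is an idealisation; real sleeves can deviate
  near saturation. The `extrapolated` flag marks readings outside the
  calibrated range, but the package does not model curve misspecification.
* Blank and anchor share the media/PBS equivalence assumption; media
  whose scattering differs from PBS by more than a few noise SDs (check
  with `media_equivalence()` / `check_media_equivalence()`) invalidate
  the transposition.
* The controller implements turbidostat mode only — no chemostat or
  morbidostat regimes, and no temperature or stirring feedback beyond the
  calibrated setpoint map.
* Simulation fidelity, not biological realism, is the claim: estimator
  accuracy on the rig bounds arithmetic errors, not real-world effects
  like flocculation, wall growth or adaptation.
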