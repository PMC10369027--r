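# ---- end-to-end validation runs on the virtual rig --------------------------

#' Growth-rate recovery benchmark
#'
#' Full-chain validation of the growth-rate estimator: for each run, a
#' sleeve is calibrated on the virtual rig (fixed-vial protocol, noisy
#' optics), a medium blank is recorded, an 8-hour closed-loop turbidostat
#' is simulated at 16-s cadence with a known true doubling time, and the
#' generation time is estimated by log-linear fits between successive
#' dilutions. Returns one mean doubling-time estimate per run; their
#' average should recover the true value.
#'
#' @param n_runs number of independent runs.
#' @param hours simulated duration per run.
#' @param doubling_time_h true doubling time of the simulated culture.
#' @param ht,lt controller thresholds.
#' @param dt_s sampling cadence, seconds.
#' @param noise_sd sensor noise, raw units.
#' @param seed base RNG seed; run i uses `seed + i`.
#' @return Numeric vector of per-run mean doubling-time estimates, hours.
#' @export
growth_recovery_benchmark <- function(n_runs = 100L, hours = 8,
                                      doubling_time_h = 2.5, ht = 0.5,
                                      lt = 0.3, dt_s = 16, noise_sd = 50,
                                      seed = 1L) {
  cfg <- controller_config(ht = ht, lt = lt)
  vapply(seq_len(n_runs), function(i) {
    set.seed(seed + i)
    optics <- true_optics(sprintf("s%03d", i), led_power = 2L,
                          noise_sd = noise_sd)
    vial <- true_vial(sprintf("v%03d", i))
    curve <- calibrate_sleeve(optics, vial)
    blank <- record_blank(vial$vial_id, measure_raw(optics, vial, NULL, 5))
    rig <- new_rig(optics, vial,
                   true_culture(0.35, doubling_time_h = doubling_time_h))
    run <- run_turbidostat(rig, blank, curve, cfg, hours = hours,
                           dt_s = dt_s)
    gs <- estimate_growth_series(run$trace, run$events, cfg)
    mean(gs$doubling_time_h)
  }, numeric(1))
}
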