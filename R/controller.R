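# ---- turbidostat controller -------------------------------------------------

#' Turbidostat controller configuration
#'
#' The controller keeps each culture oscillating between a low and a high OD
#' threshold: when a reading reaches the high threshold `ht` the influx pump
#' dilutes the culture with fresh medium until it returns to the low
#' threshold `lt` (efflux keeps the volume constant). A narrow `lt`-`ht`
#' band gives turbidostat-like operation.
#'
#' @param ht high OD threshold triggering dilution (inclusive).
#' @param lt low OD threshold targeted by dilution; `0 < lt < ht`.
#' @param vial_volume_ml working culture volume, mL.
#' @param influx_flow_ml_per_s pump flow rate (used for actuation timing).
#' @param max_rounds maximum dilution rounds per event before a
#'   `dilution_failure` alert (possible pump/efflux failure or leak).
#' @param settle_time_s wait between a bolus and its control re-measurement,
#'   seconds.
#' @param window sliding-window length (readings) for growth-rate smoothing.
#' @param lt_tolerance OD slack above `lt` at which a dilution event stops;
#'   prevents endless micro-dilutions at the noise floor.
#' @param bolus_cap_frac per-round bolus cap as a fraction of the vial
#'   volume; a large correction is split across rounds (counted in
#'   `rounds`) so pump actuation per cycle stays bounded.
#' @param min_points minimum readings required for a growth fit.
#' @param settle_exclude_s post-dilution readings younger than this are
#'   excluded from growth fits (mixing transient).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(ht, lt, vial_volume_ml = 25,
                              influx_flow_ml_per_s = 1, max_rounds = 6L,
                              settle_time_s = 60, window = 10L,
                              lt_tolerance = 0.01, bolus_cap_frac = 0.4,
                              min_points = 5L, settle_exclude_s = 120) {
  stopifnot(lt > 0, ht > lt, vial_volume_ml > 0, influx_flow_ml_per_s > 0,
            max_rounds >= 1, window >= 1, lt_tolerance >= 0,
            bolus_cap_frac > 0, bolus_cap_frac <= 1)
  structure(list(ht = ht, lt = lt, vial_volume_ml = vial_volume_ml,
                 influx_flow_ml_per_s = influx_flow_ml_per_s,
                 max_rounds = as.integer(max_rounds),
                 settle_time_s = settle_time_s, window = as.integer(window),
                 lt_tolerance = lt_tolerance,
                 bolus_cap_frac = bolus_cap_frac,
                 min_points = as.integer(min_points),
                 settle_exclude_s = settle_exclude_s),
            class = "controller_config")
}

#' Dilution trigger
#'
#' `TRUE` iff the reading has reached the high threshold (boundary
#' inclusive).
#'
#' @param od OD reading.
#' @param config a [controller_config()].
#' @return Logical.
#' @export
should_dilute <- function(od, config) {
  od >= config$ht
}

#' Medium volume needed to dilute to the low threshold
#'
#' Under the bolus model (instantaneous mixing, efflux restoring the
#' level), mass balance `od_now * V = lt * (V + v)` gives
#' `v = V * (od_now / lt - 1)`.
#'
#' @param od_now current OD (must exceed `lt`).
#' @param lt target low threshold.
#' @param vial_volume_ml working volume, mL.
#' @return Volume to add, mL.
#' @export
dilution_volume <- function(od_now, lt, vial_volume_ml) {
  if (any(od_now <= lt)) stop("od_now must exceed the low threshold")
  vial_volume_ml * (od_now / lt - 1)
}

#' Execute one threshold-triggered dilution event on the virtual rig
#'
#' Commands a bolus sized by [dilution_volume()] (capped per round at
#' `bolus_cap_frac` of the vial volume), waits `settle_time_s` while the
#' culture keeps growing, re-measures, and repeats while the measured OD
#' stays above `lt + lt_tolerance`, up to `max_rounds`. The number of
#' rounds needed is the dilution-efficiency figure logged with the event;
#' hitting `max_rounds` flags the event as failed (pump or efflux fault).
#' Commanded volume is what the controller ordered; a vial with
#' `influx_efficiency < 1` receives less, requiring extra rounds.
#'
#' @param rig a [new_rig()] state.
#' @param blank a [record_blank()] result.
#' @param curve a [fit_curve()] result.
#' @param config a [controller_config()].
#' @param t_start_h simulation time at trigger, hours.
#' @param od_trigger the OD reading that triggered the event.
#' @return List: `rig` (updated state), `event` (one-row data frame:
#'   `vial_id, t_start_h, t_end_h, od_before, od_after,
#'   commanded_volume_ml, rounds, failed`), `t_h` (time after the event).
#' @export
run_dilution <- function(rig, blank, curve, config, t_start_h, od_trigger) {
  settle_h <- config$settle_time_s / 3600
  cap_ml <- config$bolus_cap_frac * config$vial_volume_ml
  od_now <- od_trigger
  t_h <- t_start_h
  commanded <- 0
  rounds <- 0L
  failed <- FALSE
  repeat {
    rounds <- rounds + 1L
    v_cmd <- min(dilution_volume(od_now, config$lt, config$vial_volume_ml),
                 cap_ml)
    commanded <- commanded + v_cmd
    rig$culture <- bolus_dilute(rig$vial, rig$culture,
                                v_cmd * rig$vial$influx_efficiency)
    rig$culture <- advance(rig$culture, settle_h)
    t_h <- t_h + settle_h
    raw <- measure_raw(rig$optics, rig$vial, rig$culture)
    od_now <- od_from_raw(curve, curve$raw_0_cal + raw - blank$raw_blank)
    if (od_now <= config$lt + config$lt_tolerance) break
    if (rounds >= config$max_rounds) { failed <- TRUE; break }
  }
  event <- data.frame(vial_id = rig$vial$vial_id, t_start_h = t_start_h,
                      t_end_h = t_h, od_before = od_trigger,
                      od_after = od_now, commanded_volume_ml = commanded,
                      rounds = rounds, failed = failed)
  list(rig = rig, event = event, t_h = t_h)
}

#' Run a closed-loop turbidostat on the virtual rig
#'
#' Samples the culture at a fixed cadence through the virtual optics and the
#' delta-raw OD engine; whenever a reading reaches the high threshold, a
#' dilution event is executed via [run_dilution()] (simulation time advances
#' by the event's settle waits). Readings taken inside an event are logged
#' on the event record, not in the main trace.
#'
#' @param rig a [new_rig()] state.
#' @param blank a [record_blank()] result for the rig's vial.
#' @param curve a [fit_curve()] result for the rig's vial.
#' @param config a [controller_config()].
#' @param hours simulated duration.
#' @param dt_s sampling cadence, seconds (default 16 s).
#' @return List: `trace` (data frame `t_h, raw, od, od_true`), `events`
#'   (dilution events), `alerts` (list of `dilution_failure` payloads),
#'   `rig` (final state).
#' @export
run_turbidostat <- function(rig, blank, curve, config, hours, dt_s = 16) {
  dt_h <- dt_s / 3600
  n_max <- ceiling(hours / dt_h) + 1L
  t_v <- raw_v <- od_v <- odt_v <- numeric(n_max)
  events <- vector("list", 256L)
  alerts <- list()
  n <- 0L; ne <- 0L; t_h <- 0
  raw0 <- curve$raw_0_cal - blank$raw_blank
  while (t_h < hours) {
    rig$culture <- advance(rig$culture, dt_h)
    t_h <- t_h + dt_h
    raw <- measure_raw(rig$optics, rig$vial, rig$culture)
    od <- od_from_raw(curve, raw0 + raw)
    n <- n + 1L
    t_v[n] <- t_h; raw_v[n] <- raw; od_v[n] <- od
    odt_v[n] <- rig$culture$od_true
    if (should_dilute(od, config)) {
      d <- run_dilution(rig, blank, curve, config, t_h, od)
      rig <- d$rig; t_h <- d$t_h
      ne <- ne + 1L
      events[[ne]] <- d$event
      if (d$event$failed)
        alerts <- c(alerts, list(list(kind = "dilution_failure",
                                      vial_id = rig$vial$vial_id,
                                      t_h = t_h)))
    }
  }
  list(trace = data.frame(t_h = t_v[seq_len(n)], raw = raw_v[seq_len(n)],
                          od = od_v[seq_len(n)], od_true = odt_v[seq_len(n)]),
       events = if (ne > 0) do.call(rbind, events[seq_len(ne)])
                else data.frame(),
       alerts = alerts, rig = rig)
}

#' Estimate the growth rate between two successive dilutions
#'
#' Ordinary least squares of `ln(OD)` on time over the readings of one
#' inter-dilution interval: the slope is the specific growth rate `mu`
#' (per hour) and the doubling (generation) time is `ln(2) / mu`,
#' undefined for `mu <= 0`. Non-positive ODs cannot enter the log fit and
#' are excluded with their count reported.
#'
#' @param t_h reading times, hours.
#' @param od OD readings.
#' @param min_points minimum usable points (default 5).
#' @return An object of class `growth_estimate`: `mu_per_h`,
#'   `doubling_time_h`, `r_squared`, `n_points`, `n_excluded`.
#' @export
estimate_growth <- function(t_h, od, min_points = 5L) {
  keep <- is.finite(od) & od > 0
  n_excl <- sum(!keep)
  if (sum(keep) < min_points)
    stop(sprintf("need at least %d positive-OD readings, got %d",
                 min_points, sum(keep)))
  t_h <- t_h[keep]; od <- od[keep]
  fit <- stats::lm(log(od) ~ t_h)
  mu <- unname(stats::coef(fit)[2])
  # exact exponentials fit perfectly; silence summary.lm's warning about it
  r2 <- if (stats::var(log(od)) == 0) 1
        else suppressWarnings(summary(fit)$r.squared)
  structure(list(mu_per_h = mu,
                 doubling_time_h = if (mu > 0) log(2) / mu else NA_real_,
                 r_squared = r2, n_points = length(od),
                 n_excluded = n_excl),
            class = "growth_estimate")
}

#' Growth estimates for every inter-dilution interval of a run
#'
#' Splits a closed-loop trace at the dilution events, drops readings within
#' `settle_exclude_s` after an event (mixing transient) and readings at or
#' above the trigger sample of the next event, and fits each interval with
#' [estimate_growth()]. Intervals with too few points are skipped.
#'
#' @param trace,events outputs of [run_turbidostat()].
#' @param config a [controller_config()].
#' @return Data frame: `t_mid_h, mu_per_h, doubling_time_h, r_squared,
#'   n_points`, one row per usable interval, plus a `window_mu` column --
#'   the trailing sliding-window mean of `mu_per_h` (see
#'   [window_average()]).
#' @export
estimate_growth_series <- function(trace, events, config) {
  bounds <- c(0, if (nrow(events) > 0) events$t_end_h else numeric(0),
              Inf)
  excl_h <- config$settle_exclude_s / 3600
  rows <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i] + excl_h
    hi <- if (i <= nrow(events)) events$t_start_h[i] else Inf
    sel <- trace$t_h > lo & trace$t_h < hi
    if (sum(sel) < config$min_points) next
    g <- estimate_growth(trace$t_h[sel], trace$od[sel], config$min_points)
    rows[[length(rows) + 1L]] <- data.frame(
      t_mid_h = mean(range(trace$t_h[sel])), mu_per_h = g$mu_per_h,
      doubling_time_h = g$doubling_time_h, r_squared = g$r_squared,
      n_points = g$n_points)
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  out$window_mu <- window_average(out$mu_per_h, config$window)
  out
}

#' Trailing sliding-window average
#'
#' Mean of the last `window` values at each position; a shorter prefix is
#' averaged over the points available so far. `window = 1` is the identity.
#'
#' @param x numeric series.
#' @param window window length (>= 1).
#' @return Numeric series of the same length.
#' @export
window_average <- function(x, window = 10L) {
  stopifnot(window >= 1)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}
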