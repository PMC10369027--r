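# ---- media bottles, scales and alerts ---------------------------------------

#' Create a media-bottle ledger
#'
#' Tracks which bottle feeds which vials, every dilution's medium draw, and
#' bottle switches, so that medium consumption can be audited and compared
#' against scale weights. Each vial is assigned to exactly one bottle at a
#' time.
#'
#' @param bottles data frame with columns `bottle_id`, `medium`,
#'   `start_weight_g` and optionally `density_g_per_ml` (default 1.0 --
#'   aqueous media; override per medium), `low_limit_g` (default 0).
#' @return An object of class `bottle_ledger`.
#' @export
bottle_ledger <- function(bottles) {
  stopifnot(all(c("bottle_id", "medium", "start_weight_g") %in% names(bottles)))
  if (anyDuplicated(bottles$bottle_id)) stop("duplicate bottle ids")
  if (is.null(bottles$density_g_per_ml)) bottles$density_g_per_ml <- 1.0
  if (is.null(bottles$low_limit_g)) bottles$low_limit_g <- 0
  structure(list(bottles = bottles,
                 assignments = data.frame(vial_id = character(0),
                                          bottle_id = character(0),
                                          t_h = numeric(0)),
                 events = data.frame(vial_id = character(0),
                                     bottle_id = character(0),
                                     volume_ml = numeric(0),
                                     t_h = numeric(0)),
                 switches = data.frame(old_bottle = character(0),
                                       new_bottle = character(0),
                                       t_h = numeric(0))),
            class = "bottle_ledger")
}

#' Assign vials to a media bottle
#'
#' @param ledger a [bottle_ledger()].
#' @param bottle_id bottle receiving the vials.
#' @param vial_ids vials to (re)assign.
#' @param t_h assignment time, hours.
#' @return The updated ledger.
#' @export
assign_bottle <- function(ledger, bottle_id, vial_ids, t_h = 0) {
  if (!bottle_id %in% ledger$bottles$bottle_id)
    stop("unknown bottle: ", bottle_id)
  keep <- !(ledger$assignments$vial_id %in% vial_ids)
  ledger$assignments <- rbind(
    ledger$assignments[keep, ],
    data.frame(vial_id = vial_ids, bottle_id = bottle_id, t_h = t_h))
  ledger
}

#' Current bottle of a vial
#' @param ledger a [bottle_ledger()].
#' @param vial_id vial identifier.
#' @return The bottle id, or `NA` when unassigned.
#' @export
bottle_of <- function(ledger, vial_id) {
  i <- match(vial_id, ledger$assignments$vial_id)
  if (is.na(i)) NA_character_ else ledger$assignments$bottle_id[i]
}

#' Record the medium draw of a dilution event
#'
#' Appends the event's commanded volume to the consumption history of the
#' vial's current bottle. Unassigned vials are an error -- medium cannot be
#' drawn from nowhere.
#'
#' @param ledger a [bottle_ledger()].
#' @param event one dilution event (row with `vial_id`,
#'   `commanded_volume_ml`, `t_end_h`), or a multi-row event data frame.
#' @return The updated ledger.
#' @export
record_consumption <- function(ledger, event) {
  for (i in seq_len(nrow(event))) {
    b <- bottle_of(ledger, event$vial_id[i])
    if (is.na(b))
      stop("vial ", event$vial_id[i], " is not assigned to any bottle")
    ledger$events <- rbind(ledger$events, data.frame(
      vial_id = event$vial_id[i], bottle_id = b,
      volume_ml = event$commanded_volume_ml[i], t_h = event$t_end_h[i]))
  }
  ledger
}

#' Register a bottle switch
#'
#' Moves every vial of `old_bottle` to `new_bottle` and logs the switch.
#'
#' @param ledger a [bottle_ledger()].
#' @param old_bottle,new_bottle bottle ids.
#' @param t_h switch time, hours.
#' @return The updated ledger.
#' @export
switch_bottle <- function(ledger, old_bottle, new_bottle, t_h) {
  if (!new_bottle %in% ledger$bottles$bottle_id)
    stop("unknown bottle: ", new_bottle)
  sel <- ledger$assignments$bottle_id == old_bottle
  ledger$assignments$bottle_id[sel] <- new_bottle
  ledger$assignments$t_h[sel] <- t_h
  ledger$switches <- rbind(ledger$switches, data.frame(
    old_bottle = old_bottle, new_bottle = new_bottle, t_h = t_h))
  ledger
}

#' Per-vial and per-bottle consumption totals
#'
#' @param ledger a [bottle_ledger()].
#' @return List of two data frames, `by_vial` and `by_bottle`, with columns
#'   `id` and `volume_ml`.
#' @export
consumption_totals <- function(ledger) {
  agg <- function(key) {
    if (nrow(ledger$events) == 0L)
      return(data.frame(id = character(0), volume_ml = numeric(0)))
    s <- tapply(ledger$events$volume_ml, ledger$events[[key]], sum)
    data.frame(id = names(s), volume_ml = as.numeric(s), row.names = NULL)
  }
  list(by_vial = agg("vial_id"), by_bottle = agg("bottle_id"))
}

#' Synthesise the scale weight series implied by a ledger
#'
#' Weight at time t is the start weight minus density times the cumulative
#' consumption of the bottle up to t -- the signal a dedicated scale under
#' the bottle would show.
#'
#' @param ledger a [bottle_ledger()].
#' @param bottle_id bottle to render.
#' @param times_h sample times, hours (increasing).
#' @return Data frame of class `scale_series`: `t_h`, `weight_g`.
#' @export
ledger_weight_series <- function(ledger, bottle_id, times_h) {
  b <- ledger$bottles[ledger$bottles$bottle_id == bottle_id, ]
  if (nrow(b) != 1L) stop("unknown bottle: ", bottle_id)
  ev <- ledger$events[ledger$events$bottle_id == bottle_id, ]
  used <- vapply(times_h,
                 function(t) sum(ev$volume_ml[ev$t_h <= t]), numeric(1))
  out <- data.frame(t_h = times_h,
                    weight_g = b$start_weight_g - b$density_g_per_ml * used)
  class(out) <- c("scale_series", class(out))
  out
}

#' Forecast when a bottle will hit its low limit
#'
#' Linear fit of weight versus time over the trailing window of the scale
#' series; the consumption rate is the negative slope and the time to the
#' low limit extrapolates from the latest weight. A non-decreasing weight
#' gives an infinite eta.
#'
#' @param series a data frame with `t_h` (increasing) and `weight_g`.
#' @param low_limit_g alarm weight, g.
#' @param density_g_per_ml medium density for the mL/h rate.
#' @param window_h trailing window length, hours (default 6).
#' @return List: `rate_ml_per_h` (consumption rate, >= 0 when emptying),
#'   `rate_g_per_h`, `eta_h` (hours until `low_limit_g`; `Inf` when not
#'   emptying), `weight_now_g`.
#' @export
forecast_empty <- function(series, low_limit_g, density_g_per_ml = 1.0,
                           window_h = 6) {
  if (nrow(series) < 2L) stop("at least two scale samples are required")
  if (any(diff(series$t_h) <= 0)) stop("scale timestamps must be increasing")
  t_now <- series$t_h[nrow(series)]
  win <- series[series$t_h >= t_now - window_h, ]
  if (nrow(win) < 2L) win <- series[(nrow(series) - 1L):nrow(series), ]
  slope <- unname(stats::coef(stats::lm(weight_g ~ t_h, data = win))[2])
  w_now <- series$weight_g[nrow(series)]
  if (slope >= -1e-9)  # flat within numerical jitter: not emptying
    return(list(rate_ml_per_h = 0, rate_g_per_h = 0, eta_h = Inf,
                weight_now_g = w_now))
  list(rate_ml_per_h = -slope / density_g_per_ml, rate_g_per_h = -slope,
       eta_h = max(w_now - low_limit_g, 0) / -slope, weight_now_g = w_now)
}

# ---- alert conditions and notifier contract ---------------------------------

#' Create an edge-triggered alert monitor
#'
#' Surveillance conditions for a running assay: an error in the experiment
#' code that blocks the assay, a pause lasting longer than 10 minutes
#' (cultures grow to saturation if a paused assay is forgotten), a bottle
#' below its low weight limit, a missing scale heartbeat (power loss), and
#' controller dilution failures. Each condition fires once per episode:
#' an alert is emitted when the condition becomes true and not again until
#' it has cleared.
#'
#' Alerts are dispatched to a pluggable notifier, a function of one
#' `alert_event` argument (e.g. print to stdout, append to a file, post to
#' a webhook). Notifier failures are caught and logged, never fatal.
#'
#' @param notifier function called with each alert event; the default
#'   collects events silently.
#' @param pause_limit_min pause duration threshold, minutes (default 10).
#' @param heartbeat_limit_min maximum scale-heartbeat age before a
#'   `power_loss` alert, minutes.
#' @return An object of class `alert_monitor`.
#' @export
alert_monitor <- function(notifier = NULL, pause_limit_min = 10,
                          heartbeat_limit_min = 5) {
  structure(list(notifier = notifier, pause_limit_min = pause_limit_min,
                 heartbeat_limit_min = heartbeat_limit_min,
                 prev = character(0), log = list()),
            class = "alert_monitor")
}

#' Evaluate alert conditions at a point in time
#'
#' `state` describes the assay now: `paused_since_h` (`NA` when running),
#' `code_error` (logical), `weights_g`/`low_limits_g` (named by bottle),
#' `scale_last_seen_h` (last heartbeat), `dilution_failed_vials`
#' (character). Returns the events newly fired at `now_h` (edge-triggered)
#' after dispatching each to the notifier.
#'
#' @param monitor an [alert_monitor()].
#' @param state list describing current assay state (see Details).
#' @param now_h current time, hours.
#' @return List: `monitor` (updated episode state, cumulative `log`) and
#'   `events` (alert events fired this call; each has `kind`, `payload`,
#'   `t_h`).
#' @export
check_alerts <- function(monitor, state, now_h) {
  active <- list()
  if (isTRUE(state$code_error))
    active[["code_error"]] <- list(kind = "code_error",
                                   payload = state$code_error_message,
                                   t_h = now_h)
  if (!is.null(state$paused_since_h) && !is.na(state$paused_since_h) &&
      (now_h - state$paused_since_h) * 60 > monitor$pause_limit_min)
    active[["paused_too_long"]] <- list(
      kind = "paused_too_long",
      payload = list(paused_min = (now_h - state$paused_since_h) * 60),
      t_h = now_h)
  if (!is.null(state$weights_g)) {
    low <- names(state$weights_g)[state$weights_g <
                                    state$low_limits_g[names(state$weights_g)]]
    for (b in low)
      active[[paste0("low_medium:", b)]] <- list(
        kind = "low_medium",
        payload = list(bottle_id = b,
                       weight_g = unname(state$weights_g[b])),
        t_h = now_h)
  }
  if (!is.null(state$scale_last_seen_h) &&
      (now_h - state$scale_last_seen_h) * 60 > monitor$heartbeat_limit_min)
    active[["power_loss"]] <- list(
      kind = "power_loss",
      payload = list(last_seen_h = state$scale_last_seen_h), t_h = now_h)
  for (v in state$dilution_failed_vials)
    active[[paste0("dilution_failure:", v)]] <- list(
      kind = "dilution_failure", payload = list(vial_id = v), t_h = now_h)

  fired <- active[setdiff(names(active), monitor$prev)]
  monitor$prev <- names(active)  # an episode re-fires only after clearing
  if (length(fired) > 0) {
    monitor$log <- c(monitor$log, fired)
    if (!is.null(monitor$notifier))
      for (ev in fired)
        tryCatch(monitor$notifier(ev),
                 error = function(e)
                   message("notifier failed (ignored): ",
                           conditionMessage(e)))
  }
  list(monitor = monitor, events = unname(fired))
}

#' Stdout and file notifiers
#'
#' Ready-made notifier implementations for [alert_monitor()]:
#' `stdout_notifier()` prints one line per alert; `file_notifier(path)`
#' appends JSON lines.
#'
#' @param path file for the JSON-lines notifier.
#' @return A notifier function of one event.
#' @export
stdout_notifier <- function() {
  function(event)
    cat(sprintf("[alert %s] t=%.2f h %s\n", event$kind, event$t_h,
                jsonlite::toJSON(event$payload, auto_unbox = TRUE)))
}

#' @rdname stdout_notifier
#' @export
file_notifier <- function(path) {
  function(event)
    cat(jsonlite::toJSON(event, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = path, append = TRUE)
}

#' Text report of consumption and bottle forecasts
#'
#' Renders per-vial consumption totals and, per bottle, the current weight,
#' consumption rate and forecast time to the low limit -- the textual
#' equivalent of a dilution/scale dashboard.
#'
#' @param ledger a [bottle_ledger()].
#' @param series_by_bottle named list of scale series (one per bottle);
#'   when omitted, series are synthesised from the ledger.
#' @param now_h report time, hours.
#' @return A character vector of report lines, invisibly; also printed.
#' @export
consumption_report <- function(ledger, series_by_bottle = NULL, now_h = NULL) {
  tot <- consumption_totals(ledger)
  lines <- c("== vial consumption (mL) ==",
             sprintf("  %-8s %10.3f", tot$by_vial$id, tot$by_vial$volume_ml),
             "== bottles ==")
  for (i in seq_len(nrow(ledger$bottles))) {
    b <- ledger$bottles[i, ]
    ser <- if (!is.null(series_by_bottle)) series_by_bottle[[b$bottle_id]]
           else {
             tmax <- if (nrow(ledger$events)) max(ledger$events$t_h) else 1
             ledger_weight_series(ledger, b$bottle_id,
                                  seq(0, tmax, length.out = 25))
           }
    fc <- forecast_empty(ser, b$low_limit_g, b$density_g_per_ml)
    lines <- c(lines, sprintf(
      "  %-8s %-6s %7.1f g  rate %6.2f mL/h  eta %s",
      b$bottle_id, b$medium, fc$weight_now_g, fc$rate_ml_per_h,
      if (is.infinite(fc$eta_h)) "inf" else sprintf("%.1f h", fc$eta_h)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
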