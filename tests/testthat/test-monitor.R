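make_ledger <- function() {
  led <- bottle_ledger(data.frame(
    bottle_id = c("b1", "b2"), medium = c("EMM", "EMM"),
    start_weight_g = c(1000, 1000), low_limit_g = c(100, 100)))
  led <- assign_bottle(led, "b1", c("v1", "v2"))
  assign_bottle(led, "b2", "v3")
}

test_that("consumption events accumulate into per-vial and per-bottle totals", {
  led <- make_ledger()
  ev <- data.frame(vial_id = c("v1", "v1", "v2"),
                   commanded_volume_ml = rep(50 / 3, 3),
                   t_end_h = c(1, 2, 3))
  led <- record_consumption(led, ev)
  tot <- consumption_totals(led)
  expect_equal(tot$by_bottle$volume_ml[tot$by_bottle$id == "b1"], 50)
  expect_equal(tot$by_vial$volume_ml[tot$by_vial$id == "v1"], 100 / 3)

  led0 <- record_consumption(led, data.frame(vial_id = "v2",
                                             commanded_volume_ml = 0,
                                             t_end_h = 4))
  expect_equal(consumption_totals(led0)$by_bottle,
               consumption_totals(led)$by_bottle)
  expect_error(record_consumption(led, data.frame(
    vial_id = "vX", commanded_volume_ml = 1, t_end_h = 1)),
    "not assigned")
})

test_that("bottle switches reassign vials and are logged", {
  led <- make_ledger()
  led <- switch_bottle(led, "b1", "b2", t_h = 5)
  expect_equal(bottle_of(led, "v1"), "b2")
  expect_equal(nrow(led$switches), 1)
  led <- record_consumption(led, data.frame(vial_id = "v1",
                                            commanded_volume_ml = 10,
                                            t_end_h = 6))
  expect_equal(consumption_totals(led)$by_bottle$id, "b2")
})

test_that("emptying forecast extrapolates the trailing linear trend", {
  ser <- data.frame(t_h = seq(0, 10, by = 1),
                    weight_g = seq(1000, 900, by = -10))
  class(ser) <- c("scale_series", class(ser))
  fc <- forecast_empty(ser, low_limit_g = 100, window_h = 20)
  expect_equal(fc$rate_g_per_h, 10, tolerance = 1e-9)
  expect_equal(fc$rate_ml_per_h, 10, tolerance = 1e-9)
  expect_equal(fc$eta_h, 80, tolerance = 1e-9)

  flat <- data.frame(t_h = 0:5, weight_g = rep(800, 6))
  expect_equal(forecast_empty(flat, 100)$eta_h, Inf)
  expect_error(forecast_empty(ser[1, ], 100), "two scale samples")
  expect_error(forecast_empty(data.frame(t_h = c(1, 1), weight_g = c(2, 1)),
                              0), "increasing")
  # eta is monotone decreasing in consumption rate at fixed weight
  etas <- vapply(c(5, 10, 20), function(r) {
    s <- data.frame(t_h = 0:10, weight_g = 1000 - r * (0:10))
    forecast_empty(s, 100)$eta_h
  }, numeric(1))
  expect_true(all(diff(etas) < 0))
})

test_that("ledger-driven synthetic weights agree with the forecast arithmetic", {
  led <- make_ledger()
  ev <- data.frame(vial_id = rep("v1", 12),
                   commanded_volume_ml = rep(15, 12),
                   t_end_h = seq(0.5, 6, by = 0.5))
  led <- record_consumption(led, ev)
  ser <- ledger_weight_series(led, "b1", seq(0, 6, by = 0.25))
  expect_equal(ser$weight_g[1], 1000)
  expect_equal(ser$weight_g[nrow(ser)], 1000 - 180)
  fc <- forecast_empty(ser, low_limit_g = 100)
  expect_equal(fc$rate_ml_per_h, 30, tolerance = 0.02 * 30)
})

test_that("alerts respect the 10-minute pause rule and fire once per episode", {
  mon <- alert_monitor()
  state9 <- list(paused_since_h = 0)
  expect_length(check_alerts(mon, state9, now_h = 9 / 60)$events, 0)
  r11 <- check_alerts(mon, state9, now_h = 11 / 60)
  expect_equal(r11$events[[1]]$kind, "paused_too_long")
  # still paused at 12 min: no re-fire
  r12 <- check_alerts(r11$monitor, state9, now_h = 12 / 60)
  expect_length(r12$events, 0)
  # resume clears the episode; a fresh pause fires again
  r_clear <- check_alerts(r12$monitor, list(paused_since_h = NA), 1)
  r_new <- check_alerts(r_clear$monitor, list(paused_since_h = 2), 2.5)
  expect_equal(r_new$events[[1]]$kind, "paused_too_long")
})

test_that("low-medium, power-loss and dilution-failure conditions alert", {
  mon <- alert_monitor()
  st <- list(weights_g = c(b1 = 90, b2 = 500),
             low_limits_g = c(b1 = 100, b2 = 100),
             scale_last_seen_h = 0,
             dilution_failed_vials = "v2")
  r <- check_alerts(mon, st, now_h = 0.5)
  kinds <- vapply(r$events, `[[`, "", "kind")
  expect_setequal(kinds, c("low_medium", "power_loss", "dilution_failure"))
  expect_length(check_alerts(r$monitor, st, now_h = 0.6)$events, 0)
})

test_that("notifier failures are logged but never fatal", {
  boom <- function(event) stop("webhook down")
  mon <- alert_monitor(notifier = boom)
  expect_message(
    r <- check_alerts(mon, list(paused_since_h = 0), now_h = 1),
    "notifier failed")
  expect_equal(r$events[[1]]$kind, "paused_too_long")

  path <- withr::local_tempfile(fileext = ".jsonl")
  mon2 <- alert_monitor(notifier = file_notifier(path))
  check_alerts(mon2, list(paused_since_h = 0), now_h = 1)
  expect_equal(jsonlite::fromJSON(readLines(path)[1])$kind,
               "paused_too_long")
})

test_that("the consumption report renders vial totals and bottle forecasts", {
  led <- make_ledger()
  led <- record_consumption(led, data.frame(vial_id = "v1",
                                            commanded_volume_ml = 120,
                                            t_end_h = 6))
  lines <- capture.output(consumption_report(led))
  expect_true(any(grepl("v1", lines)))
  expect_true(any(grepl("b2", lines) & grepl("inf", lines)))
})
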