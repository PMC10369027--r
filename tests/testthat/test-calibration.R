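test_that("inoculation planning solves the dilution algebra", {
  # single PBS step
  p0 <- plan_inoculation(0, 25, 20)
  expect_equal(nrow(p0$steps), 1)
  expect_equal(p0$steps$added_volume_ml, 0)
  expect_equal(p0$steps$nominal_od, 0)

  # cumulative stock volume solves S*v/(V+v) = od
  p <- plan_inoculation(c(0, 0.2), 25, 20)
  expect_equal(p$steps$cumulative_stock_volume_ml[2], 0.2 * 25 / 19.8,
               tolerance = 1e-12)
  expect_equal(p$steps$nominal_od, c(0, 0.2), tolerance = 1e-12)

  # consecutive equal targets add nothing
  pe <- plan_inoculation(c(0, 0.2, 0.2), 25, 20)
  expect_equal(pe$steps$added_volume_ml[3], 0)

  # invariants: strictly increasing cumulative quantities, fraction identity
  pl <- plan_inoculation(c(0, 0.05, 0.1, 0.2, 0.4, 0.8), 25, 20)
  expect_true(all(diff(pl$steps$cumulative_stock_volume_ml) > 0))
  expect_equal(pl$steps$cumulative_fraction,
               pl$steps$cumulative_stock_volume_ml /
                 (25 + pl$steps$cumulative_stock_volume_ml))
  expect_equal(pl$steps$nominal_od, 20 * pl$steps$cumulative_fraction)

  expect_error(plan_inoculation(c(0, 0.3, 0.2), 25, 20), "non-decreasing")
  expect_error(plan_inoculation(c(0, 0.8), 25, 10), "concentrated")
})

test_that("stock back-calculation inverts the dilution factor and is scale-consistent", {
  # plan whose final cumulative fraction is exactly 0.03
  V <- 25; f <- 0.03; v <- f * V / (1 - f); S <- 20
  od_final <- S * v / (V + v)
  plan <- plan_inoculation(c(0, od_final / 2, od_final), V, S)
  expect_equal(plan$steps$cumulative_fraction[3], f, tolerance = 1e-12)

  bc <- backcalculate_stock(plan, 0.618)
  expect_equal(bc$stock_od_actual, 20.6, tolerance = 1e-12)
  expect_equal(bc$corrected_ods[1], 0)  # PBS point stays zero
  expect_equal(bc$corrected_ods, plan$steps$nominal_od * 20.6 / 20,
               tolerance = 1e-12)

  # measurements matching the nominal prediction change nothing
  bc0 <- backcalculate_stock(plan, od_final)
  expect_equal(bc0$corrected_ods, plan$steps$nominal_od, tolerance = 1e-12)

  # scale consistency: k on measurements is k on stock and every point
  k <- 1.37
  bck <- backcalculate_stock(plan, 0.618 * k)
  expect_equal(bck$stock_od_actual, 20.6 * k, tolerance = 1e-12)
  expect_equal(bck$corrected_ods, bc$corrected_ods * k, tolerance = 1e-12)

  expect_error(backcalculate_stock(plan, numeric(0)), "no endpoint")
  expect_error(backcalculate_stock(plan_inoculation(0, 25, 20), 0.5),
               "final cumulative fraction")
})

test_that("calibration correction rescales ODs in place and guards the layout", {
  ds <- new_calibration_dataset("s1", "v1", 2L,
                                raw_mean = c(41270, 41000, 40600, 40100,
                                             39500, 38800),
                                raw_sd = rep(20, 6),
                                nominal_od = c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(ds$raw_0_cal, 41270)
  cor_ods <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5) * 1.03
  ds2 <- correct_calibration(ds, cor_ods)
  expect_true(ds2$corrected)
  expect_equal(ds2$points$corrected_od, cor_ods)
  expect_equal(ds2$points$raw_mean, ds$points$raw_mean)  # raws untouched
  expect_equal(ds2$order_map, 1:6)  # fixed-vial: identity reordering

  expect_error(correct_calibration(ds, cor_ods[-1]), "length mismatch")
  expect_error(correct_calibration(ds, c(0.05, cor_ods[-1])), "PBS")
  expect_error(new_calibration_dataset("s1", "v1", 2L, 41270, 20, 0.1),
               "PBS")
  # non-monotone raws beyond the gate are flagged, not rejected
  ds_bad <- new_calibration_dataset("s1", "v1", 2L,
                                    raw_mean = c(41270, 40600, 41050, 40100,
                                                 39500, 38800),
                                    raw_sd = rep(20, 6),
                                    nominal_od = c(0, 0.1, 0.2, 0.3, 0.4, 0.5))
  expect_warning(correct_calibration(ds_bad, cor_ods), "monotone")
})

test_that("curve fitting is deterministic and noise-free fits anchor at zero", {
  optics <- quiet_optics()
  vial <- fixed_vial(glass_offset = 150)
  set.seed(1)
  c1 <- exact_curve(optics, vial)
  set.seed(99)  # no stochastic restarts: RNG state must not matter
  c2 <- exact_curve(optics, vial)
  expect_identical(c1$params, c2$params)
  expect_lt(abs(od_from_raw(c1, c1$raw_0_cal)), 1e-6)
  expect_equal(unname(c1$params["amp"]), 15000, tolerance = 1e-3)

  ds <- new_calibration_dataset("s1", "v1", 2L, c(41270, 41000, 40600),
                                rep(20, 3), c(0, 0.1, 0.2))
  ds <- correct_calibration(ds, c(0, 0.1, 0.2))
  expect_error(fit_curve(ds), "at least 5")
})

test_that("noisy calibrations stay accurate at the calibration points", {
  set.seed(21)
  med_err <- replicate(40, {
    optics <- noisy_optics(noise_sd = 50)
    vial <- fixed_vial(glass_offset = rnorm(1, 0, 250))
    plan <- plan_inoculation(c(0, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5, 0.65,
                               0.8), 25, 20)
    sim <- simulate_calibration(optics, vial, plan, stock_od_actual = 20.6)
    bc <- backcalculate_stock(plan, sim$measured_final_od)
    ds <- correct_calibration(sim$dataset, bc$corrected_ods)
    cv <- fit_curve(ds)
    pts <- ds$points[ds$points$corrected_od <= 0.6 &
                     ds$points$corrected_od > 0, ]
    median(abs(od_from_raw(cv, pts$raw_mean) - pts$corrected_od))
  })
  expect_lt(median(med_err), 0.01)
})

test_that("LED-power selection maximises worst-case slope with low-power ties", {
  set.seed(5)
  curves <- lapply(1:3, function(p)
    exact_curve(quiet_optics(sprintf("s%d", p), led_power = p),
                fixed_vial()))
  names(curves) <- 1:3
  expect_equal(select_led_power(curves), 3L)  # steepest by construction
  expect_equal(select_led_power(curves["2"]), 2L)
  expect_equal(select_led_power(list(`2` = curves[[2]], `3` = curves[[2]])),
               2L)  # identical curves: lower power wins
  expect_error(select_led_power(curves, od_window = c(2, 3)), "outside")
})

test_that("calibration datasets round-trip through delimited text", {
  optics <- quiet_optics(); vial <- fixed_vial()
  plan <- plan_inoculation(c(0, 0.1, 0.2, 0.4, 0.6, 0.8), 25, 20)
  sim <- simulate_calibration(optics, vial, plan, spectro_sd = 0)
  ds <- correct_calibration(sim$dataset,
                            backcalculate_stock(plan,
                                                sim$measured_final_od)$corrected_ods)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calibration_dataset(ds, path)
  back <- read_calibration_dataset(path)
  expect_equal(back$points, ds$points, tolerance = 1e-9)
  expect_equal(back$raw_0_cal, ds$raw_0_cal)
  expect_true(back$corrected)
})

test_that("the calibration store enforces lifecycle rules", {
  cv <- exact_curve()
  st <- calibration_store()
  st <- store_add(st, cv, id = "s1:v1")
  expect_equal(store_list(st), "s1:v1")
  expect_equal(store_get(st, "s1:v1")$params, cv$params)

  st <- store_mark_active(st, "s1:v1")
  expect_error(delete_calibration(st, "s1:v1"), "in use")
  st <- store_release(st, "s1:v1")
  st <- delete_calibration(st, "s1:v1")
  expect_length(store_list(st), 0)
  expect_error(delete_calibration(st, "nope"), "unknown")

  # JSON persistence round-trip
  st2 <- store_add(calibration_store(), cv, id = "s1:v1")
  path <- withr::local_tempfile(fileext = ".json")
  save_store(st2, path)
  st3 <- load_store(path)
  expect_equal(store_get(st3, "s1:v1")$params, cv$params, tolerance = 1e-12)
  expect_equal(od_from_raw(store_get(st3, "s1:v1"), cv$raw_0_cal - 2000),
               od_from_raw(cv, cv$raw_0_cal - 2000), tolerance = 1e-12)
})

test_that("media table reports water-referenced differences and equivalence", {
  eq <- media_equivalence()
  expect_equal(eq$difference_raw[eq$solution == "water"], 0)
  expect_true(all(c("PBS", "EMM", "EMM6S", "YE4S") %in% eq$solution))
  # simulator construction: PBS and medium share the optics map, so their
  # raws differ only by noise
  set.seed(8)
  optics <- noisy_optics(noise_sd = 50)
  vial <- fixed_vial()
  raw_pbs <- median(measure_raw(optics, vial, NULL, 5))
  raw_med <- median(measure_raw(optics, vial, NULL, 5))
  expect_true(check_media_equivalence(raw_pbs, raw_med, 50))
})
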