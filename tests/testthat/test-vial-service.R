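test_that("a replacement vial with the old offset displays zero immediately", {
  optics <- quiet_optics()
  old_vial <- fixed_vial(glass_offset = 200)
  cv <- exact_curve(optics, old_vial)
  bl <- exact_blank(optics, old_vial)
  new_vial <- fixed_vial("v1", glass_offset = 200)
  raw_live <- measure_raw(optics, new_vial, NULL)
  expect_lt(abs(display_od(raw_live, bl, cv)), 1e-6)
})

test_that("an offset change shows up in the display scaled by the curve slope", {
  optics <- quiet_optics()
  old_vial <- fixed_vial(glass_offset = 0)
  cv <- exact_curve(optics, old_vial)
  bl <- exact_blank(optics, old_vial)
  raw_live <- measure_raw(optics, fixed_vial("v1", glass_offset = 300), NULL)
  od_disp <- display_od(raw_live, bl, cv)
  expect_gt(abs(od_disp), 0.01)
  expect_equal(od_disp, 300 / curve_slope(cv, 0), tolerance = 0.15)
})

test_that("rotation can equilibrate a close-enough vial under the auto gate", {
  set.seed(41)
  optics <- noisy_optics()
  old_vial <- fixed_vial(glass_offset = 0)
  cv <- calibrate_sleeve(optics, old_vial)
  bl <- record_blank("v1", measure_raw(optics, old_vial, NULL, 5))
  done <- replicate(20, {
    new_vial <- fixed_vial("v1", glass_offset = rnorm(1, 0, 150),
                           rotation_sd = 100)
    ses <- replacement_session("v1", bl, cv, auto_gate = 0.01)
    res <- equilibrate_monitor(ses, new_rig(optics, new_vial, NULL),
                               max_rotations = 100)
    identical(res$session$decision, "equilibrated")
  })
  expect_gt(mean(done), 0.5)  # usually reachable, not guaranteed
})

test_that("blank reset exactly cancels an additive offset change", {
  optics <- quiet_optics()
  old_vial <- fixed_vial(glass_offset = -100)
  cv <- exact_curve(optics, old_vial)
  bl_old <- exact_blank(optics, old_vial)
  for (doff in c(-500, -200, 100, 300, 500)) {
    new_vial <- fixed_vial("v1", glass_offset = -100 + doff)
    ses <- replacement_session("v1", bl_old, cv)
    res <- reset_blank(ses, rep(measure_raw(optics, new_vial, NULL), 3))
    # medium-only reading: OD back to zero by construction
    raw_med <- measure_raw(optics, new_vial, NULL)
    expect_lt(abs(compute_od(raw_med, res$blank, cv)$od), 1e-6)
    # inoculated culture read accurately through the new blank
    raw_035 <- measure_raw(optics, new_vial, true_culture(0.35))
    expect_lt(abs(compute_od(raw_035, res$blank, cv)$od - 0.35), 1e-3)
  }
})

test_that("skipping the reset after a large swap leaves a real OD error", {
  set.seed(43)
  optics <- noisy_optics()
  old_vial <- fixed_vial(glass_offset = 0)
  cv <- calibrate_sleeve(optics, old_vial)
  bl_old <- record_blank("v1", measure_raw(optics, old_vial, NULL, 5))
  new_vial <- fixed_vial("v1", glass_offset = 500)
  raw <- median(measure_raw(optics, new_vial, true_culture(0.35), 5))
  err_skip <- abs(compute_od(raw, bl_old, cv)$od - 0.35)
  ses <- replacement_session("v1", bl_old, cv)
  res <- reset_blank(ses, measure_raw(optics, new_vial, NULL, 5))
  err_reset <- abs(compute_od(raw, res$blank, cv)$od - 0.35)
  expect_gt(err_skip, 0.02)
  expect_lt(err_reset, 0.01)
})

test_that("sessions record exactly one decision and write an audit line", {
  cv <- exact_curve(); bl <- exact_blank()
  ses <- replacement_session("v1", bl, cv)
  res <- reset_blank(ses, rep(41500, 3))
  expect_equal(res$session$decision, "blank_reset")
  expect_error(reset_blank(res$session, rep(41500, 3)), "already")

  path <- withr::local_tempfile(fileext = ".jsonl")
  write_replacement_audit(res$session, path)
  rec <- jsonlite::fromJSON(readLines(path)[1])
  expect_equal(rec$decision, "blank_reset")
  expect_equal(rec$raw_blank_new, 41500)
  expect_error(write_replacement_audit(replacement_session("v1", bl, cv),
                                       path), "no decision")
})

test_that("servicing one vial leaves another vial's log byte-identical", {
  optics <- quiet_optics()
  vial_a <- fixed_vial("A", glass_offset = 50)
  cv_a <- exact_curve(optics, vial_a)
  bl_a <- exact_blank(optics, vial_a)
  cfg <- controller_config(ht = 0.5, lt = 0.3)

  log_a <- function() {
    set.seed(77)  # vial A's own measurement stream
    run <- run_turbidostat(new_rig(noisy_optics("s1"), vial_a,
                                   true_culture(0.4)), bl_a, cv_a, cfg, 2)
    dir <- withr::local_tempdir()
    r <- compute_od(run$trace$raw, bl_a, cv_a, timestamp = run$trace$t_h,
                    check_vial = FALSE)
    write_od_log(r, dir)
    readBin(file.path(dir, "od_A.tsv"), "raw",
            file.size(file.path(dir, "od_A.tsv")))
  }
  before <- log_a()
  # replacement on vial B, with its own RNG stream
  set.seed(78)
  vial_b <- fixed_vial("B", glass_offset = 400)
  ses <- replacement_session("B", record_blank("B", rep(41600, 3)), cv_a)
  reset_blank(ses, measure_raw(noisy_optics("s2"), vial_b, NULL, 5))
  after <- log_a()
  expect_identical(before, after)
})

test_that("mid-run vial addition requires a pre-experiment calibration", {
  ex <- new_experiment(calibrated_vials = c("v1", "v2", "v3"),
                       active_vials = c("v1", "v2"))
  ex <- add_vial_midrun(ex, "v3")
  expect_true("v3" %in% ex$active)
  expect_error(add_vial_midrun(ex, "v4"), "no pre-experiment calibration")
  expect_error(add_vial_midrun(ex, "v3"), "already active")
})
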