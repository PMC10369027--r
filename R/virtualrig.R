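# ---- virtual rig: ground-truth optics, vials, cultures, pumps ----------------

#' Ground-truth optics of one smart sleeve
#'
#' The virtual rig models the raw light-scattering signal of a sleeve as a
#' strictly monotone saturating map of culture optical density,
#' `raw_true = g(OD) = base + amp / (1 + exp(steep * (OD - mid)))`,
#' with additive Gaussian sensor noise. With `steep > 0` the raw signal
#' decreases as OD rises; downstream code never assumes the sign, only
#' monotonicity. The amplitude scales with LED power, so a higher LED power
#' strictly increases the worst-case slope `min |dg/dOD|` over the working
#' window (OD 0.2-0.5) -- the property the LED-power selector exploits.
#'
#' @param sleeve_id identifier of the sleeve.
#' @param led_power integer LED power setting (>= 1).
#' @param curve_params named numeric vector `c(base, amp, mid, steep)`;
#'   defaults to [optics_params()] at `led_power`.
#' @param noise_sd standard deviation of the sensor noise, raw units.
#' @return An object of class `true_optics`.
#' @export
true_optics <- function(sleeve_id, led_power = 2L, curve_params = NULL,
                        noise_sd = 50) {
  stopifnot(noise_sd >= 0, led_power >= 1)  # 0 = noise-free limit for tests
  if (is.null(curve_params)) curve_params <- optics_params(led_power)
  stopifnot(all(c("base", "amp", "mid", "steep") %in% names(curve_params)))
  structure(list(sleeve_id = sleeve_id, led_power = as.integer(led_power),
                 curve_params = curve_params, noise_sd = noise_sd),
            class = "true_optics")
}

#' Default optics curve parameters for a given LED power
#'
#' Defaults place the blank (OD 0) raw value near 41,000 -- the scale of a
#' 16-bit scattering ADC -- and make the dynamic range proportional to LED
#' power.
#'
#' @param led_power integer LED power setting.
#' @return Named numeric vector `c(base, amp, mid, steep)`.
#' @export
optics_params <- function(led_power = 2L) {
  c(base = 28400, amp = 7500 * as.numeric(led_power), mid = 0.30, steep = 6)
}

#' True (noise-free) sleeve response and its slope
#'
#' @param optics a [true_optics()] object.
#' @param od optical density value(s).
#' @return `optics_response`: raw value(s); `optics_slope`: d raw / d OD.
#' @export
optics_response <- function(optics, od) {
  p <- optics$curve_params
  p[["base"]] + p[["amp"]] / (1 + exp(p[["steep"]] * (od - p[["mid"]])))
}

#' @rdname optics_response
#' @export
optics_slope <- function(optics, od) {
  p <- optics$curve_params
  s <- 1 / (1 + exp(p[["steep"]] * (od - p[["mid"]])))
  -p[["amp"]] * p[["steep"]] * s * (1 - s)
}

#' Invert the true optics map (ground truth only)
#'
#' Used by tests to check that a noise-free, offset-free measurement composed
#' with the true inverse recovers `od_true` to machine precision. Experiment
#' code never sees this function; it works from fitted calibration curves.
#'
#' @param optics a [true_optics()] object.
#' @param raw raw value(s) strictly inside `(base, base + amp)`.
#' @return OD value(s).
#' @export
optics_inverse <- function(optics, raw) {
  p <- optics$curve_params
  p[["mid"]] + log(p[["amp"]] / (raw - p[["base"]]) - 1) / p[["steep"]]
}

#' One culture vessel with its glass signature
#'
#' Each glass vial contributes a purely additive offset to the raw signal,
#' redrawn only on explicit rotation or swap events. `rotation_sd` is chosen
#' well above the sensor noise so that rotating a vial between acquisitions
#' inflates the measurement variance detectably.
#'
#' @param vial_id identifier.
#' @param glass_offset additive raw offset of this vial; if `NULL`, drawn
#'   from Normal(0, `offset_sd`).
#' @param rotation_sd SD of the offset step applied per rotation, raw units.
#' @param volume_ml working culture volume, mL.
#' @param offset_sd SD of the vial-to-vial offset distribution, raw units.
#' @param influx_efficiency fraction of commanded medium actually delivered
#'   (1 = healthy pump; < 1 injects a dilution fault).
#' @return An object of class `true_vial`.
#' @export
true_vial <- function(vial_id, glass_offset = NULL, rotation_sd = 100,
                      volume_ml = 25, offset_sd = 250,
                      influx_efficiency = 1) {
  stopifnot(volume_ml > 0, rotation_sd >= 0,
            influx_efficiency >= 0, influx_efficiency <= 1)
  if (is.null(glass_offset)) glass_offset <- stats::rnorm(1, 0, offset_sd)
  structure(list(vial_id = vial_id, glass_offset = glass_offset,
                 rotation_sd = rotation_sd, volume_ml = volume_ml,
                 influx_efficiency = influx_efficiency),
            class = "true_vial")
}

#' An exponentially growing culture
#'
#' @param od_true current true optical density (>= 0).
#' @param doubling_time_h doubling time in hours (> 0). The default, 2.5 h,
#'   is typical of fission yeast in minimal medium at 32 C.
#' @param stress_factor multiplier in (0, 1] applied to the growth rate;
#'   time-varying stress scenarios rescale it between steps.
#' @return An object of class `true_culture`.
#' @export
true_culture <- function(od_true = 0.2, doubling_time_h = 2.5,
                         stress_factor = 1) {
  stopifnot(od_true >= 0, doubling_time_h > 0,
            stress_factor > 0, stress_factor <= 1)
  structure(list(od_true = od_true, doubling_time_h = doubling_time_h,
                 stress_factor = stress_factor),
            class = "true_culture")
}

#' Advance a culture by pure exponential growth
#'
#' `od' = od * 2^(dt * stress_factor / doubling_time_h)`. Growth is
#' memoryless: advancing by `t1` then `t2` equals advancing by `t1 + t2`.
#'
#' @param culture a [true_culture()] object.
#' @param dt_h elapsed time in hours (>= 0).
#' @return The advanced culture.
#' @export
advance <- function(culture, dt_h) {
  if (dt_h < 0) stop("dt_h must be non-negative")
  culture$od_true <- culture$od_true *
    2^(dt_h * culture$stress_factor / culture$doubling_time_h)
  culture
}

#' Measure raw light scattering of a vial in a sleeve
#'
#' Returns `g(od_true) + glass_offset + eps`, `eps ~ Normal(0, noise_sd)`.
#' Draws come from the session RNG; seed scenarios with [set.seed()] or
#' `withr::with_seed()` for exact replay.
#'
#' @param optics a [true_optics()] object.
#' @param vial a [true_vial()] object.
#' @param culture a [true_culture()] object, or `NULL` for a cell-free vial
#'   (PBS or plain medium, OD 0).
#' @param n number of consecutive reads.
#' @return Numeric vector of `n` raw values.
#' @export
measure_raw <- function(optics, vial, culture = NULL, n = 1L) {
  od <- if (is.null(culture)) 0 else culture$od_true
  optics_response(optics, od) + vial$glass_offset +
    stats::rnorm(n, 0, optics$noise_sd)
}

#' Rotate a vial a few degrees inside its sleeve
#'
#' Each rotation perturbs the glass offset by an independent step
#' `delta ~ Normal(0, rotation_sd)`; successive rotations accumulate. The
#' redraw is independent of the culture state.
#'
#' @param vial a [true_vial()] object.
#' @return The vial with updated `glass_offset`.
#' @export
rotate <- function(vial) {
  vial$glass_offset <- vial$glass_offset + stats::rnorm(1, 0, vial$rotation_sd)
  vial
}

#' Dilute a culture by an instantaneous medium bolus
#'
#' The efflux pump runs concomitantly, so the working volume is conserved and
#' the OD scales by `volume / (volume + v_add)` (ratio dilution). A continuous
#' co-flow (exponential washout) model is available for comparison.
#'
#' @param vial a [true_vial()] object.
#' @param culture a [true_culture()] object.
#' @param v_add_ml volume of medium added, mL (>= 0).
#' @param model `"bolus"` (default) or `"coflow"` (exponential washout
#'   `od * exp(-v_add / volume)`).
#' @return The diluted culture.
#' @export
bolus_dilute <- function(vial, culture, v_add_ml, model = c("bolus", "coflow")) {
  model <- match.arg(model)
  if (v_add_ml < 0) stop("v_add_ml must be non-negative")
  if (vial$volume_ml <= 0) stop("vial volume must be positive")
  culture$od_true <- if (model == "bolus") {
    culture$od_true * vial$volume_ml / (vial$volume_ml + v_add_ml)
  } else {
    culture$od_true * exp(-v_add_ml / vial$volume_ml)
  }
  culture
}

# ---- rig bundle and scenario i/o --------------------------------------------

#' Bundle optics, vial and culture into one rig state
#'
#' @param optics,vial,culture rig components.
#' @return An object of class `rig`.
#' @export
new_rig <- function(optics, vial, culture) {
  structure(list(optics = optics, vial = vial, culture = culture),
            class = "rig")
}

#' Load a simulation scenario from YAML/JSON
#'
#' A scenario names the sleeves, vials and cultures, the sampling cadence and
#' the RNG seed, so every simulated dataset is exactly replayable. Fields
#' mirror the arguments of [true_optics()], [true_vial()] and
#' [true_culture()]; `cadence_s` defaults to 16 s.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A list with elements `rigs` (list of [new_rig()] states),
#'   `cadence_s` and `seed`.
#' @export
load_scenario <- function(path) {
  sc <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
        else yaml::read_yaml(path)
  cadence_s <- if (is.null(sc$cadence_s)) 16 else sc$cadence_s
  seed <- if (is.null(sc$seed)) 1L else as.integer(sc$seed)
  set.seed(seed)
  rigs <- lapply(sc$vials, function(v) {
    sl <- sc$sleeves[[v$sleeve]]
    optics <- true_optics(v$sleeve,
                          led_power = if (is.null(sl$led_power)) 2L else sl$led_power,
                          noise_sd = if (is.null(sl$noise_sd)) 50 else sl$noise_sd)
    vial <- true_vial(v$id,
                      glass_offset = v$glass_offset,
                      volume_ml = if (is.null(v$volume_ml)) 25 else v$volume_ml)
    cu <- v$culture
    culture <- true_culture(od_true = if (is.null(cu$od)) 0.2 else cu$od,
                            doubling_time_h = if (is.null(cu$doubling_time_h)) 2.5
                                              else cu$doubling_time_h,
                            stress_factor = if (is.null(cu$stress_factor)) 1
                                            else cu$stress_factor)
    new_rig(optics, vial, culture)
  })
  list(rigs = rigs, cadence_s = cadence_s, seed = seed)
}

#' Write a simulated trajectory as delimited text
#'
#' One row per reading: ISO-8601 timestamp, vial id, raw value, true OD and
#' (when present) the engine's OD estimate.
#'
#' @param trace data frame with columns `t_h`, `raw`, `od_true` and
#'   optionally `od`.
#' @param path output file path (tab-separated).
#' @param vial_id vial identifier recorded in each row.
#' @param start_time POSIXct experiment start used to render timestamps.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, vial_id,
                        start_time = as.POSIXct("2026-01-01 00:00:00", tz = "UTC")) {
  out <- data.frame(
    timestamp = format(start_time + trace$t_h * 3600, "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    vial_id = vial_id, raw = trace$raw, od_true = trace$od_true)
  if (!is.null(trace$od)) out$od <- trace$od
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
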