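# ---- sleeve temperature calibration -----------------------------------------

#' Plan a three-point sleeve temperature calibration
#'
#' Culture temperature is inferred from a sensor on the sleeve surface, so
#' the surface-to-culture relationship must be calibrated per sleeve. The
#' plan uses three setpoints at room temperature and moderate elevations --
#' RT, RT+6 and RT+12 C -- which stay inside the physiological range of
#' yeast growth (25-32 C) and are reliably reachable even in warm rooms,
#' unlike larger elevations.
#'
#' @param room_temp_c room temperature, Celsius.
#' @param offset_c optional constant correction added to commanded targets:
#'   if the culture equilibrates below the target by a known constant, the
#'   commanded setpoint is `requested + offset_c` (see
#'   [commanded_temp_target()]).
#' @return An object of class `temp_cal_plan` with `setpoints_c` exactly
#'   `c(RT, RT + 6, RT + 12)`.
#' @export
plan_temp_calibration <- function(room_temp_c, offset_c = 0) {
  stopifnot(is.finite(room_temp_c))
  structure(list(room_temp_c = room_temp_c,
                 elevations_c = c(0, 6, 12),
                 setpoints_c = room_temp_c + c(0, 6, 12),
                 offset_c = offset_c,
                 coefficients = NULL),
            class = "temp_cal_plan")
}

#' Fit the surface-to-culture temperature map
#'
#' Ordinary least squares of the reference (in-culture) temperature on the
#' sleeve-surface reading, over the three stabilised setpoints.
#'
#' @param surface_c surface-sensor readings, Celsius (length >= 3).
#' @param reference_c matched reference (immersed-sensor) temperatures,
#'   strictly increasing.
#' @return Named numeric vector `c(intercept, slope)`; the slope must be
#'   positive.
#' @export
fit_temp_map <- function(surface_c, reference_c) {
  if (length(surface_c) < 3 || length(reference_c) < 3)
    stop("at least three (surface, reference) pairs are required")
  if (length(surface_c) != length(reference_c)) stop("length mismatch")
  if (any(diff(reference_c) <= 0))
    stop("reference temperatures must be strictly increasing")
  cf <- stats::coef(stats::lm(reference_c ~ surface_c))
  if (cf[[2]] <= 0) stop("fitted slope is not positive")
  c(intercept = unname(cf[[1]]), slope = unname(cf[[2]]))
}

#' Commanded setpoint for a requested culture temperature
#'
#' When a constant residual offset has been measured for a vial (culture
#' running `offset_c` below target on average), the commanded target is the
#' requested temperature plus that offset.
#'
#' @param requested_c requested culture temperature, Celsius.
#' @param offset_c measured constant offset, Celsius (default 0).
#' @return Commanded setpoint, Celsius.
#' @export
commanded_temp_target <- function(requested_c, offset_c = 0) {
  requested_c + offset_c
}
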