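# ---- delta-raw OD engine ----------------------------------------------------

#' Record the medium blank of a vial
#'
#' An experiment starts with blank measurements of the medium-filled vials.
#' The blank raw value is the median of the reads; the read dispersion
#' (range) must stay under `gate` -- a larger spread suggests the vial is
#' not seated and should be re-seated before blanking. The legacy-path
#' `od_blank` (`f(raw_blank)`) is stored when a curve is supplied, for
#' comparison studies only.
#'
#' @param vial_id vial identifier.
#' @param raws raw reads of the medium-only vial (>= 3 recommended; a single
#'   read is accepted with a warning).
#' @param gate maximum allowed dispersion (max - min), raw units.
#' @param curve optional [fit_curve()] result used to store `od_blank`.
#' @param timestamp record timestamp.
#' @return An object of class `blank_record`.
#' @export
record_blank <- function(vial_id, raws, gate = 300, curve = NULL,
                         timestamp = Sys.time()) {
  if (length(raws) == 0L) stop("no blank reads given")
  disp <- diff(range(raws))
  if (disp > gate)
    stop(sprintf(
      "blank dispersion %.0f exceeds gate %.0f raw units; re-seat the vial and re-measure",
      disp, gate))
  if (length(raws) < 3)
    warning("blank recorded from fewer than 3 reads")
  raw_blank <- stats::median(raws)
  structure(list(vial_id = vial_id, raw_blank = raw_blank,
                 dispersion = disp, n_reads = length(raws),
                 od_blank = if (is.null(curve)) NA_real_
                            else od_from_raw(curve, raw_blank),
                 timestamp = timestamp),
            class = "blank_record")
}

#' Compute culture OD by the delta-raw method
#'
#' The raw difference `delta_raw = raw_t - raw_blank` is measured on one and
#' the same fixed vial, so it reflects only the change in culture density --
#' the additive glass-vial offset cancels exactly. Transposing the
#' difference onto the calibration curve's PBS anchor,
#' `raw_final = raw_0_cal + delta_raw`, and evaluating `OD = f(raw_final)`
#' yields an OD estimate invariant to any constant shift applied to both
#' `raw_t` and `raw_blank`.
#'
#' Slightly negative ODs are reported as-is (clamping would hide noise from
#' the controller); values below -0.02 are flagged. Readings whose
#' `raw_final` leaves the calibrated raw range carry an extrapolation flag,
#' and raw values outside the invertible domain of the curve are an error.
#'
#' @param raw_t raw reading(s) at time t.
#' @param blank a [record_blank()] result for the same vial.
#' @param curve a [fit_curve()] result for the same vial.
#' @param timestamp reading timestamp(s) (any vector, carried through).
#' @param check_vial require `blank` and `curve` to name the same vial.
#' @return Data frame of class `od_reading` with columns `vial_id`,
#'   `timestamp`, `raw`, `delta_raw`, `od`, `extrapolated`, `flag_negative`.
#' @export
compute_od <- function(raw_t, blank, curve, timestamp = NA,
                       check_vial = TRUE) {
  if (check_vial && !identical(blank$vial_id, curve$vial_id))
    stop(sprintf("blank (%s) and calibration (%s) refer to different vials",
                 blank$vial_id, curve$vial_id))
  delta <- raw_t - blank$raw_blank
  raw_final <- curve$raw_0_cal + delta
  od <- od_from_raw(curve, raw_final)
  if (anyNA(od) || any(!is.finite(od)))
    stop("raw value outside the invertible range of the calibration curve")
  out <- data.frame(
    vial_id = blank$vial_id, timestamp = timestamp, raw = raw_t,
    delta_raw = delta, od = od,
    extrapolated = raw_final < curve$valid_raw_range[1] |
                   raw_final > curve$valid_raw_range[2],
    flag_negative = od < -0.02)
  class(out) <- c("od_reading", class(out))
  out
}

#' Legacy OD calculation (difference of calibrated ODs)
#'
#' The historical path computes `f(raw_t) - f(raw_blank)`: both terms pass
#' through the curve separately, so any glass-vial offset common to the two
#' raw values is distorted by the curve's nonlinearity instead of
#' cancelling. Kept for comparison studies; for a perfectly linear curve it
#' coincides with the delta-raw method.
#'
#' @inheritParams compute_od
#' @return Numeric OD value(s).
#' @export
legacy_od <- function(raw_t, blank, curve) {
  od_from_raw(curve, raw_t) - od_from_raw(curve, blank$raw_blank)
}

#' Append OD readings to a per-vial log file
#'
#' One tab-separated file per vial (`od_<vial>.tsv`), append-only, columns
#' `timestamp, raw, delta_raw, od` -- mirroring an experiment-folder layout
#' with one OD file per culture position.
#'
#' @param readings an `od_reading` data frame from [compute_od()].
#' @param dir directory for the log files (created if needed).
#' @return The file path(s) written, invisibly.
#' @export
write_od_log <- function(readings, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (v in unique(readings$vial_id)) {
    path <- file.path(dir, sprintf("od_%s.tsv", v))
    sub <- readings[readings$vial_id == v,
                    c("timestamp", "raw", "delta_raw", "od")]
    utils::write.table(sub, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(path),
                       append = file.exists(path))
    paths <- c(paths, path)
  }
  invisible(paths)
}
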