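# ---- mid-experiment vial replacement ----------------------------------------

#' Open a vial-replacement session
#'
#' When a culture position fails (contamination, leak), the experiment for
#' that vial is paused, a fresh medium-filled vial is inserted, and its
#' apparent OD -- computed against the *old* medium blank, not the
#' calibration blank -- is watched while the vial is rotated toward zero.
#' If zero cannot be approached (glass vials differ widely), the blank is
#' reset instead. Exactly one decision (`"equilibrated"` or
#' `"blank_reset"`) closes a session; other vials are untouched.
#'
#' @param vial_id position being serviced.
#' @param blank_old the [record_blank()] in force before the swap.
#' @param curve the position's [fit_curve()] calibration (never refit
#'   mid-experiment: vial changes shift the raw signal by a constant
#'   offset only, which the blank absorbs).
#' @param auto_gate |OD| below which equilibration is auto-accepted
#'   (default 0.01; what counts as negligible is assay-specific).
#' @return An object of class `replacement_session`.
#' @export
replacement_session <- function(vial_id, blank_old, curve, auto_gate = 0.01) {
  stopifnot(auto_gate > 0)
  structure(list(vial_id = vial_id, blank_old = blank_old, curve = curve,
                 auto_gate = auto_gate, decision = NULL,
                 raw_blank_new = NA_real_, od_history = numeric(0),
                 timestamp = Sys.time(), note = NA_character_),
            class = "replacement_session")
}

#' Apparent OD of a replacement vial against the old medium blank
#'
#' `f(raw_0_cal + raw_live - raw_blank_old)`: the quantity a live display
#' shows during equilibration. The application's standard OD (referenced to
#' the calibration blank) cannot be used here.
#'
#' @param raw_live raw reading(s) of the new, medium-only vial.
#' @param blank_old the pre-swap [record_blank()].
#' @param curve the position's [fit_curve()] calibration.
#' @return Apparent OD value(s).
#' @export
display_od <- function(raw_live, blank_old, curve) {
  od_from_raw(curve, curve$raw_0_cal + raw_live - blank_old$raw_blank)
}

#' Rotate a replacement vial until its apparent OD is close enough to zero
#'
#' Each attempt takes `reads_per_check` consecutive reads of the medium-only
#' vial, displays the median's apparent OD, and accepts when its magnitude
#' falls below the session gate; otherwise the vial is rotated and tried
#' again. If the gate is never reached within `max_rotations`, the session
#' is left undecided and should proceed to [reset_blank()].
#'
#' @param session a [replacement_session()].
#' @param rig a [new_rig()] whose vial is the replacement (culture ignored;
#'   vial must be medium-only).
#' @param max_rotations attempts before giving up.
#' @param reads_per_check consecutive reads per attempt.
#' @return List: `session` (decision `"equilibrated"` when the gate was
#'   met; `od_history` holds every displayed OD) and `rig` (vial in its
#'   final orientation).
#' @export
equilibrate_monitor <- function(session, rig, max_rotations = 50L,
                                reads_per_check = 5L) {
  for (i in seq_len(max_rotations)) {
    raws <- measure_raw(rig$optics, rig$vial, culture = NULL,
                        n = reads_per_check)
    od_disp <- display_od(stats::median(raws), session$blank_old,
                          session$curve)
    session$od_history <- c(session$od_history, od_disp)
    if (is.finite(od_disp) && abs(od_disp) < session$auto_gate) {
      session$decision <- "equilibrated"
      session$note <- sprintf("equilibrated after %d orientation(s), |OD| = %.4f",
                              i, abs(od_disp))
      break
    }
    rig$vial <- rotate(rig$vial)
  }
  list(session = session, rig = rig)
}

#' Reset the calibration blank after a vial swap
#'
#' Different vials shift the raw scattering of a sleeve by a constant
#' offset only, so re-blanking on the new medium-filled vial restores OD
#' accuracy exactly: the delta-raw formula absorbs the offset and the
#' calibration curve is left untouched. All subsequent readings for this
#' position must use the returned blank.
#'
#' @param session a [replacement_session()] (not yet decided, or decided
#'   `"equilibrated"` in which case resetting is refused).
#' @param raws_new_medium raw reads of the new medium-only vial.
#' @param gate dispersion gate, as in [record_blank()].
#' @return List: `session` (decision `"blank_reset"`, `raw_blank_new`
#'   recorded) and `blank` (the new [record_blank()]).
#' @export
reset_blank <- function(session, raws_new_medium, gate = 300) {
  if (identical(session$decision, "equilibrated"))
    stop("session already closed as equilibrated; blank reset not needed")
  if (identical(session$decision, "blank_reset"))
    stop("blank already reset in this session")
  blank <- record_blank(session$vial_id, raws_new_medium, gate = gate)
  session$decision <- "blank_reset"
  session$raw_blank_new <- blank$raw_blank
  session$note <- sprintf("blank reset: %.0f -> %.0f raw",
                          session$blank_old$raw_blank, blank$raw_blank)
  list(session = session, blank = blank)
}

#' Append a closed replacement session to a JSON-lines audit log
#'
#' @param session a decided [replacement_session()].
#' @param path audit log file (one JSON object per line, appended).
#' @return `path`, invisibly.
#' @export
write_replacement_audit <- function(session, path) {
  if (is.null(session$decision)) stop("session has no decision to audit")
  rec <- list(vial_id = session$vial_id, decision = session$decision,
              raw_blank_old = session$blank_old$raw_blank,
              raw_blank_new = session$raw_blank_new,
              auto_gate = session$auto_gate,
              timestamp = format(session$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
              note = session$note)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      sep = "", file = path, append = TRUE)
  invisible(path)
}

# ---- experiment registry (mid-run vial addition) ----------------------------

#' Experiment registry of calibrated and active positions
#'
#' Positions must be calibrated before the experiment starts; cultures may
#' then be added mid-run by treating the addition as the replacement of a
#' failed vial.
#'
#' @param calibrated_vials vial ids calibrated before start.
#' @param active_vials vial ids running from the start.
#' @return An object of class `experiment_registry`.
#' @export
new_experiment <- function(calibrated_vials, active_vials = character(0)) {
  if (!all(active_vials %in% calibrated_vials))
    stop("active vials must all be calibrated")
  structure(list(calibrated = calibrated_vials, active = active_vials),
            class = "experiment_registry")
}

#' Activate an additional vial during an ongoing experiment
#'
#' Refused unless the position was calibrated before the experiment
#' started, and refused when already active. The caller then runs the
#' replacement workflow ([replacement_session()] etc.) and attaches the
#' controller loop.
#'
#' @param experiment an [new_experiment()] registry.
#' @param vial_id position to activate.
#' @return The updated registry.
#' @export
add_vial_midrun <- function(experiment, vial_id) {
  if (!vial_id %in% experiment$calibrated)
    stop(sprintf("vial %s has no pre-experiment calibration; cannot add mid-run",
                 vial_id))
  if (vial_id %in% experiment$active)
    stop(sprintf("vial %s is already active", vial_id))
  experiment$active <- c(experiment$active, vial_id)
  experiment
}
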