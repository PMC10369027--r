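# ---- calibration store ------------------------------------------------------

#' In-memory calibration store with JSON persistence
#'
#' A calibration is tied to one experiment: each assay gets a fresh
#' fixed-vial calibration and obsolete entries are deleted afterwards. The
#' store keeps fitted curves by id, knows which ids are in use by an active
#' experiment, and round-trips to a JSON file (parameters, ranges,
#' residuals, timestamps).
#'
#' @return An empty object of class `calibration_store`.
#' @export
calibration_store <- function() {
  structure(list(entries = list(), in_use = character(0)),
            class = "calibration_store")
}

#' Add, fetch, list and mark calibrations
#'
#' @param store a [calibration_store()].
#' @param curve a [fit_curve()] result.
#' @param id entry id (default `"<sleeve>:<vial>"`).
#' @return `store_add()`, `store_mark_active()` and `store_release()`
#'   return the updated store; `store_get()` returns the curve;
#'   `store_list()` returns a character vector of ids.
#' @export
store_add <- function(store, curve, id = paste0(curve$sleeve_id, ":",
                                                curve$vial_id)) {
  curve$stored_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  store$entries[[id]] <- curve
  store
}

#' @rdname store_add
#' @export
store_get <- function(store, id) {
  if (!id %in% names(store$entries)) stop("unknown calibration id: ", id)
  store$entries[[id]]
}

#' @rdname store_add
#' @export
store_list <- function(store) names(store$entries)

#' @rdname store_add
#' @export
store_mark_active <- function(store, id) {
  if (!id %in% names(store$entries)) stop("unknown calibration id: ", id)
  store$in_use <- union(store$in_use, id)
  store
}

#' @rdname store_add
#' @export
store_release <- function(store, id) {
  store$in_use <- setdiff(store$in_use, id)
  store
}

#' Delete an obsolete calibration
#'
#' Removes an entry from the store. Deleting a calibration referenced by an
#' active experiment is refused; release it first.
#'
#' @param store a [calibration_store()].
#' @param id entry to delete.
#' @return The updated store.
#' @export
delete_calibration <- function(store, id) {
  if (!id %in% names(store$entries)) stop("unknown calibration id: ", id)
  if (id %in% store$in_use)
    stop(sprintf("calibration '%s' is in use by an active experiment; release it before deleting",
                 id))
  store$entries[[id]] <- NULL
  store
}

#' Persist / load a calibration store as JSON
#'
#' @param store a [calibration_store()].
#' @param path JSON file path.
#' @return `save_store()` returns `path` invisibly; `load_store()` returns
#'   the store.
#' @export
save_store <- function(store, path) {
  ser <- list(in_use = store$in_use,
              entries = lapply(store$entries, function(cv) {
                cv_ <- unclass(cv)
                cv_$params <- as.list(cv$params)
                cv_$residuals <- as.list(cv$residuals)
                cv_
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  store <- calibration_store()
  store$in_use <- as.character(ser$in_use)
  store$entries <- lapply(ser$entries, function(e) {
    e$params <- unlist(e$params)
    e$residuals <- unlist(e$residuals)
    e$valid_raw_range <- as.numeric(e$valid_raw_range)
    class(e) <- "calibration_curve"
    e
  })
  store
}
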