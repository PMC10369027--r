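# ---- media / PBS light-scattering equivalence -------------------------------

#' Reference light-scattering measurements of calibration solutions
#'
#' Bundled reference table of raw light-scattering values for water, PBS and
#' common fission-yeast growth media (EMM minimal, EMM6S supplemented
#' minimal, YE4S rich), each recorded as five consecutive reads of a single
#' fixed glass vial in one sleeve, with bench-spectrophotometer OD595 values
#' (water-blanked). PBS is the calibration solution; the table documents
#' that the media scatter like PBS to within the measurement noise, which is
#' what licenses calibrating in PBS and blanking in growth medium.
#'
#' @return Data frame with columns `solution`, `raw_mean`, `raw_sd`, `od595`.
#' @export
media_scattering_reference <- function() {
  utils::read.delim(system.file("extdata", "media_scattering.tsv",
                                package = "turbidr"))
}

#' Water-referenced light-scattering differences of media
#'
#' Computes, for each solution, the difference of its average raw value from
#' the water reference, and flags whether each non-water solution sits
#' within `k` standard deviations (the larger of the pair) of the water
#' value -- the equivalence criterion under which PBS-based calibration
#' transfers to medium-blanked experiments.
#'
#' @param table a data frame as returned by [media_scattering_reference()]
#'   (the default).
#' @param reference name of the reference solution.
#' @param k equivalence multiple of the per-solution raw SD.
#' @return The table with added columns `difference_raw` and `equivalent`.
#' @export
media_equivalence <- function(table = media_scattering_reference(),
                              reference = "water", k = 3) {
  i <- match(reference, table$solution)
  if (is.na(i)) stop("reference solution not found: ", reference)
  table$difference_raw <- table$raw_mean - table$raw_mean[i]
  gate <- k * pmax(table$raw_sd, table$raw_sd[i])
  table$equivalent <- abs(table$difference_raw) <= gate
  table
}

#' Check that two blank solutions scatter equivalently
#'
#' Startup gate of the OD engine: the medium blank of an experiment should
#' not differ from the PBS calibration anchor by more than a few noise SDs
#' once the common vial offset is accounted for.
#'
#' @param raw_a,raw_b raw values of the two solutions in the same vial.
#' @param noise_sd sensor noise SD, raw units.
#' @param k allowed multiple of `noise_sd`.
#' @return Logical: `TRUE` when `|raw_a - raw_b| < k * noise_sd`.
#' @export
check_media_equivalence <- function(raw_a, raw_b, noise_sd, k = 3) {
  abs(raw_a - raw_b) < k * noise_sd
}
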