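# ---- fixed-vial OD calibration ----------------------------------------------

#' Plan the inoculation steps of a fixed-vial calibration
#'
#' The fixed-vial protocol replaces vial permutation by a first PBS-only
#' measurement followed by successive inoculations of a concentrated stock
#' culture into the same vial. For a cumulative stock volume `v` added to a
#' vial of volume `V`, the nominal OD is `S * v / (V + v)` where `S` is the
#' nominal stock OD; each step's added volume is solved so the nominal ODs
#' meet the requested targets while accounting for the growing total volume.
#'
#' The stock must be at least `min_stock_ratio` times the largest target so
#' the cumulative added volume stays small relative to the vial volume
#' (default 20x keeps it under ~5%).
#'
#' @param target_ods non-decreasing OD targets; a leading 0 (the PBS point)
#'   is prepended if absent.
#' @param vial_volume_ml working volume of the calibration vial, mL.
#' @param stock_od_nominal nominal OD of the concentrated stock culture.
#' @param min_stock_ratio feasibility guard on `stock / max(target)`.
#' @return An object of class `inoculation_plan` with a `steps` data frame
#'   (`added_volume_ml`, `cumulative_stock_volume_ml`, `cumulative_fraction`,
#'   `nominal_od`).
#' @export
plan_inoculation <- function(target_ods, vial_volume_ml, stock_od_nominal,
                             min_stock_ratio = 20) {
  stopifnot(vial_volume_ml > 0, stock_od_nominal > 0)
  if (length(target_ods) == 0L) stop("no target ODs given")
  if (target_ods[1] != 0) target_ods <- c(0, target_ods)
  if (any(diff(target_ods) < 0))
    stop("target ODs must be non-decreasing (an OD decrease is infeasible)")
  if (max(target_ods) > 0 &&
      stock_od_nominal < min_stock_ratio * max(target_ods))
    stop(sprintf(
      "stock OD %.3g is below %gx the maximum target %.3g; use a more concentrated stock",
      stock_od_nominal, min_stock_ratio, max(target_ods)))
  v_cum <- target_ods * vial_volume_ml / (stock_od_nominal - target_ods)
  steps <- data.frame(
    added_volume_ml = diff(c(0, v_cum)),
    cumulative_stock_volume_ml = v_cum,
    cumulative_fraction = v_cum / (vial_volume_ml + v_cum),
    nominal_od = target_ods)
  structure(list(vial_volume_ml = vial_volume_ml,
                 stock_od_nominal = stock_od_nominal, steps = steps),
            class = "inoculation_plan")
}

#' Back-calculate the true stock OD from endpoint measurements
#'
#' After the last calibration point, the culture OD of each vial sharing the
#' stock is measured on a bench spectrophotometer and averaged. Dividing that
#' average by the final cumulative dilution fraction recovers the actual OD
#' of the stock -- whose direct measurement is error-prone because it is
#' highly concentrated -- and every calibration-point OD is rescaled
#' accordingly. Vial groups fed from distinct stocks must be back-calculated
#' separately.
#'
#' @param plan an [plan_inoculation()] result.
#' @param measured_final_ods spectrophotometer ODs of the final calibration
#'   point, one per vial sharing this stock.
#' @return List with `stock_od_actual` and `corrected_ods` (one per plan
#'   step; the PBS point stays exactly 0).
#' @export
backcalculate_stock <- function(plan, measured_final_ods) {
  if (length(measured_final_ods) == 0L) stop("no endpoint measurements given")
  fr <- plan$steps$cumulative_fraction
  f_final <- fr[length(fr)]
  if (f_final <= 0) stop("final cumulative fraction is zero; nothing to back-calculate")
  stock <- mean(measured_final_ods) / f_final
  list(stock_od_actual = stock, corrected_ods = stock * fr)
}

#' Assemble a per-sleeve calibration dataset
#'
#' Point 0 must be the PBS measurement (OD 0); its raw mean is stored as
#' `raw_0_cal`, the anchor onto which experiment-time delta-raw values are
#' transposed.
#'
#' @param sleeve_id,vial_id,led_power identifiers of the sleeve/vial pairing.
#' @param raw_mean per-point summary raw values (median of the consecutive
#'   reads of each point).
#' @param raw_sd per-point raw standard deviations.
#' @param nominal_od planned ODs (from the inoculation plan).
#' @param corrected_od back-calculated ODs, or `NA` before correction.
#' @return An object of class `calibration_dataset`.
#' @export
new_calibration_dataset <- function(sleeve_id, vial_id, led_power,
                                    raw_mean, raw_sd, nominal_od,
                                    corrected_od = NA_real_) {
  n <- length(raw_mean)
  stopifnot(length(raw_sd) == n, length(nominal_od) == n)
  if (nominal_od[1] != 0)
    stop("point 0 must be the PBS point (OD 0)")
  structure(list(sleeve_id = sleeve_id, vial_id = vial_id,
                 led_power = led_power,
                 points = data.frame(raw_mean = raw_mean, raw_sd = raw_sd,
                                     nominal_od = nominal_od,
                                     corrected_od = rep_len(corrected_od, n)),
                 raw_0_cal = raw_mean[1], corrected = FALSE),
            class = "calibration_dataset")
}

#' Apply back-calculated ODs to a calibration dataset
#'
#' Replaces the nominal ODs by the corrected ones, leaving the raw values and
#' their order untouched. Under the fixed-vial protocol every sleeve records
#' its points in the same order, so the measurement reordering needed by the
#' legacy rotational-permutation layout reduces to an explicit identity
#' mapping (kept as `order_map`). Raw values that are not monotone in the
#' corrected OD beyond `noise_gate` are flagged with a warning rather than
#' rejected.
#'
#' @param dataset a [new_calibration_dataset()] object.
#' @param corrected_ods one OD per point, typically from
#'   [backcalculate_stock()]; the first must be 0 (PBS).
#' @param noise_gate raw-unit slack allowed before a monotonicity violation
#'   is flagged.
#' @return The corrected dataset (field `corrected = TRUE`).
#' @export
correct_calibration <- function(dataset, corrected_ods, noise_gate = 150) {
  pts <- dataset$points
  if (length(corrected_ods) != nrow(pts))
    stop("length mismatch between raw points and corrected ODs")
  if (corrected_ods[1] != 0)
    stop("point 0 must be the PBS point (corrected OD 0)")
  ord <- seq_len(nrow(pts))  # fixed-vial protocol: identity order map
  pts$corrected_od <- corrected_ods[ord]
  d_raw <- diff(pts$raw_mean[order(pts$corrected_od)])
  if (length(unique(sign(d_raw[abs(d_raw) > noise_gate]))) > 1)
    warning("raw values are not monotone in corrected OD beyond the noise gate")
  dataset$points <- pts
  dataset$order_map <- ord
  dataset$corrected <- TRUE
  dataset
}

# deterministic start values for the 4-parameter logistic, from data quantiles
.logistic_start <- function(od, raw) {
  lo <- min(raw); hi <- max(raw); r <- hi - lo
  decreasing <- stats::cor(od, raw) < 0
  mid0 <- od[which.min(abs(raw - (lo + hi) / 2))]
  span <- max(od) - min(od)
  list(base = lo - 0.05 * r, amp = 1.1 * r, mid = mid0,
       steep = (if (decreasing) 1 else -1) * 4 / span)
}

#' Fit a monotone calibration curve
#'
#' Least-squares fit of a 4-parameter logistic
#' `raw = base + amp / (1 + exp(steep * (OD - mid)))`
#' to the corrected calibration points (Levenberg-Marquardt, deterministic
#' initialisation from data quantiles -- fitting the same points twice gives
#' identical parameters). The OD lookup `OD = f(raw)` is the analytic inverse
#' of the fitted logistic, hence strictly monotone and single-valued over the
#' valid raw range; see [od_from_raw()].
#'
#' @param dataset a corrected [new_calibration_dataset()].
#' @param min_points minimum number of corrected points required.
#' @return An object of class `calibration_curve` holding the four
#'   parameters, `valid_raw_range`, a residual summary and `raw_0_cal`.
#' @export
fit_curve <- function(dataset, min_points = 5L) {
  if (!isTRUE(dataset$corrected))
    stop("dataset must be corrected (back-calculated ODs) before fitting")
  pts <- dataset$points
  ok <- is.finite(pts$corrected_od) & is.finite(pts$raw_mean)
  if (sum(ok) < min_points)
    stop(sprintf("need at least %d corrected points, got %d", min_points, sum(ok)))
  od <- pts$corrected_od[ok]; raw <- pts$raw_mean[ok]
  start <- .logistic_start(od, raw)
  fit <- tryCatch(
    minpack.lm::nlsLM(raw ~ base + amp / (1 + exp(steep * (od - mid))),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("calibration fit did not converge: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["amp"]] <= 0)
    stop("fitted curve is not monotone (non-positive amplitude)")
  res <- stats::resid(fit)
  curve <- structure(list(
    sleeve_id = dataset$sleeve_id, vial_id = dataset$vial_id,
    led_power = dataset$led_power,
    params = c(base = unname(cf[["base"]]), amp = unname(cf[["amp"]]),
               mid = unname(cf[["mid"]]), steep = unname(cf[["steep"]])),
    valid_raw_range = range(raw),
    residuals = c(rmse = sqrt(mean(res^2)), max_abs = max(abs(res))),
    raw_0_cal = dataset$raw_0_cal), class = "calibration_curve")
  blank_od <- od_from_raw(curve, dataset$raw_0_cal)
  if (!is.finite(blank_od) || abs(blank_od) > 0.02)
    warning(sprintf("f(raw_0_cal) = %.4f is not within tolerance of 0", blank_od))
  curve
}

#' Evaluate a fitted calibration curve
#'
#' `od_from_raw()` computes `OD = f(raw)`, the analytic inverse of the fitted
#' logistic: `f(raw) = mid + log(amp / (raw - base) - 1) / steep`. Raw values
#' outside the open interval `(base, base + amp)` have no finite OD and give
#' `NaN`. `raw_from_od()` is the forward map and `curve_slope()` its
#' derivative `d raw / d OD`, used by the LED-power selector.
#'
#' @param curve a [fit_curve()] result.
#' @param raw,od numeric vectors.
#' @return Numeric vector.
#' @export
od_from_raw <- function(curve, raw) {
  p <- curve$params
  u <- p[["amp"]] / (raw - p[["base"]]) - 1
  out <- rep(NaN, length(raw))
  okv <- is.finite(u) & u > 0 & (raw > p[["base"]])
  out[okv] <- p[["mid"]] + log(u[okv]) / p[["steep"]]
  out
}

#' @rdname od_from_raw
#' @export
raw_from_od <- function(curve, od) {
  p <- curve$params
  p[["base"]] + p[["amp"]] / (1 + exp(p[["steep"]] * (od - p[["mid"]])))
}

#' @rdname od_from_raw
#' @export
curve_slope <- function(curve, od) {
  p <- curve$params
  s <- 1 / (1 + exp(p[["steep"]] * (od - p[["mid"]])))
  -p[["amp"]] * p[["steep"]] * s * (1 - s)
}

#' OD range over which a curve is supported by calibration points
#' @param curve a [fit_curve()] result.
#' @return Length-2 numeric vector (low, high OD).
#' @export
curve_od_range <- function(curve) {
  sort(od_from_raw(curve, curve$valid_raw_range))
}

#' Select the LED power with the best worst-case dynamic range
#'
#' Candidate powers are compared by the minimum absolute slope
#' `|d raw / d OD|` of their calibration curves over the target OD window
#' (default 0.2-0.5, the working range of exponentially growing yeast on the
#' 135-degree photodiode). The power maximising that worst-case slope wins;
#' ties break toward the lower power. Curves that do not cover the window
#' are excluded (error if none covers it).
#'
#' @param curves_by_power named list of [fit_curve()] results; names are the
#'   integer LED powers.
#' @param od_window length-2 OD window.
#' @param n_grid grid density for the window scan.
#' @return The selected LED power (integer).
#' @export
select_led_power <- function(curves_by_power, od_window = c(0.2, 0.5),
                             n_grid = 201L) {
  stopifnot(length(curves_by_power) >= 1)
  powers <- as.integer(names(curves_by_power))
  if (anyNA(powers)) stop("curves_by_power must be named by integer LED power")
  grid <- seq(od_window[1], od_window[2], length.out = n_grid)
  score <- vapply(curves_by_power, function(cv) {
    rng <- curve_od_range(cv)
    if (rng[1] > od_window[1] + 1e-6 || rng[2] < od_window[2] - 1e-6)
      return(NA_real_)
    min(abs(curve_slope(cv, grid)))
  }, numeric(1))
  if (all(is.na(score)))
    stop("the OD window lies outside every candidate curve's range")
  ok <- which(!is.na(score))
  ord <- ok[order(-score[ok], powers[ok])]
  powers[ord[1]]
}

# ---- simulated fixed-vial calibration run (virtual rig protocol) -------------

#' Run the fixed-vial calibration protocol on the virtual rig
#'
#' Executes the full protocol against a [true_optics()]/[true_vial()] pair:
#' PBS blank first, then successive stock inoculations per the plan (PBS
#' keeps cells from growing, so the true OD at each point is exactly
#' `stock_od_actual * cumulative_fraction`), five consecutive raw reads per
#' point summarised by their median, and a final endpoint OD measured with
#' spectrophotometer noise. The true stock OD may differ from nominal --
#' that is the error the back-calculation corrects.
#'
#' @param optics,vial virtual rig components.
#' @param plan an [plan_inoculation()] result.
#' @param stock_od_actual true OD of the stock culture (defaults to nominal).
#' @param reads_per_point consecutive raw reads summarised per point.
#' @param spectro_sd SD of the endpoint spectrophotometer measurement, OD.
#' @return List with `dataset` (a [new_calibration_dataset()]),
#'   `measured_final_od` and `true_ods`.
#' @export
simulate_calibration <- function(optics, vial, plan,
                                 stock_od_actual = plan$stock_od_nominal,
                                 reads_per_point = 5L, spectro_sd = 0.005) {
  st <- plan$steps
  true_ods <- stock_od_actual * st$cumulative_fraction
  raw_mean <- raw_sd <- numeric(nrow(st))
  for (i in seq_len(nrow(st))) {
    cult <- if (true_ods[i] > 0) true_culture(true_ods[i]) else NULL
    reads <- measure_raw(optics, vial, cult, n = reads_per_point)
    raw_mean[i] <- stats::median(reads)
    raw_sd[i] <- if (reads_per_point > 1) stats::sd(reads) else 0
  }
  final_od <- true_ods[length(true_ods)] +
    if (spectro_sd > 0) stats::rnorm(1, 0, spectro_sd) else 0
  list(dataset = new_calibration_dataset(optics$sleeve_id, vial$vial_id,
                                         optics$led_power, raw_mean, raw_sd,
                                         st$nominal_od),
       measured_final_od = final_od, true_ods = true_ods)
}

#' Calibrate one sleeve/vial pairing end to end on the virtual rig
#'
#' Convenience wrapper: plan, simulate, back-calculate, correct, fit.
#'
#' @inheritParams simulate_calibration
#' @param target_ods calibration OD targets (default 10 points over 0-0.8).
#' @param stock_od_nominal nominal stock OD.
#' @return A [fit_curve()] result.
#' @export
calibrate_sleeve <- function(optics, vial,
                             target_ods = c(0, 0.05, 0.1, 0.15, 0.2, 0.3,
                                            0.4, 0.5, 0.65, 0.8),
                             stock_od_nominal = 20,
                             stock_od_actual = stock_od_nominal,
                             reads_per_point = 5L, spectro_sd = 0.005) {
  plan <- plan_inoculation(target_ods, vial$volume_ml, stock_od_nominal)
  sim <- simulate_calibration(optics, vial, plan, stock_od_actual,
                              reads_per_point, spectro_sd)
  bc <- backcalculate_stock(plan, sim$measured_final_od)
  ds <- correct_calibration(sim$dataset, bc$corrected_ods)
  fit_curve(ds)
}

# ---- calibration dataset / curve i/o ----------------------------------------

#' Read and write calibration datasets as delimited text
#'
#' Columns: `sleeve_id, vial_id, led_power, point_index, raw_mean, raw_sd,
#' nominal_od, corrected_od` (tab-separated).
#'
#' @param dataset a [new_calibration_dataset()] object.
#' @param path file path.
#' @return `write_calibration_dataset()` returns `path` invisibly;
#'   `read_calibration_dataset()` returns the dataset object.
#' @export
write_calibration_dataset <- function(dataset, path) {
  pts <- dataset$points
  out <- data.frame(sleeve_id = dataset$sleeve_id, vial_id = dataset$vial_id,
                    led_power = dataset$led_power,
                    point_index = seq_len(nrow(pts)) - 1L, pts)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_dataset
#' @export
read_calibration_dataset <- function(path) {
  df <- utils::read.delim(path)
  ds <- new_calibration_dataset(df$sleeve_id[1], df$vial_id[1],
                                df$led_power[1], df$raw_mean, df$raw_sd,
                                df$nominal_od)
  if (!anyNA(df$corrected_od)) {
    ds$points$corrected_od <- df$corrected_od
    ds$corrected <- TRUE
  }
  ds
}
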