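#' Calibration constants and screening thresholds
#'
#' Bundles the TEX86 temperature calibration, the ring-index/TEX86 core-top
#' parabola and the quality-screening thresholds into one overridable
#' configuration object.
#'
#' Defaults: temperature calibration `SST = 68.4 * log10(TEX86) + 38.6`;
#' calibration curve `RI = 3.32 * TEX86^2 - 0.77 * TEX86 + 1.59` with a
#' zone half-width of 0.3 ring units (about 2 sigma of the core-top
#' residuals); screening thresholds BIT > 0.2, GDGT-2/cren > 0.4,
#' Methane Index > 0.5, GDGT-0/cren > 2, %GDGT-2 > 45. All inequalities are
#' strict; boundary values do not flag.
#'
#' @param slope Temperature-calibration slope, degrees C per log unit.
#' @param intercept Temperature-calibration intercept, degrees C.
#' @param ri_a,ri_b,ri_c Quadratic coefficients of the RI-TEX86 curve.
#' @param zone_halfwidth Half-width of the calibration zone, ring units.
#' @param log_base Base of the logarithm in the temperature calibration
#'   (10 by default; kept configurable so natural-log variants can be
#'   tested).
#' @param thresholds Named list of screening thresholds (`bit`,
#'   `ratio_2_cren`, `methane_index`, `ratio_0_cren`, `pct_gdgt2`).
#' @return A list with class `calibration_params`.
#' @export
calibration_params <- function(slope = 68.4, intercept = 38.6,
                               ri_a = 3.32, ri_b = -0.77, ri_c = 1.59,
                               zone_halfwidth = 0.3, log_base = 10,
                               thresholds = list()) {
  defaults <- list(bit = 0.2, ratio_2_cren = 0.4, methane_index = 0.5,
                   ratio_0_cren = 2, pct_gdgt2 = 45)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(thresholds)] <- thresholds
  stopifnot(zone_halfwidth >= 0, log_base > 1)
  structure(list(slope = slope, intercept = intercept,
                 ri_a = ri_a, ri_b = ri_b, ri_c = ri_c,
                 zone_halfwidth = zone_halfwidth, log_base = log_base,
                 thresholds = defaults),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("<calibration_params>\n")
  cat(sprintf("  SST = %.4g * log%g(TEX86) + %.4g degC\n",
              x$slope, x$log_base, x$intercept))
  cat(sprintf("  RI  = %.4g * TEX86^2 + %.4g * TEX86 + %.4g  (zone +/- %.4g)\n",
              x$ri_a, x$ri_b, x$ri_c, x$zone_halfwidth))
  cat("  flags (strict >):",
      paste(sprintf("%s %.4g", names(x$thresholds),
                    unlist(x$thresholds)), collapse = ", "), "\n")
  invisible(x)
}

#' TEX86-derived temperature
#'
#' Applies the logarithmic core-top calibration
#' `T = slope * log10(TEX86) + intercept`.
#'
#' @param t TEX86 values (dimensionless, in `(0, 1]`).
#' @param cal A [calibration_params()] object.
#' @return Temperatures in degrees Celsius; `NA` where `t <= 0` or `NA`.
#' @export
tex86_temperature <- function(t, cal = calibration_params()) {
  ifelse(!is.na(t) & t > 0,
         cal$slope * log(t, base = cal$log_base) + cal$intercept,
         NA_real_)
}

#' Ring index predicted from TEX86 by the core-top calibration
#'
#' `RI = ri_a * t^2 + ri_b * t + ri_c`, the parabola fitted to the global
#' core-top dataset. Strictly increasing for `t` above the vertex
#' (`-ri_b / (2 ri_a)`, about 0.116 at default coefficients).
#'
#' @inheritParams tex86_temperature
#' @return Predicted ring index, ring units.
#' @export
predicted_ri <- function(t, cal = calibration_params()) {
  cal$ri_a * t^2 + cal$ri_b * t + cal$ri_c
}

#' Deviation from the ring-index calibration zone
#'
#' `delta = ri_measured - predicted_ri(t)`. Samples with `|delta|` beyond
#' the zone half-width carry a GDGT pool whose ring distribution is not
#' explained by temperature alone (extra cyclopentyl-GDGT sources,
#' terrestrial input, ...).
#'
#' @param ri_measured Measured ring index (ring units).
#' @param t TEX86 values.
#' @param cal A [calibration_params()] object.
#' @return A tibble with columns `delta` (ring units) and `in_zone`
#'   (`|delta| <= zone_halfwidth`); both `NA` where an input is undefined.
#' @export
delta_ri <- function(ri_measured, t, cal = calibration_params()) {
  delta <- ri_measured - predicted_ri(t, cal)
  tibble::tibble(delta = delta,
                 in_zone = abs(delta) <= cal$zone_halfwidth)
}

#' Advisory quality-control flags for TEX86 interpretation
#'
#' Evaluates the standard screening thresholds against a computed index set.
#' Each flag is `TRUE` iff its strict inequality holds, `FALSE` if the index
#' is defined and below threshold, and `NA` (indeterminate) where the index
#' is undefined or absent. Flags are advisory: nothing downstream drops
#' flagged samples.
#'
#' @param ix An index tibble from [compute_indices()] (or any data frame
#'   with the relevant columns).
#' @param cal A [calibration_params()] object.
#' @param delta Optional `delta` column (ring units) from [delta_ri()];
#'   drives the `ri_deviation` flag.
#' @return A tibble of logical columns `bit_gt_0_2`, `g2_cren_gt_0_4`,
#'   `mi_gt_0_5`, `g0_cren_gt_2`, `pct_g2_gt_45`, `ri_deviation`.
#' @export
qc_flags <- function(ix, cal = calibration_params(), delta = NULL) {
  ix <- as.data.frame(ix)
  n <- nrow(ix)
  col_or_na <- function(nm) if (nm %in% names(ix)) ix[[nm]] else rep(NA_real_, n)
  th <- cal$thresholds
  out <- tibble::tibble(
    bit_gt_0_2 = col_or_na("bit") > th$bit,
    g2_cren_gt_0_4 = col_or_na("ratio_2_cren") > th$ratio_2_cren,
    mi_gt_0_5 = col_or_na("methane_index") > th$methane_index,
    g0_cren_gt_2 = col_or_na("ratio_0_cren") > th$ratio_0_cren,
    pct_g2_gt_45 = col_or_na("pct_gdgt2") > th$pct_gdgt2
  )
  if (is.null(delta)) delta <- rep(NA_real_, n)
  out$ri_deviation <- abs(delta) > cal$zone_halfwidth
  out
}

#' Screen an index table against the calibration
#'
#' Combines [tex86_temperature()], [predicted_ri()], [delta_ri()] and
#' [qc_flags()] into one per-row screening result.
#'
#' The calibration-zone test uses RI_1 by default, the form the core-top
#' parabola was fitted with; `ri = "ri2"` selects the crenarchaeol-free
#' variant when RI_1 is unavailable (e.g. index-only datasets).
#'
#' @param ix An index tibble (columns `tex86` and the chosen ring index at
#'   minimum).
#' @param cal A [calibration_params()] object.
#' @param ri Which measured ring index enters the zone test, `"ri1"`
#'   (default) or `"ri2"`.
#' @return A tibble with `tex86_temp`, `ri_used`, `ri_predicted`,
#'   `delta_ri`, `in_calibration_zone` and the flag columns.
#' @export
screen_indices <- function(ix, cal = calibration_params(),
                           ri = c("ri1", "ri2")) {
  ri <- match.arg(ri)
  ix <- tibble::as_tibble(ix)
  t <- ix$tex86
  ri_meas <- if (ri %in% names(ix)) ix[[ri]] else rep(NA_real_, nrow(ix))
  d <- delta_ri(ri_meas, t, cal)
  out <- tibble::tibble(
    tex86_temp = tex86_temperature(t, cal),
    ri_used = ri,
    ri_predicted = predicted_ri(t, cal),
    delta_ri = d$delta,
    in_calibration_zone = d$in_zone
  )
  dplyr::bind_cols(out, qc_flags(ix, cal, delta = d$delta))
}
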