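#' Build a piecewise-linear pH calibration curve
#'
#' The sensor's delta-F/F versus pH relation, measured at a small set of
#' buffer pH steps, is fit with monotone piecewise-linear interpolation and
#' anchored at a reference pH (7.3) where delta-F/F is 0 by convention. The
#' curve converts delta-F/F to pH in the analysis pipeline.
#'
#' @param pairs data frame with columns `pH` and `dff` (the knots).
#' @param reference_pH the anchoring pH (default 7.3); a knot at this pH with
#'   `dff` 0 must be present.
#' @return A `calibration_curve`.
#' @examples
#' cal <- build_calibration(data.frame(pH = c(6.4, 7.3), dff = c(-0.6, 0)))
#' dff_to_ph(-0.3, cal)  # 6.85
#' @export
build_calibration <- function(pairs, reference_pH = 7.3) {
  stopifnot(all(c("pH", "dff") %in% names(pairs)))
  pairs <- pairs[order(pairs$pH), , drop = FALSE]
  if (nrow(pairs) < 2) stop("need at least 2 calibration pairs", call. = FALSE)
  if (anyDuplicated(pairs$pH)) {
    stop("duplicate pH values in calibration pairs", call. = FALSE)
  }
  if (any(diff(pairs$dff) <= 0)) {
    stop("delta-F/F must increase strictly with pH (monotone sensor assumption violated)",
         call. = FALSE)
  }
  ref <- which(abs(pairs$pH - reference_pH) < 1e-9)
  if (length(ref) != 1 || abs(pairs$dff[ref]) > 1e-9) {
    stop("calibration must contain the reference knot (pH ", reference_pH,
         ", dff = 0)", call. = FALSE)
  }
  structure(list(pH = pairs$pH, dff = pairs$dff, reference_pH = reference_pH),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("Piecewise-linear pH calibration,", length(x$pH), "knots, reference pH",
      x$reference_pH, "\n")
  print(data.frame(pH = x$pH, dff = x$dff))
  invisible(x)
}

#' Evaluate a calibration curve (pH -> delta-F/F)
#'
#' @param curve a [build_calibration()] curve.
#' @param pH pH values within the knot range.
#' @return Interpolated delta-F/F.
#' @export
cal_dff <- function(curve, pH) {
  approx(curve$pH, curve$dff, xout = pH, rule = 2)$y
}

#' Convert a delta-F/F trace to pH
#'
#' Inverts the monotone calibration: `pH_t = curve^-1(dff_t + curve(pH0))`,
#' where `pH0` is the assumed initial pH (default 7.3, the curve's anchor).
#' Values outside the knot range are clamped to the end knots and flagged
#' per-sample rather than extrapolated (piecewise-linear extrapolation of a
#' saturating sensor is unbounded).
#'
#' @param x an `roi_trace` (artifact-corrected), or a numeric delta-F/F
#'   vector.
#' @param curve a [build_calibration()] curve.
#' @param initial_pH assumed pH at the first epoch.
#' @param waive_correction set TRUE to silence the warning when converting an
#'   uncorrected trace.
#' @return For a trace input: data frame with `t`, `pH`, `clamped`. For a
#'   numeric input: pH vector with logical attribute `clamped`.
#' @export
dff_to_ph <- function(x, curve, initial_pH = 7.3, waive_correction = FALSE) {
  is_trace <- inherits(x, "roi_trace") || (is.data.frame(x) && "dff" %in% names(x))
  dff <- if (is_trace) x$dff else x
  if (is_trace && !isTRUE(attr(x, "corrected")) && !waive_correction) {
    warning("converting an uncorrected trace; pass waive_correction = TRUE to silence",
            call. = FALSE)
  }
  target <- dff + cal_dff(curve, initial_pH)
  lo <- min(curve$dff); hi <- max(curve$dff)
  clamped <- target < lo | target > hi
  target <- pmin(pmax(target, lo), hi)
  pH <- approx(curve$dff, curve$pH, xout = target)$y
  if (is_trace) {
    data.frame(t = x$t, pH = pH, clamped = clamped)
  } else {
    structure(pH, clamped = clamped)
  }
}

#' Fold change in free-proton concentration between two pH values
#'
#' @param pH_from,pH_to pH values.
#' @return `10^(pH_from - pH_to)`; e.g. a drop from 7.3 to 6.76 is a ~3.5-fold
#'   rise in free protons.
#' @export
proton_fold_change <- function(pH_from, pH_to) {
  stopifnot(is.finite(pH_from), is.finite(pH_to))
  10^(pH_from - pH_to)
}
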