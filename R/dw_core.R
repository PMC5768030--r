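# Water-equivalent diameter: A_w, table calibration, Dw(z) profiles and the
# scalar metrics Dw_c / Dw_ave / Dw range.
#
# For a region of interest with mean CT number <CT> (HU) and area A_ROI, the
# water-equivalent area is
#     A_w = (<CT>/1000) * A_ROI + A_ROI,
# and the water-equivalent diameter of a slice, after subtracting the couch
# contribution A_w(table), is
#     Dw = 2 * sqrt((A_w - A_w(table)) / pi).
# The ROI used here is the entire image (air outside the patient contributes
# nothing to A_w), which is the fast whole-FOV variant of the attenuation-based
# patient size metric; no body contouring is performed.

#' Water-equivalent area of a region
#'
#' @param mean_ct Mean CT number of the region in HU.
#' @param area Region area in cm^2.
#' @return Water-equivalent area in cm^2, `(mean_ct/1000)*area + area`. The
#'   result is negative only if `mean_ct < -1000` (callers clamp at the
#'   profile level).
#' @export
#' @examples
#' water_equivalent_area(0, 100)      # water: 100
#' water_equivalent_area(-1000, 50)   # air: 0
water_equivalent_area <- function(mean_ct, area) {
  if (any(area < 0)) stop("'area' must be >= 0")
  (mean_ct / 1000) * area + area
}

#' Couch (CT table) calibration
#'
#' Water-equivalent area of the patient couch, obtained once per scanner by
#' contouring the table in a patient-free region of one image.
#'
#' @param aw_table Water-equivalent area of the couch in cm^2.
#' @param scanner_id Scanner label.
#' @return An object of class `table_calibration`.
#' @export
table_calibration <- function(aw_table = 0, scanner_id = "unknown") {
  if (!is.numeric(aw_table) || length(aw_table) != 1L || is.na(aw_table) ||
      aw_table < 0)
    stop("'aw_table' must be a single number >= 0")
  structure(list(aw_table = as.numeric(aw_table), scanner_id = scanner_id),
            class = "table_calibration")
}

#' Calibrate the couch contribution from a contoured region
#'
#' Applies the water-equivalent area formula to the masked couch region of a
#' slice.
#'
#' @param slice A normalized [ct_slice].
#' @param table_mask Logical matrix of the same dimension as `slice$pixels`,
#'   `TRUE` over the couch.
#' @param scanner_id Scanner label recorded in the calibration.
#' @return A [table_calibration]. `aw_table` is clamped at zero if the masked
#'   region is less attenuating than air.
#' @export
calibrate_table <- function(slice, table_mask, scanner_id = "unknown") {
  stopifnot(inherits(slice, "ct_slice"))
  if (!is.logical(table_mask) || !identical(dim(table_mask), dim(slice$pixels)))
    stop("'table_mask' must be a logical matrix matching the slice pixels")
  n <- sum(table_mask)
  if (n == 0L) stop("empty table mask")
  area_cm2 <- n * .pixel_area_mm2(slice) / 100
  aw <- water_equivalent_area(mean(slice$pixels[table_mask]), area_cm2)
  table_calibration(max(aw, 0), scanner_id = scanner_id)
}

#' Water-equivalent diameter of one slice
#'
#' Whole-image ROI: the area is the full pixel grid and the mean CT number is
#' taken over all pixels. The couch contribution `cal$aw_table` is subtracted
#' before converting area to diameter.
#'
#' @param slice A normalized [ct_slice] (HU, padding masked).
#' @param cal A [table_calibration]; default zero (no couch).
#' @return Dw in cm. A negative radicand (couch calibration exceeding the
#'   slice content, e.g. an air-only slice) clamps to 0 with a warning.
#' @export
slice_dw <- function(slice, cal = table_calibration(0)) {
  stopifnot(inherits(slice, "ct_slice"), inherits(cal, "table_calibration"))
  area_cm2 <- length(slice$pixels) * .pixel_area_mm2(slice) / 100
  aw <- water_equivalent_area(mean(slice$pixels), area_cm2)
  rad <- aw - cal$aw_table
  if (rad < 0) {
    warning(sprintf(
      "negative water-equivalent area (%.2f cm^2) after table correction; clamped to 0",
      rad))
    rad <- 0
  }
  2 * sqrt(rad / pi)
}

#' Dw(z) profile of a series
#'
#' @param series A [scan_series] of normalized slices.
#' @param cal A [table_calibration].
#' @return A `dw_profile` object: parallel vectors `z` (mm), `dw` (cm) and
#'   `current` (mA, possibly `NA`), plus the series' `exam_type` and
#'   `ctdi_vol`.
#' @export
dw_profile <- function(series, cal = table_calibration(0)) {
  stopifnot(inherits(series, "scan_series"))
  dw <- vapply(seq_along(series$slices), function(i) {
    tryCatch(slice_dw(series$slices[[i]], cal),
             error = function(e) stop("slice ", i, ": ", conditionMessage(e)))
  }, 0)
  new_dw_profile(z = series_z(series), dw = dw,
                 current = series_currents(series),
                 exam_type = series$exam_type, ctdi_vol = series$ctdi_vol)
}

#' Construct a Dw(z) profile directly
#'
#' @param z Slice positions in mm, strictly increasing.
#' @param dw Dw values in cm, same length as `z`, all `>= 0`.
#' @param current Tube currents in mA (optional, `NA` allowed).
#' @param exam_type,ctdi_vol Examination metadata.
#' @return A `dw_profile` object.
#' @export
new_dw_profile <- function(z, dw, current = rep(NA_real_, length(z)),
                           exam_type = "phantom", ctdi_vol = NA_real_) {
  if (length(z) < 1L || length(dw) != length(z) || length(current) != length(z))
    stop("'z', 'dw' and 'current' must have equal length >= 1")
  if (is.unsorted(z, strictly = TRUE)) stop("'z' must be strictly increasing")
  if (any(dw < 0)) stop("all 'dw' must be >= 0")
  structure(list(z = as.numeric(z), dw = as.numeric(dw),
                 current = as.numeric(current), exam_type = exam_type,
                 ctdi_vol = as.numeric(ctdi_vol)),
            class = "dw_profile")
}

#' Mid-scan water-equivalent diameter (Dw_c)
#'
#' Dw at the slice whose z is nearest the midpoint of the scanned range; an
#' exact tie between two slices resolves to the lower-z slice.
#'
#' @param profile A `dw_profile`.
#' @return Dw_c in cm.
#' @export
dw_central <- function(profile) {
  stopifnot(inherits(profile, "dw_profile"))
  mid <- (profile$z[1L] + profile$z[length(profile$z)]) / 2
  d <- abs(profile$z - mid)
  profile$dw[which(d == min(d))[1L]]
}

#' Scan-average water-equivalent diameter (Dw_ave)
#'
#' Unweighted arithmetic mean of Dw(z) over all slices in the imaged region.
#'
#' @param profile A `dw_profile`.
#' @return Dw_ave in cm.
#' @export
dw_average <- function(profile) {
  stopifnot(inherits(profile, "dw_profile"))
  mean(profile$dw)
}

#' Scalar size metrics of a Dw(z) profile
#'
#' @param profile A `dw_profile`.
#' @return A `dw_metrics` object with `dw_c`, `dw_ave`, `dw_min`, `dw_max`,
#'   `dw_range` (all cm) and `n_slices`.
#' @export
dw_metrics <- function(profile) {
  stopifnot(inherits(profile, "dw_profile"))
  structure(list(dw_c = dw_central(profile), dw_ave = dw_average(profile),
                 dw_min = min(profile$dw), dw_max = max(profile$dw),
                 dw_range = max(profile$dw) - min(profile$dw),
                 n_slices = length(profile$dw)),
            class = "dw_metrics")
}

#' Fraction of the image border occupied by non-air tissue
#'
#' Flags scans where part of the patient contour lies outside the
#' field of view (truncation). Measured as the fraction of pixels in the
#' outermost 2-pixel frame of the image with HU above `threshold`. Scans are
#' typically excluded when this exceeds a configured cutoff (default
#' convention: 0.05) on any slice; no attenuation correction is attempted.
#'
#' @param slice A normalized [ct_slice].
#' @param threshold HU above which a border pixel counts as tissue; default
#'   -600.
#' @return Fraction in \eqn{[0, 1]}.
#' @export
truncation_fraction <- function(slice, threshold = -600) {
  stopifnot(inherits(slice, "ct_slice"))
  px <- slice$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (nr <= 4L || nc <= 4L) return(mean(px > threshold))
  ring <- px
  ring[3:(nr - 2), 3:(nc - 2)] <- NA
  mean(ring > threshold, na.rm = TRUE)
}

#' @export
print.dw_profile <- function(x, ...) {
  m <- dw_metrics(x)
  cat(sprintf(
    "<dw_profile> %s: %d slices, z %.1f..%.1f mm\n  Dw_c %.2f, Dw_ave %.2f, range [%.2f, %.2f] cm\n",
    x$exam_type, m$n_slices, x$z[1L], x$z[length(x$z)],
    m$dw_c, m$dw_ave, m$dw_min, m$dw_max))
  invisible(x)
}

#' @export
summary.dw_profile <- function(object, ...) dw_metrics(object)

#' @export
print.dw_metrics <- function(x, ...) {
  cat(sprintf(
    "<dw_metrics> Dw_c %.2f cm, Dw_ave %.2f cm, min %.2f, max %.2f, range %.2f cm (%d slices)\n",
    x$dw_c, x$dw_ave, x$dw_min, x$dw_max, x$dw_range, x$n_slices))
  invisible(x)
}

#' Plot a Dw(z) profile
#'
#' Dw(z) against table position with the mid-scan slice marked and Dw_ave as a
#' horizontal reference; optionally overlays the tube current I(z) on a second
#' axis.
#'
#' @param x A `dw_profile`.
#' @param show_current Overlay I(z) if available. Default `TRUE`.
#' @param ... Passed to [plot].
#' @export
plot.dw_profile <- function(x, show_current = TRUE, ...) {
  m <- dw_metrics(x)
  graphics::plot(x$z, x$dw, type = "l", xlab = "table position z (mm)",
                 ylab = "Dw (cm)", ...)
  graphics::abline(h = m$dw_ave, lty = 2, col = "grey40")
  mid <- (x$z[1L] + x$z[length(x$z)]) / 2
  i <- which.min(abs(x$z - mid))
  graphics::points(x$z[i], x$dw[i], pch = 19)
  if (show_current && any(!is.na(x$current))) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(x$z, x$current, type = "l", col = "steelblue", axes = FALSE,
                   xlab = "", ylab = "")
    graphics::axis(4, col.axis = "steelblue")
    graphics::mtext("I(z) (mA)", side = 4, line = 2, col = "steelblue")
  }
  invisible(x)
}
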