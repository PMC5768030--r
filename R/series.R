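# In-memory model of a CT series: ct_slice, scan_series, patient_bio.

#' One reconstructed CT slice
#'
#' @param pixels Numeric matrix of CT numbers in HU (already rescaled and
#'   padding-masked; see \code{\link{mask_padding}}). Values below -1100 HU
#'   are rejected as un-masked padding.
#' @param pixel_spacing Length-2 numeric, (row, column) spacing in mm.
#' @param z_position Table position of the slice in mm.
#' @param tube_current Tube current in mA, or `NA` if unknown.
#' @param slice_id Ordinal identifier.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, pixel_spacing, z_position, tube_current = NA_real_,
                     slice_id = 1L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("'pixel_spacing' must be two positive numbers (row, col) in mm")
  if (any(pixels < -1100))
    stop("pixels below -1100 HU present; mask padding sentinels first")
  structure(
    list(pixels = pixels,
         pixel_spacing = as.numeric(pixel_spacing),
         z_position = as.numeric(z_position),
         tube_current = as.numeric(tube_current),
         slice_id = as.integer(slice_id)),
    class = "ct_slice")
}

# Pixel area in mm^2.
.pixel_area_mm2 <- function(slice) prod(slice$pixel_spacing)

#' An ordered CT image series with examination metadata
#'
#' Slices are sorted by ascending table position on construction; duplicate z
#' positions are an error.
#'
#' @param slices List of [ct_slice] objects (any order).
#' @param ctdi_vol Examination CTDIvol in mGy, 32-cm body phantom reference
#'   (`NA` if not yet known).
#' @param exam_type One of `"chest"`, `"CAP"`, `"phantom"`.
#' @param scanner_id Scanner label.
#' @param patient Optional [patient_bio].
#' @return An object of class `scan_series`.
#' @export
scan_series <- function(slices, ctdi_vol = NA_real_,
                        exam_type = c("phantom", "chest", "CAP"),
                        scanner_id = "unknown", patient = NULL) {
  exam_type <- match.arg(exam_type)
  if (!is.list(slices) || length(slices) < 1L)
    stop("'slices' must be a non-empty list of ct_slice objects")
  if (!all(vapply(slices, inherits, TRUE, what = "ct_slice")))
    stop("all elements of 'slices' must be ct_slice objects")
  z <- vapply(slices, function(s) s$z_position, 0)
  if (anyDuplicated(z)) stop("duplicate slice z positions")
  slices <- slices[order(z)]
  if (!is.na(ctdi_vol) && ctdi_vol < 0) stop("'ctdi_vol' must be >= 0")
  if (!is.null(patient) && !inherits(patient, "patient_bio"))
    stop("'patient' must be a patient_bio object")
  structure(
    list(slices = slices, ctdi_vol = as.numeric(ctdi_vol),
         exam_type = exam_type, scanner_id = scanner_id, patient = patient),
    class = "scan_series")
}

#' Patient biometrics
#'
#' @param weight Body weight in kg.
#' @param height Height in cm.
#' @param sex `"F"` or `"M"`.
#' @param age Age in years (optional).
#' @return An object of class `patient_bio`.
#' @export
patient_bio <- function(weight, height, sex = c("F", "M"), age = NA_real_) {
  sex <- match.arg(sex)
  stop_if_not_scalar_pos(weight, "weight")
  stop_if_not_scalar_pos(height, "height")
  structure(list(weight = weight, height = height, sex = sex, age = age),
            class = "patient_bio")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice #%d> %dx%d px, %.3gx%.3g mm, z = %.1f mm, I = %s mA\n",
              x$slice_id, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2], x$z_position,
              if (is.na(x$tube_current)) "?" else format(x$tube_current)))
  invisible(x)
}

#' @export
print.scan_series <- function(x, ...) {
  z <- vapply(x$slices, function(s) s$z_position, 0)
  cat(sprintf("<scan_series> %s on %s: %d slices, z %.1f..%.1f mm, CTDIvol %s mGy\n",
              x$exam_type, x$scanner_id, length(x$slices), min(z), max(z),
              if (is.na(x$ctdi_vol)) "?" else format(x$ctdi_vol)))
  invisible(x)
}

#' @export
print.patient_bio <- function(x, ...) {
  cat(sprintf("<patient_bio> %s, %.0f kg, %.0f cm (BMI %.1f kg/m2)\n",
              x$sex, x$weight, x$height, bmi(x$weight, x$height)))
  invisible(x)
}

# z positions of a series, ascending by construction.
series_z <- function(series) vapply(series$slices, function(s) s$z_position, 0)

# tube currents of a series (may contain NA).
series_currents <- function(series)
  vapply(series$slices, function(s) s$tube_current, 0)
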