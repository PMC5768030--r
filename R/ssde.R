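# Size-specific dose estimate: SSDE = CTDIvol * f(Dw), with f the
# size-dependent conversion factor for CTDIvol referenced to the 32-cm body
# phantom. The packaged factor table is tabulated at 1-cm steps from the
# published exponential parameterization
#     f(D) = 3.704369 * exp(-0.03671937 * D),   D in cm,
# which is the standard fit distributed with the body-phantom factor tables;
# head-phantom (16 cm) factors are not supported.

#' Conversion-factor table constructor
#'
#' @param diameters Patient water-equivalent diameters in cm, strictly
#'   increasing.
#' @param factors Conversion factors, strictly decreasing, all positive.
#' @return An object of class `conversion_table`.
#' @export
conversion_table <- function(diameters, factors) {
  if (length(diameters) == 0L) stop("empty conversion table")
  if (length(diameters) != length(factors))
    stop("'diameters' and 'factors' must have equal length")
  if (is.unsorted(diameters, strictly = TRUE))
    stop("'diameters' must be strictly increasing")
  if (any(factors <= 0) || any(diff(factors) >= 0))
    stop("'factors' must be positive and strictly decreasing")
  structure(list(diameters = as.numeric(diameters),
                 factors = as.numeric(factors), phantom_ref = "body-32cm"),
            class = "conversion_table")
}

#' Packaged 32-cm body phantom conversion-factor table
#'
#' Factors for diameters 6-55 cm at 1-cm steps, tabulated from the published
#' exponential parameterization (see [f32_fit]).
#'
#' @return A `conversion_table`.
#' @export
f32_table <- function() {
  csv <- system.file("extdata", "f32_conversion.csv", package = "dwmetrics",
                     mustWork = TRUE)
  tab <- utils::read.csv(csv)
  conversion_table(tab$diameter_cm, tab$factor)
}

#' Exponential conversion-factor fit (32-cm body phantom)
#'
#' The continuous parameterization `3.704369 * exp(-0.03671937 * dw)`
#' underlying the packaged table; kept as an independent cross-check of the
#' interpolated table values.
#'
#' @param dw Water-equivalent diameter in cm.
#' @return Conversion factor(s).
#' @export
f32_fit <- function(dw) 3.704369 * exp(-0.03671937 * dw)

#' Interpolate a size-dependent conversion factor
#'
#' Piecewise-linear interpolation in diameter. Outside the tabulated range the
#' factor clamps to the nearest endpoint with a warning.
#'
#' @param dw Water-equivalent diameter in cm (vectorized).
#' @param table A [conversion_table]; default the packaged 32-cm body table.
#' @return Conversion factor(s).
#' @export
conversion_factor <- function(dw, table = f32_table()) {
  stopifnot(inherits(table, "conversion_table"))
  rng <- range(table$diameters)
  if (any(dw < rng[1] | dw > rng[2]))
    warning(sprintf("Dw outside tabulated range [%g, %g] cm; factor clamped to endpoint",
                    rng[1], rng[2]))
  stats::approx(table$diameters, table$factors, xout = dw, rule = 2)$y
}

#' Size-specific dose estimate
#'
#' `SSDE = ctdi_vol * f(dw)`. The size metric is Dw_c in the standard
#' formulation; `metric` records which metric `dw` is, for downstream
#' bookkeeping in comparative analyses.
#'
#' @param ctdi_vol Examination CTDIvol in mGy (32-cm body phantom reference),
#'   `>= 0`.
#' @param dw Water-equivalent diameter in cm.
#' @param table A [conversion_table].
#' @param metric Which size metric `dw` is: `"dwc"` (default) or `"dwave"`.
#' @return SSDE in mGy, with attribute `metric`.
#' @export
#' @examples
#' ssde(10, 25)
ssde <- function(ctdi_vol, dw, table = f32_table(), metric = c("dwc", "dwave")) {
  metric <- match.arg(metric)
  if (any(ctdi_vol < 0)) stop("'ctdi_vol' must be >= 0")
  structure(ctdi_vol * conversion_factor(dw, table), metric = metric)
}

#' @export
print.conversion_table <- function(x, ...) {
  cat(sprintf("<conversion_table> %s: %d entries, D %g..%g cm, f %.3g..%.3g\n",
              x$phantom_ref, length(x$diameters), min(x$diameters),
              max(x$diameters), max(x$factors), min(x$factors)))
  invisible(x)
}
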