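# Cohort-level statistics: linear fits of dose indices against patient size
# metrics, metric-difference summaries, and descriptive cohort tables.
#
# Record layout used throughout ("exam records", one row per examination):
#   patient_id, scanner_id, exam_type, sex, weight_kg, height_cm,
#   ctdivol_mGy, dwc_cm, dwave_cm, dwmin_cm, dwmax_cm, ssde_mGy
# All SDs reported by this module are population SDs (n denominator).

#' Body mass index
#'
#' @param weight Weight in kg, positive.
#' @param height Height in cm, positive.
#' @return BMI in kg/m^2.
#' @export
#' @examples
#' bmi(70, 167)  # 25.1
bmi <- function(weight, height) {
  if (any(weight <= 0) || any(height <= 0))
    stop("'weight' and 'height' must be positive")
  weight / (height / 100)^2
}

#' Ordinary least-squares fit with R-squared
#'
#' Simple linear regression `y ~ x` via [stats::lm], reporting slope,
#' intercept and the coefficient of determination. A constant response is
#' reported as `r_squared = 0` with a warning; a constant predictor is an
#' error.
#'
#' @param x Predictor.
#' @param y Response, same length as `x`, at least 3 points.
#' @param x_name,y_name Labels carried into the result.
#' @return An object of class `fit_result` with fields `slope`, `intercept`,
#'   `r_squared`, `n`, `x_name`, `y_name`.
#' @export
linear_fit <- function(x, y, x_name = deparse1(substitute(x)),
                       y_name = deparse1(substitute(y))) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) != length(y) || length(x) < 3L)
    stop("need at least 3 complete (x, y) pairs")
  if (max(x) == min(x)) stop("constant predictor: slope undefined")
  fit <- stats::lm(y ~ x)
  if (max(y) == min(y)) {
    warning("constant response; r_squared reported as 0")
    r2 <- 0
  } else {
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  }
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n = length(x),
                 x_name = x_name, y_name = y_name),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s = %.4g + %.4g * %s   (R^2 = %.3f, n = %d)\n",
              x$y_name, x$intercept, x$slope, x$x_name, x$r_squared, x$n))
  invisible(x)
}

# Size-metric column lookup; bmi derived on the fly.
.metric_values <- function(records, metric) {
  switch(metric,
         weight = records$weight_kg,
         bmi = ifelse(!is.na(records$weight_kg) & !is.na(records$height_cm) &
                        records$weight_kg > 0 & records$height_cm > 0,
                      records$weight_kg / (records$height_cm / 100)^2,
                      NA_real_),
         dw_c = records$dwc_cm,
         dw_ave = records$dwave_cm,
         stop("unknown metric: ", metric))
}

#' R-squared grid: dose indices vs patient size metrics
#'
#' For each (scanner, exam type) stratum, fits each dose index against each
#' size metric and tabulates slope, intercept and R-squared. Records lacking
#' biometrics are dropped from the weight/BMI cells only, with the usable
#' count reported per cell. Cells with fewer than 3 usable records are marked
#' unavailable (`NA` fit fields).
#'
#' @param records Exam-record data frame (see module header).
#' @param metrics Size metrics to compare; subset of
#'   `c("weight", "bmi", "dw_c", "dw_ave")`.
#' @param doses Dose indices; subset of `c("ctdi_vol", "ssde")`.
#' @return Data frame of class `metric_comparison`: one row per
#'   (scanner, exam type, dose, metric) with `slope`, `intercept`,
#'   `r_squared`, `n`, `n_dropped`.
#' @export
metric_comparison <- function(records,
                              metrics = c("weight", "bmi", "dw_c", "dw_ave"),
                              doses = c("ctdi_vol", "ssde")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  doses <- match.arg(doses, several.ok = TRUE)
  strata <- unique(records[, c("scanner_id", "exam_type")])
  out <- NULL
  for (si in seq_len(nrow(strata))) {
    sub <- records[records$scanner_id == strata$scanner_id[si] &
                     records$exam_type == strata$exam_type[si], , drop = FALSE]
    for (dose in doses) {
      yv <- if (dose == "ctdi_vol") sub$ctdivol_mGy else sub$ssde_mGy
      for (metric in metrics) {
        xv <- .metric_values(sub, metric)
        ok <- !is.na(xv) & !is.na(yv)
        row <- data.frame(scanner_id = strata$scanner_id[si],
                          exam_type = strata$exam_type[si],
                          dose = dose, metric = metric,
                          slope = NA_real_, intercept = NA_real_,
                          r_squared = NA_real_, n = sum(ok),
                          n_dropped = nrow(sub) - sum(ok))
        if (sum(ok) >= 3L && max(xv[ok]) > min(xv[ok])) {
          fit <- linear_fit(xv[ok], yv[ok], x_name = metric, y_name = dose)
          row$slope <- fit$slope; row$intercept <- fit$intercept
          row$r_squared <- fit$r_squared
        }
        out <- rbind(out, row)
      }
    }
  }
  class(out) <- c("metric_comparison", "data.frame")
  out
}

#' @export
print.metric_comparison <- function(x, digits = 3, ...) {
  cat("R-squared of linear fits: dose index vs size metric\n")
  df <- as.data.frame(x)
  df$r_squared <- round(df$r_squared, digits)
  print(df[, c("scanner_id", "exam_type", "dose", "metric", "r_squared", "n")],
        row.names = FALSE)
  invisible(x)
}

# mean +/- population SD of v within rows `idx`, in cm and in % of dwave.
.diff_row <- function(records, idx, exam, sex) {
  r <- records[idx, , drop = FALSE]
  dcm <- r$dwc_cm - r$dwave_cm
  dpc <- 100 * dcm / r$dwave_cm
  rcm <- r$dwmax_cm - r$dwmin_cm
  rpc <- 100 * rcm / r$dwave_cm
  data.frame(exam_type = exam, sex = sex, n = nrow(r),
             dwc_minus_dwave_pct_mean = mean(dpc),
             dwc_minus_dwave_pct_sd = sd_pop(dpc),
             dwc_minus_dwave_cm_mean = mean(dcm),
             dwc_minus_dwave_cm_sd = sd_pop(dcm),
             dw_range_pct_mean = mean(rpc),
             dw_range_pct_sd = sd_pop(rpc),
             dw_range_cm_mean = mean(rcm),
             dw_range_cm_sd = sd_pop(rcm))
}

#' Differences between the two size metrics, and Dw variation
#'
#' Per exam type and sex (plus an "All" stratum per exam type): mean and
#' population SD of `Dw_c - Dw_ave` and of `Dw_max - Dw_min`, each in cm and
#' in percent of Dw_ave (signed).
#'
#' @param records Exam-record data frame.
#' @return Data frame with one row per stratum.
#' @export
difference_stats <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  out <- NULL
  for (exam in unique(records$exam_type)) {
    ei <- records$exam_type == exam
    for (sx in intersect(c("F", "M"), unique(records$sex[ei])))
      out <- rbind(out, .diff_row(records, ei & records$sex == sx, exam, sx))
    out <- rbind(out, .diff_row(records, ei, exam, "All"))
  }
  out
}

#' Do two examination types share one dose-size curve?
#'
#' Measures how much allowing separate CTDIvol-vs-Dw_ave lines per
#' examination type improves on a single pooled line, as the difference in
#' R-squared between the nested models `dose ~ dw_ave * exam_type` and
#' `dose ~ dw_ave`, both fitted to the pooled records. Near-zero gap means
#' the examination types fall on a common curve.
#'
#' @param records Exam-record data frame with at least two exam types.
#' @param dose `"ctdi_vol"` (default) or `"ssde"`.
#' @return List: `r2_pooled`, `r2_stratified`, `gap` (stratified minus
#'   pooled, always `>= 0`).
#' @export
common_curve_gap <- function(records, dose = c("ctdi_vol", "ssde")) {
  dose <- match.arg(dose)
  y <- if (dose == "ctdi_vol") records$ctdivol_mGy else records$ssde_mGy
  x <- records$dwave_cm
  g <- factor(records$exam_type)
  if (nlevels(g) < 2L) stop("need at least two exam types")
  r2p <- summary(stats::lm(y ~ x))$r.squared
  r2s <- summary(stats::lm(y ~ x * g))$r.squared
  list(r2_pooled = r2p, r2_stratified = r2s, gap = r2s - r2p)
}

#' Descriptive cohort summary
#'
#' Per (scanner, exam type) stratum: mean and population SD of CTDIvol and
#' SSDE, and mean (min-max) of weight, height and BMI where biometrics exist.
#'
#' @param records Exam-record data frame.
#' @return Data frame with one row per stratum.
#' @export
cohort_summary <- function(records) {
  if (nrow(records) == 0L) stop("no records")
  strata <- unique(records[, c("scanner_id", "exam_type")])
  out <- NULL
  for (si in seq_len(nrow(strata))) {
    r <- records[records$scanner_id == strata$scanner_id[si] &
                   records$exam_type == strata$exam_type[si], , drop = FALSE]
    has_bio <- !is.na(r$weight_kg) & !is.na(r$height_cm)
    b <- r[has_bio, , drop = FALSE]
    bmiv <- if (nrow(b)) bmi(b$weight_kg, b$height_cm) else numeric(0)
    rng <- function(v, f = "%.1f") {
      if (!length(v)) return(NA_character_)
      sprintf(paste0(f, " (", f, "-", f, ")"), mean(v), min(v), max(v))
    }
    out <- rbind(out, data.frame(
      scanner_id = strata$scanner_id[si], exam_type = strata$exam_type[si],
      n = nrow(r), n_with_biometrics = nrow(b),
      mean_ctdivol = mean(r$ctdivol_mGy), sd_ctdivol = sd_pop(r$ctdivol_mGy),
      mean_ssde = mean(r$ssde_mGy), sd_ssde = sd_pop(r$ssde_mGy),
      weight_kg = rng(b$weight_kg), height_cm = rng(b$height_cm),
      bmi = rng(bmiv)))
  }
  attr(out, "sd_convention") <- "population (n denominator)"
  out
}
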