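# Imin thresholding simulation: raising the ATCM minimum tube current is
# emulated by clamping the recorded I(z) series from below and rescaling the
# examination CTDIvol by the ratio of mean currents (CTDIvol is proportional
# to mean tube current at fixed kV, pitch and rotation time). Only Imin values
# at or above the originally applied minimum are meaningful; lower values
# reproduce the original examination.

#' Threshold a tube-current series at a minimum value
#'
#' @param current Recorded I(z) in mA, all positive.
#' @param imin Minimum tube current in mA, positive.
#' @return `pmax(current, imin)`, same length.
#' @export
threshold_currents <- function(current, imin) {
  if (length(current) == 0L) stop("empty tube-current array")
  if (any(is.na(current)) || any(current <= 0))
    stop("all tube currents must be positive and non-missing")
  stop_if_not_scalar_pos(imin, "imin")
  pmax(current, imin)
}

#' Simulated examination CTDIvol under a raised Imin
#'
#' @param ctdi_vol Original examination CTDIvol in mGy, `>= 0`.
#' @param current Recorded I(z) in mA.
#' @param imin Simulated minimum tube current in mA. Values at or below
#'   `min(current)` return `ctdi_vol` unchanged (with a warning when below the
#'   recorded minimum, since only raised minima are simulable).
#' @return Simulated CTDIvol in mGy:
#'   `ctdi_vol * mean(pmax(current, imin)) / mean(current)`.
#' @export
#' @examples
#' simulate_ctdivol(10, c(100, 200, 300), 150)  # 10 * (650/3) / 200
simulate_ctdivol <- function(ctdi_vol, current, imin) {
  if (length(ctdi_vol) != 1L || is.na(ctdi_vol) || ctdi_vol < 0)
    stop("'ctdi_vol' must be a single number >= 0")
  thr <- threshold_currents(current, imin)
  if (imin < min(current))
    warning("imin below the recorded minimum current; returning the original CTDIvol")
  ctdi_vol * mean(thr) / mean(current)
}

#' An Imin scenario
#'
#' @param imin Minimum tube current in mA, positive.
#' @param label Scenario label; default `"Imin<value>"`.
#' @return An object of class `imin_scenario`.
#' @export
imin_scenario <- function(imin, label = sprintf("Imin%g", imin)) {
  stop_if_not_scalar_pos(imin, "imin")
  structure(list(imin = imin, label = label), class = "imin_scenario")
}

#' Sweep Imin scenarios over a cohort
#'
#' For each scenario, recomputes every examination's CTDIvol under the raised
#' Imin and the corresponding SSDE using the examination's original Dw_c (the
#' patient's size is unchanged by the scenario), then summarizes across
#' examinations as mean and population SD. A `"baseline"` row reports the
#' unsimulated cohort.
#'
#' @param records Data frame with columns `ctdivol_mGy` and `dwc_cm`.
#' @param currents List of I(z) vectors (mA), one per record.
#' @param scenarios List of [imin_scenario] objects (or a numeric vector of
#'   Imin values in mA).
#' @param table A [conversion_table] for the SSDE recomputation.
#' @return Data frame with one row per scenario (baseline first): `scenario`,
#'   `imin_mA`, `n`, `n_skipped`, `mean_ctdivol`, `sd_ctdivol`, `mean_ssde`,
#'   `sd_ssde`. SDs are population SDs. Records without currents are skipped
#'   with a warning and counted in `n_skipped`.
#' @export
scenario_sweep <- function(records, currents, scenarios, table = f32_table()) {
  if (is.numeric(scenarios)) scenarios <- lapply(scenarios, imin_scenario)
  if (!all(vapply(scenarios, inherits, TRUE, what = "imin_scenario")))
    stop("'scenarios' must be imin_scenario objects or a numeric vector")
  if (length(currents) != nrow(records))
    stop("'currents' must have one entry per record")
  usable <- vapply(currents, function(cc)
    length(cc) > 0L && !any(is.na(cc)) && all(cc > 0), TRUE)
  n_skip <- sum(!usable)
  if (n_skip > 0L)
    warning(n_skip, " record(s) lack tube-current data and were skipped")
  rec <- records[usable, , drop = FALSE]
  cur <- currents[usable]
  fac <- conversion_factor(rec$dwc_cm, table)

  row_for <- function(label, imin, ctdi) {
    data.frame(scenario = label, imin_mA = imin, n = nrow(rec),
               n_skipped = n_skip,
               mean_ctdivol = mean(ctdi), sd_ctdivol = sd_pop(ctdi),
               mean_ssde = mean(ctdi * fac), sd_ssde = sd_pop(ctdi * fac))
  }
  out <- row_for("baseline", NA_real_, rec$ctdivol_mGy)
  for (sc in scenarios) {
    ctdi <- vapply(seq_len(nrow(rec)), function(i)
      suppressWarnings(simulate_ctdivol(rec$ctdivol_mGy[i], cur[[i]], sc$imin)),
      0)
    out <- rbind(out, row_for(sc$label, sc$imin, ctdi))
  }
  attr(out, "sd_convention") <- "population (n denominator)"
  out
}
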