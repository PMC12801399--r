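#' Construct an extracellular-flux trace
#'
#' A flux trace is the raw time series recorded in one measurement well:
#' per measurement cycle, time (h), oxygen partial pressure (mmHg) and
#' medium pH. The default layout is three cycles at 20-minute intervals
#' under basal conditions.
#'
#' @param cycle integer cycle index per sample.
#' @param t_h sample time, h (non-decreasing overall, increasing within a
#'   cycle).
#' @param o2_mmHg oxygen partial pressure readings.
#' @param ph pH readings.
#' @param well well identifier.
#' @param is_blank TRUE for a cell-free background well.
#' @return data.frame of class `"flux_trace"` with one row per sample.
#' @export
flux_trace <- function(cycle, t_h, o2_mmHg, ph, well = "A1",
                       is_blank = FALSE) {
  df <- data.frame(well = well, is_blank = is_blank, cycle = as.integer(cycle),
                   t_h = t_h, o2_mmHg = o2_mmHg, ph = ph)
  for (cy in split(df, df$cycle)) {
    if (nrow(cy) < 2L)
      stop("each measurement cycle needs at least two samples")
    if (any(diff(cy$t_h) <= 0))
      stop("sample times must be strictly increasing within a cycle")
  }
  class(df) <- c("flux_trace", "data.frame")
  df
}

# per-cycle least-squares slopes of one column vs time
.cycle_slopes <- function(trace, column) {
  vapply(split(trace, trace$cycle), function(cy) {
    unname(stats::coef(stats::.lm.fit(cbind(1, cy$t_h - cy$t_h[1]),
                                      cy[[column]]))[2])
  }, numeric(1))
}

.check_trace_pair <- function(trace, blank, cells_in_well) {
  if (is.null(blank)) stop("a matched blank trace is required")
  if (!isTRUE(all(!trace$is_blank)))
    stop("'trace' must come from a cell-containing well")
  if (!isTRUE(all(blank$is_blank)))
    stop("'blank' must come from a blank (cell-free) well")
  if (!setequal(unique(trace$cycle), unique(blank$cycle)))
    stop("trace and blank must share the same measurement cycles")
  if (cells_in_well <= 0) stop("cells_in_well must be positive")
}

#' Oxygen consumption rate from a flux trace
#'
#' Per cycle, the O2 partial-pressure decline is fitted by least squares;
#' the matched blank-well slope is subtracted to remove background drift;
#' the corrected slope is converted to a molar rate through the O2
#' solubility (mmHg -> mM) and the effective measurement chamber volume,
#' then normalized per 10^6 cells. Cycles are averaged. A negative
#' corrected rate is reported as-is with `flagged = TRUE`, never silently
#' clipped.
#'
#' @param trace,blank [flux_trace()] objects (cell well / matched blank).
#' @param cells_in_well cell count in the measured well (e.g. from
#'   [cells_from_dna()]).
#' @param chamber_uL effective measurement chamber volume, uL.
#' @param o2_solubility mM dissolved O2 per mmHg at 37 C.
#' @return object of class `"rate_result"`: `rate`
#'   (nmol (10^6 cells)^-1 h^-1), per-cycle rates, and `flagged`.
#' @export
ocr_from_trace <- function(trace, blank, cells_in_well,
                           chamber_uL = 22.7, o2_solubility = 1.3e-3) {
  .check_trace_pair(trace, blank, cells_in_well)
  s_tr <- .cycle_slopes(trace, "o2_mmHg")
  s_bl <- .cycle_slopes(blank, "o2_mmHg")
  corrected <- s_tr - s_bl[names(s_tr)]           # mmHg/h, negative = uptake
  # mmHg/h * mM/mmHg * uL = nmol/h (1 mM = 1 nmol/uL)
  per_cycle <- -corrected * o2_solubility * chamber_uL /
    (cells_in_well / 1e6)
  rate <- mean(per_cycle)
  structure(list(quantity = "OCR", rate = rate, per_cycle = per_cycle,
                 flagged = rate < 0, cells_in_well = cells_in_well),
            class = "rate_result")
}

#' Lactate production rate from a flux trace
#'
#' The medium acidification slope (pH/h, blank-corrected) is converted to
#' a lactate flux through the medium buffering coefficient (mM lactate per
#' pH unit, the linearized pH-lactate relationship of the assay medium)
#' and the chamber volume, then normalized per 10^6 cells.
#'
#' @inheritParams ocr_from_trace
#' @param buffering_mM_per_pH mM lactate per unit pH decline in the assay
#'   medium (required configuration; the default is a documented
#'   placeholder for unbuffered assay medium).
#' @return object of class `"rate_result"` with the LPR in
#'   nmol (10^6 cells)^-1 h^-1.
#' @export
lpr_from_trace <- function(trace, blank, cells_in_well,
                           chamber_uL = 22.7, buffering_mM_per_pH = 10) {
  .check_trace_pair(trace, blank, cells_in_well)
  s_tr <- .cycle_slopes(trace, "ph")
  s_bl <- .cycle_slopes(blank, "ph")
  corrected <- s_tr - s_bl[names(s_tr)]           # pH/h, negative = acidif.
  per_cycle <- -corrected * buffering_mM_per_pH * chamber_uL /
    (cells_in_well / 1e6)
  rate <- mean(per_cycle)
  structure(list(quantity = "LPR", rate = rate, per_cycle = per_cycle,
                 flagged = rate < 0, cells_in_well = cells_in_well),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("%s: %.4g nmol/(10^6 cells)/h over %d cycles%s\n",
              x$quantity, x$rate, length(x$per_cycle),
              if (x$flagged) " [FLAGGED: negative corrected rate]" else ""))
  invisible(x)
}

#' Cell number from DNA content
#'
#' Converts a DNA mass to a cell count through a per-cell DNA content
#' (standard-curve calibration; default 7.7 pg DNA per cell).
#'
#' @param dna_ng DNA mass, ng (> 0).
#' @param pg_per_cell DNA per cell, pg (> 0).
#' @return cell count (`dna_ng * 1000 / pg_per_cell`).
#' @examples
#' cells_from_dna(7.7)  # 1000 cells
#' @export
cells_from_dna <- function(dna_ng, pg_per_cell = 7.7) {
  if (any(dna_ng <= 0) || pg_per_cell <= 0)
    stop("DNA mass and per-cell DNA content must be positive")
  dna_ng * 1000 / pg_per_cell
}
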