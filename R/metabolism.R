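#' Per-cell metabolic rates
#'
#' Bundle of oxygen consumption (OCR), lactate production (LPR) and glucose
#' consumption (GCR) rates, all in nmol per 10^6 cells per hour. When `gcr`
#' is not supplied it is derived from the LPR under the anaerobic-glycolysis
#' stoichiometry (two lactate per glucose), i.e. GCR = LPR / 2.
#'
#' @param ocr oxygen consumption rate, nmol (10^6 cells)^-1 h^-1.
#' @param lpr lactate production rate, same units.
#' @param gcr glucose consumption rate, same units; defaults to `lpr / 2`.
#' @return an object of class `"metabolic_rates"`: a named list with
#'   elements `ocr`, `lpr`, `gcr` and a flag `gcr_derived`.
#' @examples
#' metabolic_rates(ocr = 3.8, lpr = 20)
#' @export
metabolic_rates <- function(ocr, lpr, gcr = NULL) {
  stopifnot(is.numeric(ocr), length(ocr) == 1L,
            is.numeric(lpr), length(lpr) == 1L)
  if (ocr < 0 || lpr < 0)
    stop("metabolic rates must be non-negative")
  derived <- is.null(gcr)
  if (derived) gcr <- gcr_from_lpr(lpr)
  if (gcr < 0) stop("metabolic rates must be non-negative")
  structure(list(ocr = ocr, lpr = lpr, gcr = gcr, gcr_derived = derived),
            class = "metabolic_rates")
}

#' @export
print.metabolic_rates <- function(x, ...) {
  cat("Per-cell metabolic rates [nmol/(10^6 cells)/h]\n")
  cat(sprintf("  OCR: %.4g   LPR: %.4g   GCR: %.4g%s\n",
              x$ocr, x$lpr, x$gcr,
              if (x$gcr_derived) " (= LPR/2)" else ""))
  invisible(x)
}

#' Glucose consumption rate from lactate production rate
#'
#' Under anaerobic glycolysis one glucose yields two lactate, so the glucose
#' consumption rate is half the lactate production rate.
#'
#' @param lpr lactate production rate (any consistent rate unit), >= 0.
#' @return `lpr / 2` in the same unit.
#' @examples
#' gcr_from_lpr(2)  # 1
#' @export
gcr_from_lpr <- function(lpr) {
  if (any(lpr < 0)) stop("lpr must be non-negative")
  lpr / 2
}

#' Regional cell densities scaled by viability
#'
#' Total tissue cell densities for the nucleus pulposus (NP) and annulus
#' fibrosus (AF), scaled by a scenario viability fraction to obtain the
#' metabolically active densities used as sink multipliers. Defaults are the
#' caprine tissue densities (NP 6133, AF 19732 cells mm^-3) with viability
#' 0.40 (degenerated) or 0.80 (healthy).
#'
#' @param scenario `"degenerated"` or `"healthy"`; sets the default
#'   viability (0.40 / 0.80).
#' @param total named numeric vector `c(NP = , AF = )`, cells mm^-3.
#' @param viability fraction in \[0, 1\] applied to both regions.
#' @return object of class `"cell_densities"` with elements `total`,
#'   `viability`, `active` (all per region; `active = total * viability`).
#' @examples
#' cell_densities("healthy")$active   # NP 4906.4, AF 15785.6
#' @export
cell_densities <- function(scenario = c("degenerated", "healthy"),
                           total = c(NP = 6133, AF = 19732),
                           viability = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(viability))
    viability <- if (scenario == "degenerated") 0.40 else 0.80
  stopifnot(all(c("NP", "AF") %in% names(total)))
  if (any(total < 0)) stop("total densities must be non-negative")
  if (viability < 0 || viability > 1) stop("viability must lie in [0, 1]")
  total <- total[c("NP", "AF")]
  structure(list(scenario = scenario, total = total, viability = viability,
                 active = total * viability),
            class = "cell_densities")
}

#' @export
print.cell_densities <- function(x, ...) {
  cat(sprintf("Cell densities (%s, viability %.0f%%) [cells/mm^3]\n",
              x$scenario, 100 * x$viability))
  cat(sprintf("  NP: total %g, active %g\n", x$total["NP"], x$active["NP"]))
  cat(sprintf("  AF: total %g, active %g\n", x$total["AF"], x$active["AF"]))
  invisible(x)
}

#' Volumetric sink from a per-cell rate and an active cell density
#'
#' Converts a per-cell metabolic rate to a volumetric reaction term:
#' nmol (10^6 cells)^-1 h^-1 x cells mm^-3 -> nmol mm^-3 h^-1, and
#' 1 nmol mm^-3 = 1 mM, so the result is in mM h^-1.
#'
#' @param per_cell_rate rate in nmol (10^6 cells)^-1 h^-1, >= 0.
#' @param active_density active cells mm^-3, >= 0.
#' @return volumetric rate, mM h^-1.
#' @examples
#' volumetric_sink(3.8, 4906.4)  # 0.0186 mM/h
#' @export
volumetric_sink <- function(per_cell_rate, active_density) {
  if (any(per_cell_rate < 0) || any(active_density < 0))
    stop("rate and density must be non-negative")
  per_cell_rate * active_density * 1e-6
}

#' Depletion-limited sink
#'
#' Michaelis-type clamp preventing consumption from driving a concentration
#' negative: the zeroth-order sink is multiplied by c / (c + Km). For
#' concentrations far above `half_saturation` the sink approaches its base
#' value; it vanishes linearly as the species depletes.
#'
#' @param base_sink zeroth-order volumetric sink, mM h^-1.
#' @param concentration local concentration (same unit family as
#'   `half_saturation`).
#' @param half_saturation Km of the clamp, > 0.
#' @return clamped sink, never exceeding `base_sink`.
#' @export
clamped_sink <- function(base_sink, concentration, half_saturation) {
  if (any(half_saturation <= 0)) stop("half_saturation must be > 0")
  conc <- pmax(concentration, 0)
  base_sink * conc / (conc + half_saturation)
}

#' Linear lactate to pH map
#'
#' Tissue pH is modelled as a linearly decreasing function of lactate
#' concentration, pH = intercept - slope * lactate. The default
#' coefficients are fitted through the two anchor pairs (0.465 mM, pH 7.45)
#' and (5.379 mM, pH 6.96) reported for caprine NP tissue.
#'
#' @param intercept pH at zero lactate.
#' @param slope pH decrease per mM lactate, > 0.
#' @return object of class `"ph_lactate_map"`.
#' @examples
#' m <- ph_lactate_map()
#' lactate_to_ph(0.465, m)  # ~7.45
#' @export
ph_lactate_map <- function(intercept = NULL, slope = NULL) {
  if (is.null(intercept) || is.null(slope)) {
    # line through the two published anchor pairs
    anchors_mM <- c(0.465, 5.379)
    anchors_ph <- c(7.45, 6.96)
    s <- -diff(anchors_ph) / diff(anchors_mM)
    i <- anchors_ph[1] + s * anchors_mM[1]
    if (is.null(slope)) slope <- s
    if (is.null(intercept)) intercept <- i
  }
  if (slope <= 0) stop("slope must be > 0 (pH decreases with lactate)")
  structure(list(intercept = intercept, slope = slope),
            class = "ph_lactate_map")
}

#' @export
print.ph_lactate_map <- function(x, ...) {
  cat(sprintf("pH(lactate) = %.4f - %.5f * lactate[mM]\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Convert lactate concentration to pH
#'
#' @param lactate lactate concentration, mM (>= 0).
#' @param map a [ph_lactate_map()].
#' @return pH values.
#' @export
lactate_to_ph <- function(lactate, map = ph_lactate_map()) {
  if (any(lactate < 0)) stop("lactate must be non-negative")
  map$intercept - map$slope * lactate
}

#' Convert pH to lactate concentration (inverse map)
#'
#' @param ph pH values at or below the map intercept.
#' @param map a [ph_lactate_map()].
#' @return lactate, mM.
#' @export
ph_to_lactate <- function(ph, map = ph_lactate_map()) {
  lac <- (map$intercept - ph) / map$slope
  if (any(lac < 0))
    stop("pH above the zero-lactate intercept has no non-negative lactate")
  lac
}

#' Oxygen unit conversion between percent and mM
#'
#' Dissolved oxygen is carried in percent-of-atmosphere units throughout the
#' disc model; the default conversion factor 0.00925 mM per % follows the
#' 2--10% <-> 0.0185--0.0925 mM correspondence for tissue at 37 C.
#'
#' @param percent oxygen tension, % (>= 0).
#' @param mM dissolved oxygen, mM (>= 0).
#' @param factor mM per % (strictly positive).
#' @return the converted value.
#' @examples
#' oxygen_percent_to_mM(2)      # 0.0185
#' oxygen_mM_to_percent(0.0925) # 10
#' @export
oxygen_percent_to_mM <- function(percent, factor = 0.00925) {
  if (factor <= 0) stop("conversion factor must be > 0")
  if (any(percent < 0)) stop("oxygen percent must be non-negative")
  percent * factor
}

#' @rdname oxygen_percent_to_mM
#' @export
oxygen_mM_to_percent <- function(mM, factor = 0.00925) {
  if (factor <= 0) stop("conversion factor must be > 0")
  if (any(mM < 0)) stop("oxygen concentration must be non-negative")
  mM / factor
}
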