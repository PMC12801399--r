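#' The 24-condition factorial culture design
#'
#' Full crossing of oxygen (2, 5 %), pH (6.5, 6.8, 7.1), glucose (0.5,
#' 1.0 mM) and osmolarity (350, 500 mOsm), in the canonical nesting order
#' (oxygen, then pH, then glucose, then osmolarity), yielding culture
#' groups 1-24; group 1 is (2 %, pH 6.5, 0.5 mM, 350 mOsm).
#'
#' @param oxygen,ph,glucose,osmolarity factor levels.
#' @return data.frame with columns `group`, `oxygen_pct`, `ph`,
#'   `glucose_mM`, `osmolarity_mOsm`.
#' @export
generate_design <- function(oxygen = c(2, 5), ph = c(6.5, 6.8, 7.1),
                            glucose = c(0.5, 1.0),
                            osmolarity = c(350, 500)) {
  g <- expand.grid(osmolarity_mOsm = osmolarity, glucose_mM = glucose,
                   ph = ph, oxygen_pct = oxygen, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("oxygen_pct", "ph", "glucose_mM", "osmolarity_mOsm")]
  data.frame(group = seq_len(nrow(g)), g)
}

#' Effect model for synthetic per-bead readouts
#'
#' Parameterizes the generator's qualitative effect structure: viability is
#' dominated by pH (anchored at 0.40 at pH 6.5 and 0.80 at pH 7.1,
#' intermediate at 6.8); DNA and GAG scale with viability; collagen is
#' constant across groups (the experiment's null finding). Donor effects
#' are additive on viability and multiplicative on biochemical readouts.
#'
#' @param viability_by_ph named mean viabilities per pH level.
#' @param donor_sd SD of the per-donor random effect (viability scale).
#' @param resid_sd residual SD of per-bead viability.
#' @param cells_per_bead encapsulated cells per bead.
#' @param pg_dna_per_cell DNA per cell, pg.
#' @param gag_pg_per_active_cell GAG produced per active cell over the
#'   24-day culture, pg.
#' @param hyp_ug_mean mean hydroxyproline per bead, ug (converted to
#'   collagen at 1:7.69; constant across groups).
#' @param biochem_cv multiplicative coefficient of variation of the
#'   biochemical readouts.
#' @return object of class `"effect_model"`.
#' @export
effect_model <- function(viability_by_ph = c("6.5" = 0.40, "6.8" = 0.60,
                                             "7.1" = 0.80),
                         donor_sd = 0.03, resid_sd = 0.04,
                         cells_per_bead = 20450,
                         pg_dna_per_cell = 7.7,
                         gag_pg_per_active_cell = 610,
                         hyp_ug_mean = 0.65,
                         biochem_cv = 0.10) {
  if (any(viability_by_ph < 0) || any(viability_by_ph > 1))
    stop("viability means must lie in [0, 1]")
  if (donor_sd < 0 || resid_sd < 0 || biochem_cv < 0)
    stop("dispersion parameters must be non-negative")
  if (cells_per_bead <= 0 || pg_dna_per_cell <= 0 ||
      gag_pg_per_active_cell < 0 || hyp_ug_mean < 0)
    stop("assay constants must be positive")
  structure(list(viability_by_ph = viability_by_ph, donor_sd = donor_sd,
                 resid_sd = resid_sd, cells_per_bead = cells_per_bead,
                 pg_dna_per_cell = pg_dna_per_cell,
                 gag_pg_per_active_cell = gag_pg_per_active_cell,
                 hyp_ug_mean = hyp_ug_mean, biochem_cv = biochem_cv),
            class = "effect_model")
}

#' Generate per-bead assay readouts for the factorial design
#'
#' Draws donor random effects, then per-bead readouts for every design
#' group: viability (fraction), DNA (ng), retained GAG (ug) and collagen
#' via hydroxyproline (ug). Mean viability follows the pH effect; DNA and
#' GAG scale with realized viability; collagen group means carry no pH
#' trend. Reproducible for a fixed seed.
#'
#' @param design a [generate_design()] table.
#' @param effects an [effect_model()].
#' @param seed integer RNG seed.
#' @param donors number of biological donors.
#' @param beads_per_purpose beads per donor per group for each assay
#'   purpose.
#' @return data.frame with one row per bead: design columns plus `donor`,
#'   `purpose`, `bead`, `viability`, `dna_ng`, `gag_ug`, `hyp_ug`,
#'   `collagen_ug` (biochemistry readouts are NA on non-biochemistry
#'   beads, viability on non-viability beads).
#' @export
generate_readouts <- function(design = generate_design(),
                              effects = effect_model(), seed,
                              donors = 3L,
                              beads_per_purpose = c(viability = 1L,
                                                    biochemistry = 3L,
                                                    histology = 2L)) {
  stopifnot(inherits(effects, "effect_model"), !missing(seed))
  set.seed(as.integer(seed))
  donor_eff <- stats::rnorm(donors, 0, effects$donor_sd)
  rows <- list()
  for (gi in seq_len(nrow(design))) {
    grp <- design[gi, ]
    mu_v <- effects$viability_by_ph[[as.character(grp$ph)]]
    for (d in seq_len(donors)) {
      for (purpose in names(beads_per_purpose)) {
        nb <- beads_per_purpose[[purpose]]
        if (nb == 0L) next
        v <- pmin(pmax(mu_v + donor_eff[d] +
                         stats::rnorm(nb, 0, effects$resid_sd), 0), 1)
        active <- effects$cells_per_bead * v
        noise <- function(n) 1 + stats::rnorm(n, 0, effects$biochem_cv)
        dna <- active * effects$pg_dna_per_cell / 1000 * noise(nb)
        gag <- active * effects$gag_pg_per_active_cell * 1e-6 * noise(nb)
        hyp <- effects$hyp_ug_mean * (1 + donor_eff[d]) * noise(nb)
        hyp <- pmax(hyp, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          grp, donor = d, purpose = purpose, bead = seq_len(nb),
          viability = if (purpose == "viability") v else NA_real_,
          dna_ng = if (purpose == "biochemistry") dna else NA_real_,
          gag_ug = if (purpose == "biochemistry") gag else NA_real_,
          hyp_ug = if (purpose == "biochemistry") hyp else NA_real_,
          collagen_ug = if (purpose == "biochemistry")
            hydroxyproline_to_collagen(hyp) else NA_real_,
          row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate raw flux traces with matched blanks
#'
#' Emits, for each row of `rates_by_group`, one cell-well and one matched
#' blank-well flux trace: three measurement cycles of linear decline (O2)
#' and acidification (pH) at 20-minute intervals, with Gaussian
#' measurement noise. Blank and cell wells share the same background drift
#' term, so blank subtraction is exact in expectation, and at zero noise
#' the extraction inverts the generator exactly.
#'
#' @param rates_by_group data.frame with columns `group`, `ocr`, `lpr`
#'   (nmol (10^6 cells)^-1 h^-1) and `oxygen_pct`, `ph` (ambient levels).
#' @param cells_in_well cells per measured well.
#' @param noise_sd named absolute noise SDs, `c(o2_mmHg = , ph = )`.
#' @param seed integer RNG seed.
#' @param n_cycles,points_per_cycle,cycle_minutes trace layout.
#' @param drift named background drift slopes shared by cell and blank
#'   wells, `c(o2_mmHg_per_h = , ph_per_h = )`.
#' @param chamber_uL,o2_solubility,buffering_mM_per_pH unit-chain
#'   constants, matching the extraction defaults.
#' @param mmHg_per_pct mmHg of O2 partial pressure per % O2.
#' @return list of per-group lists, each with elements `trace` and
#'   `blank` ([flux_trace()] objects) and the true rates.
#' @export
generate_traces <- function(rates_by_group, cells_in_well = 6e4,
                            noise_sd = c(o2_mmHg = 0, ph = 0), seed,
                            n_cycles = 3L, points_per_cycle = 15L,
                            cycle_minutes = 20,
                            drift = c(o2_mmHg_per_h = -0.5,
                                      ph_per_h = -0.01),
                            chamber_uL = 22.7, o2_solubility = 1.3e-3,
                            buffering_mM_per_pH = 10,
                            mmHg_per_pct = 7.6) {
  stopifnot(!missing(seed), all(rates_by_group$ocr >= 0),
            all(rates_by_group$lpr >= 0))
  set.seed(as.integer(seed))
  t_h <- as.vector(vapply(seq_len(n_cycles), function(cy) {
    (cy - 1) * cycle_minutes / 60 +
      seq(0, cycle_minutes / 60, length.out = points_per_cycle)
  }, numeric(points_per_cycle)))
  cycle <- rep(seq_len(n_cycles), each = points_per_cycle)

  out <- lapply(seq_len(nrow(rates_by_group)), function(i) {
    g <- rates_by_group[i, ]
    o2_0 <- g$oxygen_pct * mmHg_per_pct
    # slopes implied by the unit chain the extractor inverts
    s_o2 <- -g$ocr * (cells_in_well / 1e6) / (o2_solubility * chamber_uL)
    s_ph <- -g$lpr * (cells_in_well / 1e6) /
      (buffering_mM_per_pH * chamber_uL)
    mk <- function(rate_o2, rate_ph, blank) {
      o2 <- o2_0 + (drift[["o2_mmHg_per_h"]] + rate_o2) * t_h +
        stats::rnorm(length(t_h), 0, noise_sd[["o2_mmHg"]])
      ph <- g$ph + (drift[["ph_per_h"]] + rate_ph) * t_h +
        stats::rnorm(length(t_h), 0, noise_sd[["ph"]])
      flux_trace(cycle, t_h, o2, ph,
                 well = sprintf("G%02d%s", g$group,
                                if (blank) "B" else "C"),
                 is_blank = blank)
    }
    list(group = g$group, ocr = g$ocr, lpr = g$lpr,
         trace = mk(s_o2, s_ph, FALSE), blank = mk(0, 0, TRUE))
  })
  names(out) <- paste0("group", rates_by_group$group)
  out
}

#' Collagen from hydroxyproline
#'
#' Applies the 1:7.69 hydroxyproline-to-collagen mass conversion.
#'
#' @param hyp_ug hydroxyproline, ug (>= 0).
#' @return collagen, ug.
#' @examples
#' hydroxyproline_to_collagen(1)  # 7.69
#' @export
hydroxyproline_to_collagen <- function(hyp_ug) {
  if (any(hyp_ug < 0)) stop("hydroxyproline mass must be non-negative")
  hyp_ug * 7.69
}
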