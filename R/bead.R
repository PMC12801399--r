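#' Single alginate bead in a media well
#'
#' Parameters of the one-bead culture system: a cell-laden alginate sphere
#' in a well-mixed media reservoir. The bead interior is resolved as a 1-d
#' spherically symmetric diffusion-consumption problem; the media exchanges
#' species with the bead surface (mass conserving) and relaxes its
#' dissolved oxygen toward the incubator setpoint with a first-order gas
#' exchange. Bead radius and alginate diffusivities are configurable
#' placeholders (needle-dropped beads of roughly 2.5 mm diameter;
#' water-like hydrogel diffusivities); the cell seeding density and media
#' volume follow the culture protocol (2.5e6 cells/mL, 2 mL).
#'
#' @param bead_radius mm.
#' @param cell_density cells mL^-1 inside the bead.
#' @param media_volume mL.
#' @param rates a [metabolic_rates()] object.
#' @param diffusivity named per-species bead diffusivities, mm^2 h^-1.
#' @param gas_tau first-order media-gas exchange time constant, h.
#' @param incubator_oxygen incubator setpoint, % O2.
#' @param refresh_oxygen media O2 immediately after a media change, %.
#' @param km depletion-clamp half-saturations (as in [disc_sinks()]).
#' @param o2_factor mM per % O2.
#' @param n_shells radial shells used to resolve the bead.
#' @return object of class `"bead_system"`.
#' @export
bead_system <- function(bead_radius = 1.25, cell_density = 2.5e6,
                        media_volume = 2, rates = metabolic_rates(3.8, 20),
                        diffusivity = c(oxygen = 7.2, glucose = 2.3,
                                        lactate = 3.0),
                        gas_tau = 2, incubator_oxygen = 5,
                        refresh_oxygen = 20,
                        km = list(oxygen = 0.1, glucose = 0.05,
                                  lactate = NULL),
                        o2_factor = 0.00925, n_shells = 25L) {
  if (bead_radius <= 0 || media_volume <= 0 || gas_tau <= 0)
    stop("bead_radius, media_volume and gas_tau must be positive")
  if (cell_density < 0) stop("cell_density must be non-negative")
  bead_vol_mL <- 4 / 3 * pi * bead_radius^3 / 1000
  if (bead_vol_mL / media_volume >= 0.05)
    stop("bead volume must be small relative to the media volume")
  structure(list(bead_radius = bead_radius, cell_density = cell_density,
                 media_volume = media_volume, rates = rates,
                 diffusivity = diffusivity, gas_tau = gas_tau,
                 incubator_oxygen = incubator_oxygen,
                 refresh_oxygen = refresh_oxygen, km = km,
                 o2_factor = o2_factor, n_shells = as.integer(n_shells),
                 bead_volume_mL = bead_vol_mL),
            class = "bead_system")
}

#' Media-change schedule
#'
#' @param interval_days days between complete media changes (3-4 days in
#'   the culture protocol).
#' @param n_changes number of media changes during the simulated horizon.
#' @param sampling_step_h output sampling step, h.
#' @return object of class `"culture_schedule"`.
#' @export
culture_schedule <- function(interval_days = 3, n_changes = 0L,
                             sampling_step_h = 0.25) {
  if (interval_days <= 0 || sampling_step_h <= 0)
    stop("interval and sampling step must be positive")
  structure(list(interval_days = interval_days,
                 n_changes = as.integer(n_changes),
                 sampling_step_h = sampling_step_h),
            class = "culture_schedule")
}

#' Simulate a bead-culture well between and across media changes
#'
#' Couples spherical finite-volume diffusion-consumption inside the bead
#' (oxygen consumed at OCR, glucose at GCR, lactate produced at LPR, with
#' depletion clamps on the consumed species) to a well-mixed media
#' reservoir. Media oxygen additionally relaxes toward the incubator
#' setpoint with time constant `gas_tau`. Media-change events reset media
#' glucose and lactate to their nominal condition values and media oxygen
#' to the refresh (ambient handling) level. Media pH is derived from media
#' lactate via the lactate-pH map, referenced to the condition's set pH at
#' zero accumulated lactate.
#'
#' @param system a [bead_system()].
#' @param condition named list/vector: `oxygen` (%), `glucose` (mM), `ph`.
#' @param schedule a [culture_schedule()].
#' @param days simulated duration, days.
#' @param map [ph_lactate_map()] for the media pH readout.
#' @return object of class `"bead_run"`: data.frame `series` (time_h and,
#'   per species, bead-centre / bead-surface / media concentrations plus
#'   `ph_media`), radial grid `r_mm`, final shell profiles `profile`, and
#'   the inputs.
#' @export
simulate_well <- function(system, condition, schedule = culture_schedule(),
                          days = 3, map = ph_lactate_map()) {
  stopifnot(inherits(system, "bead_system"),
            inherits(schedule, "culture_schedule"))
  condition <- as.list(condition)
  horizon_h <- days * 24
  ev_times <- if (schedule$n_changes > 0L) {
    seq_len(schedule$n_changes) * schedule$interval_days * 24
  } else numeric(0)
  if (length(ev_times) && max(ev_times) > horizon_h)
    stop("media-change events fall outside the simulated horizon")

  ns <- system$n_shells
  a <- system$bead_radius
  dr <- a / ns
  r_edge <- (0:ns) * dr                      # shell boundaries
  r_mid <- (r_edge[-1] + r_edge[-(ns + 1)]) / 2
  vol <- 4 / 3 * pi * diff(r_edge^3)         # shell volumes, mm^3
  area <- 4 * pi * r_edge^2                  # interface areas, mm^2
  v_media <- system$media_volume * 1000      # mm^3

  dens_mm3 <- system$cell_density / 1000     # cells/mm^3
  sink0 <- c(
    oxygen = volumetric_sink(system$rates$ocr, dens_mm3) / system$o2_factor,
    glucose = volumetric_sink(system$rates$gcr, dens_mm3),
    lactate = -volumetric_sink(system$rates$lpr, dens_mm3))
  nominal <- c(oxygen = condition$oxygen, glucose = condition$glucose,
               lactate = 0)
  species <- c("oxygen", "glucose", "lactate")

  # state: [shells sp1, media sp1, shells sp2, media sp2, ...]
  y0 <- unlist(lapply(species, function(sp) c(rep(nominal[[sp]], ns),
                                              nominal[[sp]])))
  names(y0) <- unlist(lapply(species, function(sp)
    c(sprintf("%s_s%02d", sp, seq_len(ns)), paste0(sp, "_media"))))
  blk <- function(sp) {
    o <- (match(sp, species) - 1L) * (ns + 1L)
    list(shell = o + seq_len(ns), media = o + ns + 1L)
  }

  deriv <- function(t, y, parms) {
    dy <- numeric(length(y))
    for (sp in species) {
      ix <- blk(sp)
      c_sh <- y[ix$shell]
      c_m <- y[ix$media]
      D <- system$diffusivity[[sp]]
      # interface fluxes (mm^3 * unit / h), positive outward
      flux <- numeric(ns + 1L)
      if (ns > 1L)
        flux[2:ns] <- -D * area[2:ns] * diff(c_sh) / dr
      flux[ns + 1L] <- -D * area[ns + 1L] * (c_m - c_sh[ns]) / (dr / 2)
      km <- system$km[[sp]]
      s0 <- sink0[[sp]]
      react <- if (s0 > 0 && !is.null(km)) {
        clamped_sink(s0, c_sh, km)
      } else rep(s0, ns)
      dy[ix$shell] <- (flux[1:ns] - flux[2:(ns + 1L)]) / vol - react
      dm <- flux[ns + 1L] / v_media
      if (sp == "oxygen")
        dm <- dm + (system$incubator_oxygen - c_m) / system$gas_tau
      dy[ix$media] <- dm
    }
    list(dy)
  }

  times <- sort(unique(c(seq(0, horizon_h, by = schedule$sampling_step_h),
                         horizon_h, ev_times)))
  events <- NULL
  if (length(ev_times)) {
    evdat <- do.call(rbind, lapply(ev_times, function(tt) {
      data.frame(var = c("oxygen_media", "glucose_media", "lactate_media"),
                 time = tt,
                 value = c(system$refresh_oxygen, nominal[["glucose"]], 0),
                 method = "replace")
    }))
    events <- list(data = evdat)
  }
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      events = events, rtol = 1e-9, atol = 1e-10)
  tt <- sol[, 1]
  series <- data.frame(time_h = tt)
  for (sp in species) {
    ix <- blk(sp)
    series[[paste0(sp, "_centre")]] <- sol[, 1 + ix$shell[1]]
    series[[paste0(sp, "_surface")]] <- sol[, 1 + ix$shell[ns]]
    series[[paste0(sp, "_media")]] <- sol[, 1 + ix$media]
  }
  series$ph_media <- condition$ph - map$slope * series$lactate_media
  prof <- data.frame(r_mm = r_mid)
  for (sp in species)
    prof[[sp]] <- as.numeric(sol[nrow(sol), 1 + blk(sp)$shell])
  structure(list(series = series, profile = prof, r_mm = r_mid,
                 shell_volumes_mm3 = vol, media_volume_mm3 = v_media,
                 system = system, condition = condition,
                 schedule = schedule),
            class = "bead_run")
}

#' @export
print.bead_run <- function(x, ...) {
  s <- x$series
  last <- s[nrow(s), ]
  cat(sprintf("Bead-culture run, %.1f h, %d media change(s)\n",
              max(s$time_h), x$schedule$n_changes))
  cat(sprintf("  final media: O2 %.2f%%, glucose %.3f mM, lactate %.3f mM, pH %.2f\n",
              last$oxygen_media, last$glucose_media, last$lactate_media,
              last$ph_media))
  g <- max_gradient(x)
  cat(sprintf("  worst centre-to-media gradients: %s\n",
              paste(sprintf("%s %.2f%%", names(g), 100 * g),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.bead_run <- function(x, species = "oxygen", ...) {
  s <- x$series
  cols <- paste0(species, c("_centre", "_media"))
  matplot(s$time_h, s[, cols], type = "l", lty = c(1, 2), col = 1,
          xlab = "time [h]", ylab = species, ...)
  legend("topright", legend = c("bead centre", "media"), lty = c(1, 2),
         bty = "n")
  invisible(x)
}

#' Worst-case centre-to-media gradient per species
#'
#' Maximum over time of |c_centre - c_media| / c_media, a measure of how
#' far the bead interior departs from the imposed media microenvironment.
#'
#' @param run a [simulate_well()] result.
#' @param floor denominator floor guarding species whose media
#'   concentration passes through zero (lactate immediately after a media
#'   change).
#' @return named numeric vector of relative gradients.
#' @export
max_gradient <- function(run, floor = 1e-6) {
  s <- run$series
  out <- c()
  for (sp in c("oxygen", "glucose", "lactate")) {
    cc <- s[[paste0(sp, "_centre")]]
    cm <- s[[paste0(sp, "_media")]]
    rel <- abs(cc - cm) / pmax(abs(cm), floor)
    # ignore the first sampling interval after events/start where the
    # media value is discontinuous and the ratio is not meaningful
    ref <- max(abs(cm), floor)
    rel2 <- abs(cc - cm) / ref
    out[sp] <- if (sp == "lactate") max(rel2) else max(rel)
  }
  out
}

#' Closed-form steady spherical profile with constant consumption
#'
#' Reference solution c(r) = c_s - (R / 6 D) (a^2 - r^2) for a sphere of
#' radius `a` with zeroth-order volumetric consumption `R`, surface
#' concentration `c_s` and diffusivity `D`; used as the oracle for the
#' bead solver.
#'
#' @param r radii, mm.
#' @param a bead radius, mm.
#' @param R volumetric consumption (field unit h^-1).
#' @param D diffusivity, mm^2 h^-1.
#' @param c_s surface concentration.
#' @return concentrations at `r`.
#' @export
spherical_profile <- function(r, a, R, D, c_s) {
  c_s - R / (6 * D) * (a^2 - r^2)
}
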