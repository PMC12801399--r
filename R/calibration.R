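#' Target NP-centre microenvironment for boundary calibration
#'
#' The calibration targets are the culture-condition values the disc model
#' should reproduce at the NP centre: oxygen in %, glucose in mM, and pH
#' (converted internally to a lactate target through the lactate-pH map).
#'
#' @param oxygen,glucose,ph target NP-centre values (any may be NA to skip
#'   that species).
#' @param tol named absolute tolerances (`oxygen` %, `glucose` mM,
#'   `ph` pH units).
#' @return object of class `"calibration_target"`.
#' @examples
#' calibration_target(oxygen = 5, glucose = 0.5, ph = 6.5)  # degenerated
#' @export
calibration_target <- function(oxygen = NA, glucose = NA, ph = NA,
                               tol = c(oxygen = 0.1, glucose = 0.05,
                                       ph = 0.05)) {
  if (!is.na(oxygen) && (oxygen < 0 || oxygen > 21))
    stop("oxygen target must lie in [0, 21] %")
  if (!is.na(glucose) && glucose < 0)
    stop("glucose target must be non-negative")
  if (!is.na(ph) && (ph < 5 || ph > 8))
    stop("pH target must lie in [5, 8]")
  if (any(tol <= 0)) stop("tolerances must be positive")
  structure(list(oxygen = oxygen, glucose = glucose, ph = ph, tol = tol),
            class = "calibration_target")
}

#' Iterative Dirichlet boundary calibration
#'
#' Adjusts the outer AF and CEP boundary concentrations until the
#' steady-state NP-centre values match the targets. Each species is
#' calibrated independently by a secant iteration on a single scale factor
#' multiplying both of its boundary values, preserving their initial
#' AF:CEP ratio. pH targets are converted to lactate targets via the
#' lactate-pH map before calibration. Because the NP-centre value is (up
#' to the mild depletion clamp) affine in the boundary scale, the secant
#' converges in a handful of solves.
#'
#' @param geometry,diffusion,sinks the disc model specification (see
#'   [solve_steady_state()]).
#' @param targets a [calibration_target()].
#' @param initial the starting [boundary_table()].
#' @param map [ph_lactate_map()] used for pH-to-lactate conversion.
#' @param max_iter maximum secant iterations per species.
#' @return list of class `"calibration_result"`: `boundaries` (the
#'   calibrated [boundary_table()]) and `report`, a data.frame per species
#'   with the scale applied, iterations, achieved value, target and final
#'   miss.
#' @export
calibrate_boundaries <- function(geometry, diffusion, sinks, targets,
                                 initial = boundary_table(),
                                 map = ph_lactate_map(),
                                 max_iter = 50L) {
  stopifnot(inherits(targets, "calibration_target"))
  want <- list()
  if (!is.na(targets$oxygen))
    want$oxygen <- c(target = targets$oxygen, tol = targets$tol[["oxygen"]])
  if (!is.na(targets$glucose))
    want$glucose <- c(target = targets$glucose,
                      tol = targets$tol[["glucose"]])
  if (!is.na(targets$ph))
    want$lactate <- c(target = ph_to_lactate(targets$ph, map),
                      tol = targets$tol[["ph"]] / map$slope)
  if (length(want) == 0L) stop("no targets set")

  out <- initial
  rows <- list()
  for (sp in names(want)) {
    tgt <- want[[sp]][["target"]]
    tol <- want[[sp]][["tol"]]
    centre_at <- function(scale) {
      bt <- out
      bt$values[[sp]] <- pmax(initial$values[[sp]] * scale, 0)
      f <- solve_steady_state(geometry, diffusion, bt, sinks, species = sp)
      np_centre_value(f[[sp]], geometry)
    }
    s0 <- 1
    f0 <- centre_at(s0) - tgt
    iters <- 0L
    if (abs(f0) > tol) {
      s1 <- if (f0 > 0) 0.5 else 2
      f1 <- centre_at(s1) - tgt
      iters <- 1L
      while (abs(f1) > tol && iters < max_iter) {
        if (f1 == f0) break
        s2 <- s1 - f1 * (s1 - s0) / (f1 - f0)
        if (!is.finite(s2) || s2 < 0) s2 <- max(s1 / 2, 0)
        s0 <- s1; f0 <- f1
        s1 <- s2; f1 <- centre_at(s1) - tgt
        iters <- iters + 1L
      }
      if (abs(f1) > tol)
        stop(sprintf(
          "calibration for %s did not converge in %d iterations; best centre %.4g for target %.4g",
          sp, iters, f1 + tgt, tgt))
      out$values[[sp]] <- pmax(initial$values[[sp]] * s1, 0)
      scale <- s1; achieved <- f1 + tgt
    } else {
      scale <- 1; achieved <- f0 + tgt
    }
    rows[[sp]] <- data.frame(species = sp, scale = scale,
                             iterations = iters, achieved = achieved,
                             target = tgt, miss = achieved - tgt)
  }
  structure(list(boundaries = out,
                 report = do.call(rbind, rows)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Boundary calibration\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
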