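#' Regional diffusion coefficients
#'
#' Diffusivities (mm^2 h^-1) for oxygen, glucose and lactate in the NP,
#' AF (radial = in-plane, axial = through-height) and CEP. The NP and AF
#' values are common to both scenarios; the CEP value drops with
#' degeneration.
#'
#' @param scenario `"degenerated"` or `"healthy"` (selects the CEP column).
#' @param values optional full override: named list per species of
#'   `c(NP = , AF_radial = , AF_axial = , CEP = )`.
#' @return object of class `"diffusion_table"`.
#' @export
diffusion_table <- function(scenario = c("degenerated", "healthy"),
                            values = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(values)) {
    cep <- if (scenario == "degenerated") {
      c(oxygen = 1.74, glucose = 0.06, lactate = 0.1)
    } else {
      c(oxygen = 3.53, glucose = 0.12, lactate = 0.21)
    }
    values <- list(
      oxygen  = c(NP = 3.08, AF_radial = 3.08, AF_axial = 2.2,
                  CEP = cep[["oxygen"]]),
      glucose = c(NP = 0.45, AF_radial = 0.37, AF_axial = 0.45,
                  CEP = cep[["glucose"]]),
      lactate = c(NP = 0.61, AF_radial = 0.61, AF_axial = 0.5,
                  CEP = cep[["lactate"]]))
  }
  for (sp in names(values)) {
    v <- values[[sp]]
    if (!all(c("NP", "AF_radial", "AF_axial", "CEP") %in% names(v)))
      stop("diffusivities for ", sp, " must name NP, AF_radial, AF_axial, CEP")
    if (any(v <= 0)) stop("diffusivities must be strictly positive")
  }
  structure(list(scenario = scenario, values = values),
            class = "diffusion_table")
}

#' Dirichlet boundary concentrations
#'
#' Fixed concentrations imposed on the outer AF surface and the CEP faces:
#' oxygen in %, glucose and lactate in mM. Defaults are the
#' iteratively-calibrated scenario values (oxygen 15/12 in both scenarios;
#' glucose 1.4/0.8 degenerated, 4.0/2.3 healthy; lactate 6.3/10.5
#' degenerated, 2.5/1.0 healthy; AF/CEP order).
#'
#' @param scenario `"degenerated"` or `"healthy"`.
#' @param values optional override: named list per species of
#'   `c(AF_OUTER = , CEP_FACE = )`.
#' @return object of class `"boundary_table"`.
#' @export
boundary_table <- function(scenario = c("degenerated", "healthy"),
                           values = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(values)) {
    values <- if (scenario == "degenerated") {
      list(oxygen  = c(AF_OUTER = 15, CEP_FACE = 12),
           glucose = c(AF_OUTER = 1.4, CEP_FACE = 0.8),
           lactate = c(AF_OUTER = 6.3, CEP_FACE = 10.5))
    } else {
      list(oxygen  = c(AF_OUTER = 15, CEP_FACE = 12),
           glucose = c(AF_OUTER = 4.0, CEP_FACE = 2.3),
           lactate = c(AF_OUTER = 2.5, CEP_FACE = 1.0))
    }
  }
  for (sp in names(values)) {
    v <- values[[sp]]
    if (!all(c("AF_OUTER", "CEP_FACE") %in% names(v)))
      stop("boundary values for ", sp, " must name AF_OUTER and CEP_FACE")
    if (any(v < 0)) stop("boundary concentrations must be non-negative")
  }
  structure(list(scenario = scenario, values = values),
            class = "boundary_table")
}

#' Volumetric source/sink specification for the disc solver
#'
#' Builds per-region zeroth-order reaction terms from per-cell rates and
#' active cell densities: oxygen is consumed at OCR (converted from mM/h to
#' %/h), glucose at GCR, and lactate is produced at LPR. CEP is acellular.
#' Consumed species carry a Michaelis-type depletion clamp
#' ([clamped_sink()]) with half-saturation `km`; set a `km` to `NULL` to
#' disable the clamp for that species (pure zeroth-order kinetics).
#'
#' @param rates a [metabolic_rates()] object.
#' @param densities a [cell_densities()] object (active densities per
#'   region, cells mm^-3).
#' @param km named list of clamp half-saturations (`oxygen` in %,
#'   `glucose` in mM).
#' @param o2_factor mM per % oxygen (unit conversion of the oxygen sink).
#' @return object of class `"sink_table"`: per species, the zeroth-order
#'   rate per region (in the species' field unit per hour; negative =
#'   production) and the clamp `km`.
#' @export
disc_sinks <- function(rates, densities,
                       km = list(oxygen = 0.1, glucose = 0.05,
                                 lactate = NULL),
                       o2_factor = 0.00925) {
  stopifnot(inherits(rates, "metabolic_rates"),
            inherits(densities, "cell_densities"))
  act <- densities$active
  base <- list(
    oxygen  = c(NP = volumetric_sink(rates$ocr, act[["NP"]]),
                AF = volumetric_sink(rates$ocr, act[["AF"]]),
                CEP = 0) / o2_factor,
    glucose = c(NP = volumetric_sink(rates$gcr, act[["NP"]]),
                AF = volumetric_sink(rates$gcr, act[["AF"]]),
                CEP = 0),
    lactate = -c(NP = volumetric_sink(rates$lpr, act[["NP"]]),
                 AF = volumetric_sink(rates$lpr, act[["AF"]]),
                 CEP = 0))
  structure(list(base = base, km = km), class = "sink_table")
}

# direction-dependent diffusivity array for one species (0 in EXTERIOR)
.diffusivity_array <- function(geometry, dvals, direction) {
  af <- if (direction == 3L) dvals[["AF_axial"]] else dvals[["AF_radial"]]
  lut <- c(NP = dvals[["NP"]], AF = af, CEP = dvals[["CEP"]], EXTERIOR = 0)
  array(lut[geometry$region], dim = dim(geometry$region))
}

# linear index pairs (p, q) of grid-adjacent nodes along one axis
.axis_pairs <- function(nd, direction) {
  idx <- array(seq_len(prod(nd)), dim = nd)
  if (direction == 1L && nd[1] > 1L) {
    p <- idx[-nd[1], , , drop = FALSE]; q <- idx[-1, , , drop = FALSE]
  } else if (direction == 2L && nd[2] > 1L) {
    p <- idx[, -nd[2], , drop = FALSE]; q <- idx[, -1, , drop = FALSE]
  } else if (direction == 3L && nd[3] > 1L) {
    p <- idx[, , -nd[3], drop = FALSE]; q <- idx[, , -1, drop = FALSE]
  } else {
    return(NULL)
  }
  cbind(p = as.integer(p), q = as.integer(q))
}

# all finite-difference link weights w = D_harmonic / h^2 between adjacent
# tissue nodes; returns data.frame(p, q, w) with w > 0
.link_weights <- function(geometry, dvals) {
  nd <- dim(geometry$region)
  h2 <- geometry$h^2
  out <- vector("list", 3L)
  for (d in 1:3) {
    pairs <- .axis_pairs(nd, d)
    if (is.null(pairs)) next
    D <- .diffusivity_array(geometry, dvals, d)
    dp <- D[pairs[, "p"]]; dq <- D[pairs[, "q"]]
    s <- dp + dq
    w <- ifelse(s > 0, 2 * dp * dq / pmax(s, .Machine$double.xmin), 0) / h2
    keep <- w > 0
    out[[d]] <- data.frame(p = pairs[keep, "p"], q = pairs[keep, "q"],
                           w = w[keep])
  }
  do.call(rbind, out)
}

.dirichlet_mask <- function(geometry) {
  !is.na(geometry$boundary) & geometry$boundary %in% c("AF_OUTER", "CEP_FACE")
}

#' Solve the steady-state reaction--diffusion problem on the disc
#'
#' Solves div(D(x) grad c) = R(x, c) for each species on the structured
#' grid with a 7-point finite-difference stencil, harmonic-mean interface
#' diffusivities across region boundaries, an anisotropic (radial/axial)
#' diffusion tensor in the AF, Dirichlet values on the `AF_OUTER` and
#' `CEP_FACE` boundary nodes and zero flux across symmetry planes and the
#' exterior. The depletion clamp is handled by fixed-point iteration with
#' the clamp factor linearized onto the matrix diagonal (which keeps every
#' iterate non-negative); unclamped species solve in one iteration.
#'
#' @param geometry a [build_idealized_disc()] (or [slab_geometry()]) grid.
#' @param diffusion a [diffusion_table()].
#' @param boundaries a [boundary_table()].
#' @param sinks a [disc_sinks()] object (or compatible list).
#' @param species which species to solve.
#' @param tol relative fixed-point/residual tolerance.
#' @param max_iter maximum clamp iterations.
#' @return named list of `"species_field"` objects: 3-d `value` array (NA
#'   outside tissue), `species`, `unit`, `residual`, `iterations`,
#'   `converged`, and the realized volumetric reaction array `sink` (field
#'   unit per hour, negative = production).
#' @export
solve_steady_state <- function(geometry, diffusion, boundaries, sinks,
                               species = names(boundaries$values),
                               tol = 1e-8, max_iter = 100L) {
  nd <- dim(geometry$region)
  n <- prod(nd)
  tissue <- geometry$region != "EXTERIOR"
  dirich <- .dirichlet_mask(geometry)
  unknown <- tissue & !dirich
  uidx <- integer(n); uidx[unknown] <- seq_len(sum(unknown))
  region <- geometry$region

  out <- list()
  for (sp in species) {
    links <- .link_weights(geometry, diffusion$values[[sp]])
    pu <- unknown[links$p]; qu <- unknown[links$q]
    both <- pu & qu
    pd <- pu & dirich[links$q]   # unknown p, Dirichlet q
    dp <- dirich[links$p] & qu   # Dirichlet p, unknown q

    bvals <- boundaries$values[[sp]]
    bc_node <- rep(NA_real_, n)
    bc_node[dirich] <- bvals[geometry$boundary[dirich]]

    nu <- sum(unknown)
    acc <- function(vals, at) {              # fast indexed accumulation
      out <- numeric(nu)
      s <- rowsum(vals, at)
      out[as.integer(rownames(s))] <- s
      out
    }
    # diagonal from all links incident to an unknown node
    diag0 <- acc(links$w[pu], uidx[links$p[pu]]) +
      acc(links$w[qu], uidx[links$q[qu]])

    i_off <- c(uidx[links$p[both]], uidx[links$q[both]])
    j_off <- c(uidx[links$q[both]], uidx[links$p[both]])
    x_off <- c(-links$w[both], -links$w[both])

    b0 <- acc(links$w[pd] * bc_node[links$q[pd]], uidx[links$p[pd]]) +
      acc(links$w[dp] * bc_node[links$p[dp]], uidx[links$q[dp]])

    A0 <- Matrix::forceSymmetric(Matrix::sparseMatrix(
      i = c(seq_len(nu), i_off), j = c(seq_len(nu), j_off),
      x = c(diag0, x_off), dims = c(nu, nu)))

    base_sink <- c(sinks$base[[sp]], EXTERIOR = 0)[region][unknown]
    km <- sinks$km[[sp]]
    clamp_active <- !is.null(km) && any(base_sink > 0)

    if (!clamp_active) {
      ch <- Matrix::Cholesky(A0, LDL = FALSE)
      c_prev <- as.numeric(Matrix::solve(ch, b0 - base_sink))
      iterations <- 1L
      delta <- 0
    } else {
      b <- b0 - pmin(base_sink, 0)
      c_prev <- rep(mean(bvals), nu)
      iterations <- 0L
      ch <- NULL
      repeat {
        iterations <- iterations + 1L
        # consumption linearized: R(c) ~ base / (c_prev + km) * c
        diag_extra <- ifelse(base_sink > 0,
                             base_sink / (pmax(c_prev, 0) + km), 0)
        A <- A0 + Matrix::Diagonal(nu, diag_extra)
        if (is.null(ch)) {
          ch <- Matrix::Cholesky(A, LDL = FALSE)
        } else {
          ch <- Matrix::update(ch, Matrix::forceSymmetric(A))
        }
        c_new <- as.numeric(Matrix::solve(ch, b))
        delta <- max(abs(c_new - c_prev)) / max(max(abs(c_new)), 1e-12)
        c_prev <- c_new
        if (delta < tol || iterations >= max_iter) break
      }
      if (delta >= tol)
        stop(sprintf(
          "solver for %s did not converge in %d iterations (last change %.3g)",
          sp, iterations, delta))
    }
    if (clamp_active) {
      if (any(c_prev < -1e-9))
        stop("negative concentration in clamped solve; solver defect")
      c_prev <- pmax(c_prev, 0)
    }

    # realized reaction term and nonlinear residual L c + R(c) - b_dirichlet
    sink_val <- if (!is.null(km)) {
      ifelse(base_sink > 0, clamped_sink(base_sink, c_prev, km), base_sink)
    } else base_sink
    res_vec <- as.numeric(A0 %*% c_prev) + sink_val - b0
    residual <- max(abs(res_vec)) / max(max(abs(b0)), 1e-12)

    value <- array(NA_real_, dim = nd)
    value[unknown] <- c_prev
    value[dirich] <- bc_node[dirich]
    sink_arr <- array(NA_real_, dim = nd)
    sink_arr[unknown] <- sink_val
    sink_arr[dirich] <- 0

    out[[sp]] <- structure(
      list(species = sp,
           unit = c(oxygen = "%", glucose = "mM", lactate = "mM",
                    pH = "pH")[sp],
           value = value, sink = sink_arr,
           residual = residual, iterations = iterations,
           converged = TRUE),
      class = "species_field")
  }
  out
}

#' @export
print.species_field <- function(x, ...) {
  v <- x$value[!is.na(x$value)]
  cat(sprintf("%s field [%s]: min %.4g, max %.4g (%d clamp iterations)\n",
              x$species, x$unit, min(v), max(v), x$iterations))
  invisible(x)
}

#' Derive the pH field from a lactate field
#'
#' Applies the linear lactate-to-pH map node-wise, so the pH minimum is
#' colocated with the lactate maximum.
#'
#' @param lactate_field a converged lactate `"species_field"`.
#' @param map a [ph_lactate_map()].
#' @return a pH `"species_field"`.
#' @export
derive_ph_field <- function(lactate_field, map = ph_lactate_map()) {
  stopifnot(inherits(lactate_field, "species_field"),
            lactate_field$species == "lactate")
  f <- lactate_field
  f$species <- "pH"
  f$unit <- "pH"
  f$value <- map$intercept - map$slope * lactate_field$value
  f$sink <- NULL
  f
}

#' Concentration value at the NP centre node
#'
#' @param field a `"species_field"`.
#' @param geometry the grid the field was solved on.
#' @return the field value at the node nearest the disc (or slab) centre.
#' @export
np_centre_value <- function(field, geometry) {
  ctr <- geometry$centre
  field$value[ctr[1], ctr[2], ctr[3]]
}

#' Anterior-posterior mid-height profile of a field
#'
#' Samples a solved field along the mid-height anterior-posterior line
#' ([extract_midheight_line()]).
#'
#' @param field a `"species_field"`.
#' @param geometry the grid the field was solved on.
#' @param mirror sample the full anterior-to-posterior width (default)
#'   rather than the quadrant half-line.
#' @return data.frame with columns `s` (normalized position), `x_mm`,
#'   `region` and `value`.
#' @export
field_profile <- function(field, geometry, mirror = TRUE) {
  path <- extract_midheight_line(geometry, mirror = mirror)
  path$value <- field$value[cbind(path$i, path$j, path$k)]
  path[, c("s", "x_mm", "region", "value")]
}

#' Discrete flux balance of a solved field
#'
#' Independently recomputes the total diffusive influx through the
#' Dirichlet boundary nodes and the total interior reaction from a solved
#' field; at steady state the two balance (influx = consumption) up to the
#' solver tolerance.
#'
#' @param field a `"species_field"` with its realized `sink` array.
#' @param geometry,diffusion the grid and [diffusion_table()] used.
#' @return list with `influx` and `consumption` (field unit x mm^3 / h)
#'   and their relative imbalance.
#' @export
flux_balance <- function(field, geometry, diffusion) {
  links <- .link_weights(geometry, diffusion$values[[field$species]])
  dirich <- .dirichlet_mask(geometry)
  unknown <- geometry$region != "EXTERIOR" & !dirich
  v <- field$value
  h3 <- geometry$h^3
  pd <- unknown[links$p] & dirich[links$q]
  dp <- dirich[links$p] & unknown[links$q]
  influx <- sum(links$w[pd] * (v[links$q[pd]] - v[links$p[pd]])) +
    sum(links$w[dp] * (v[links$p[dp]] - v[links$q[dp]]))
  consumption <- sum(field$sink[unknown])
  list(influx = influx * h3, consumption = consumption * h3,
       imbalance = abs(influx - consumption) /
         max(abs(consumption), abs(influx), 1e-12))
}

#' One-dimensional slab grid
#'
#' Degenerate single-region grid (a 1-d slab along x) with Dirichlet ends,
#' mainly for verifying the solver against the closed-form parabolic
#' profile of a constant-sink slab, c(x) = c0 - (R / 2D) x (L - x).
#'
#' @param length_mm slab length, mm.
#' @param n number of nodes.
#' @param region region label giving the slab its diffusivity.
#' @return a grid usable by [solve_steady_state()].
#' @export
slab_geometry <- function(length_mm, n = 101L, region = "NP") {
  stopifnot(length_mm > 0, n >= 3)
  h <- length_mm / (n - 1)
  reg <- array(region, dim = c(n, 1L, 1L))
  bnd <- array(NA_character_, dim = c(n, 1L, 1L))
  bnd[c(1L, n), 1L, 1L] <- "AF_OUTER"
  x <- seq(0, length_mm, length.out = n)
  structure(list(x = x, y = 0, z = 0,
                 h = h, dim = NULL, region = reg, boundary = bnd,
                 centre = c(which.min(abs(x - length_mm / 2)), 1L, 1L)),
            class = "disc_geometry")
}
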