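#' Read a model configuration file
#'
#' Reads a YAML configuration with optional blocks `geometry:`,
#' `metabolism:`, `transport:`, `boundaries:` and `gag:` and materializes
#' the corresponding package objects, falling back to package defaults for
#' anything not specified. A template with every recognized key is shipped
#' at `system.file("extdata", "default_config.yaml", package = "ivdmicro")`.
#'
#' @param path path to a YAML file.
#' @param scenario `"degenerated"` or `"healthy"`; selects
#'   scenario-dependent defaults.
#' @return list with elements `dimensions` ([disc_dimensions()]),
#'   `densities` ([cell_densities()]), `rates` ([metabolic_rates()] or
#'   NULL when the config names none), `map` ([ph_lactate_map()]),
#'   `diffusion` ([diffusion_table()]), `boundaries` ([boundary_table()])
#'   and `gag` ([gag_parameters()]).
#' @export
read_disc_config <- function(path, scenario = c("degenerated", "healthy")) {
  scenario <- match.arg(scenario)
  cfg <- yaml::read_yaml(path)
  geo <- cfg$geometry
  dims <- do.call(disc_dimensions, if (is.null(geo)) list() else geo)

  met <- cfg$metabolism
  dens <- cell_densities(
    scenario,
    total = if (!is.null(met$total_density))
      unlist(met$total_density) else c(NP = 6133, AF = 19732),
    viability = met$viability[[scenario]])
  rates <- NULL
  if (!is.null(met$rates[[scenario]]))
    rates <- do.call(metabolic_rates, met$rates[[scenario]])
  map <- if (!is.null(met$ph_lactate))
    do.call(ph_lactate_map, met$ph_lactate) else ph_lactate_map()

  diff_vals <- NULL
  if (!is.null(cfg$transport$diffusivity[[scenario]]))
    diff_vals <- lapply(cfg$transport$diffusivity[[scenario]], unlist)
  bnd_vals <- NULL
  if (!is.null(cfg$boundaries[[scenario]]))
    bnd_vals <- lapply(cfg$boundaries[[scenario]], unlist)

  gag_cfg <- if (is.null(cfg$gag)) list() else cfg$gag
  gag <- do.call(gag_parameters, c(list(scenario = scenario), gag_cfg))

  list(dimensions = dims, densities = dens, rates = rates, map = map,
       diffusion = diffusion_table(scenario, values = diff_vals),
       boundaries = boundary_table(scenario, values = bnd_vals),
       gag = gag)
}

#' Export fields on a disc grid as a legacy VTK structured-points file
#'
#' Writes the grid and any number of node-aligned scalar fields
#' (`species_field` objects or plain arrays) as an ASCII legacy VTK
#' STRUCTURED_POINTS dataset, readable by ParaView and friends. NA values
#' (exterior nodes) are written as -1.
#'
#' @param geometry a [build_idealized_disc()] grid.
#' @param fields named list of `species_field` objects or 3-d arrays.
#' @param file output path (conventionally `.vtk`).
#' @param na value substituted for NA nodes.
#' @return the file path, invisibly.
#' @export
write_vtk_fields <- function(geometry, fields, file, na = -1) {
  nd <- dim(geometry$region)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ivdmicro disc quadrant fields",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nd[1], nd[2], nd[3]),
               sprintf("ORIGIN %g %g %g", geometry$x[1], geometry$y[1],
                       geometry$z[1]),
               sprintf("SPACING %g %g %g", geometry$h, geometry$h,
                       geometry$h),
               sprintf("POINT_DATA %d", prod(nd))), con)
  region_code <- array(match(geometry$region,
                             c("NP", "AF", "CEP", "EXTERIOR")) - 1L,
                       dim = nd)
  all_fields <- c(list(region = region_code), fields)
  for (nm in names(all_fields)) {
    f <- all_fields[[nm]]
    v <- if (inherits(f, "species_field")) f$value else f
    v <- as.numeric(v)
    v[is.na(v)] <- na
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(formatC(v, format = "g", digits = 8), con)
  }
  invisible(file)
}
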