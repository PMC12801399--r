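#' Dimensions of the idealized lumbar disc
#'
#' Geometric parameters of the idealized caprine lumbar disc model. The
#' disc is an elliptic cylinder (anterior-posterior half-width `a`, lateral
#' half-width `b`, height `h`) with an elliptical nucleus pulposus (NP)
#' core, an annulus fibrosus (AF) ring, and cartilage endplate (CEP) layers
#' of thickness `cep_thickness` capping the NP and inner AF on the top and
#' bottom faces. One quadrant is modelled; the two cut planes are
#' zero-flux symmetry planes.
#'
#' The default lengths are configurable placeholders for caprine L3-4
#' measurements (which are reported elsewhere, not fixed by this package);
#' every disc-scale result that depends on them should be read as an
#' ordering/shape prediction, not an absolute one.
#'
#' @param halfwidth_ap anterior-posterior half-width, mm.
#' @param halfwidth_lat lateral half-width, mm.
#' @param height disc height, mm.
#' @param cep_thickness endplate layer thickness, mm (< height / 2).
#' @param np_fraction fraction of each half-width occupied by the NP
#'   ellipse, in (0, 1).
#' @param cep_fraction fraction of each half-width covered by the CEP
#'   layers (NP plus inner AF); defaults to midway between `np_fraction`
#'   and 1.
#' @param grid_spacing node spacing of the structured grid, mm.
#' @return object of class `"disc_dimensions"`.
#' @export
disc_dimensions <- function(halfwidth_ap = 10, halfwidth_lat = 12.5,
                            height = 4, cep_thickness = 0.6,
                            np_fraction = 0.5, cep_fraction = NULL,
                            grid_spacing = 0.2) {
  if (is.null(cep_fraction)) cep_fraction <- (np_fraction + 1) / 2
  vals <- c(halfwidth_ap, halfwidth_lat, height, cep_thickness, grid_spacing)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all lengths must be strictly positive")
  if (np_fraction <= 0 || np_fraction >= 1)
    stop("np_fraction must lie strictly in (0, 1)")
  if (cep_fraction <= np_fraction || cep_fraction > 1)
    stop("cep_fraction must lie in (np_fraction, 1]")
  if (cep_thickness >= height / 2)
    stop("cep_thickness must be smaller than height / 2")
  structure(list(halfwidth_ap = halfwidth_ap, halfwidth_lat = halfwidth_lat,
                 height = height, cep_thickness = cep_thickness,
                 np_fraction = np_fraction, cep_fraction = cep_fraction,
                 grid_spacing = grid_spacing),
            class = "disc_dimensions")
}

# region of a point (vectorized); the single geometric rule used for both
# node labelling and cell-centre volume quadrature
classify_region <- function(x, y, z, dim) {
  a <- dim$halfwidth_ap; b <- dim$halfwidth_lat
  h2 <- dim$height / 2
  in_disc <- (x / a)^2 + (y / b)^2 <= 1 & abs(z) <= h2
  in_np_xy <- (x / (dim$np_fraction * a))^2 +
    (y / (dim$np_fraction * b))^2 <= 1
  in_cep_xy <- (x / (dim$cep_fraction * a))^2 +
    (y / (dim$cep_fraction * b))^2 <= 1
  in_cep_z <- abs(z) >= h2 - dim$cep_thickness
  region <- rep("EXTERIOR", length(x))
  region[in_disc] <- "AF"
  region[in_disc & in_cep_xy & in_cep_z] <- "CEP"
  region[in_disc & in_np_xy & !in_cep_z] <- "NP"
  region
}

#' Build the discretized idealized disc quadrant
#'
#' Discretizes one quadrant of the idealized disc on a regular structured
#' grid and labels every node as NP, AF, CEP or EXTERIOR. Boundary labels
#' are assigned on the outer AF surface (`AF_OUTER`: the lateral elliptical
#' surface and the top/bottom faces outside the CEP extent) and on the
#' endplate faces (`CEP_FACE`); the quadrant cut planes carry `SYMMETRY`
#' (zero flux).
#'
#' @param dim a [disc_dimensions()] object.
#' @return object of class `"disc_geometry"`: grid axes `x`, `y`, `z` (mm),
#'   3-d arrays `region` and `boundary`, the grid spacing `h`, and `dim`.
#' @export
build_idealized_disc <- function(dim = disc_dimensions()) {
  if (!inherits(dim, "disc_dimensions")) dim <- do.call(disc_dimensions, dim)
  h <- dim$grid_spacing
  nx <- floor(dim$halfwidth_ap / h + 1e-9) + 1L
  ny <- floor(dim$halfwidth_lat / h + 1e-9) + 1L
  nz2 <- floor(dim$height / 2 / h + 1e-9)
  x <- (seq_len(nx) - 1L) * h
  y <- (seq_len(ny) - 1L) * h
  z <- seq(-nz2, nz2) * h
  nz <- length(z)

  g <- expand.grid(x = x, y = y, z = z, KEEP.OUT.ATTRS = FALSE)
  region <- array(classify_region(g$x, g$y, g$z, dim), dim = c(nx, ny, nz))

  # require the NP to be resolved: >= 10 nodes across its full (mirrored)
  # extent in every direction
  np_idx <- which(region == "NP", arr.ind = TRUE)
  if (nrow(np_idx) == 0L) stop("grid resolves no NP nodes")
  np_across <- c(2L * diff(range(np_idx[, 1])) + 1L,
                 2L * diff(range(np_idx[, 2])) + 1L,
                 diff(range(np_idx[, 3])) + 1L)
  if (any(np_across < 10L))
    stop("grid_spacing too coarse: NP spans fewer than 10 nodes across (",
         paste(np_across, collapse = " x "), ")")

  tissue <- region != "EXTERIOR"
  boundary <- array(NA_character_, dim = dim(region))
  # symmetry cut planes
  boundary[1, , ][tissue[1, , ]] <- "SYMMETRY"
  boundary[, 1, ][tissue[, 1, ]] <- "SYMMETRY"
  # lateral outer surface: tissue node with an exterior in-plane neighbour
  ext <- !tissue
  lat_out <- array(FALSE, dim = dim(region))
  lat_out[-nx, , ] <- lat_out[-nx, , ] | ext[-1, , ]
  lat_out[nx, , ] <- TRUE
  lat_out[, -ny, ] <- lat_out[, -ny, ] | ext[, -1, ]
  lat_out[, ny, ] <- TRUE
  boundary[lat_out & tissue] <- "AF_OUTER"
  # top and bottom faces: CEP_FACE over the endplate, AF_OUTER elsewhere
  for (k in c(1L, nz)) {
    face <- region[, , k]
    boundary[, , k][face == "CEP"] <- "CEP_FACE"
    boundary[, , k][face %in% c("AF", "NP")] <- "AF_OUTER"
  }
  structure(list(x = x, y = y, z = z, h = h, dim = dim,
                 region = region, boundary = boundary,
                 centre = c(which.min(abs(x)), which.min(abs(y)),
                            which.min(abs(z)))),
            class = "disc_geometry")
}

#' @export
print.disc_geometry <- function(x, ...) {
  n <- dim(x$region)
  cat(sprintf("Idealized disc quadrant: %d x %d x %d nodes, h = %g mm\n",
              n[1], n[2], n[3], x$h))
  vols <- region_volumes(x)
  cat(sprintf("  volumes [mm^3]: NP %.1f, AF %.1f, CEP %.1f (quadrant)\n",
              vols["NP"], vols["AF"], vols["CEP"]))
  cat(sprintf("  boundary nodes: %s\n",
              paste(names(table(x$boundary)),
                    table(x$boundary), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Region volumes by column quadrature
#'
#' Estimates the quadrant volume of each region. The through-height
#' structure is piecewise constant (CEP bands of exact thickness capping
#' the core), so each in-plane cell column is split analytically into its
#' z-bands; only the in-plane elliptical boundaries are resolved by
#' midpoint sampling of the dual (cell-centred) grid. The estimate stays
#' within a fraction of a voxel layer of the analytic volume.
#'
#' @param geometry a [build_idealized_disc()] result.
#' @return named numeric vector of quadrant volumes, mm^3 (`NP`, `AF`,
#'   `CEP`).
#' @export
region_volumes <- function(geometry) {
  dim <- geometry$dim
  h <- geometry$h
  xc <- geometry$x[-1] - h / 2
  yc <- geometry$y[-1] - h / 2
  g <- expand.grid(x = xc, y = yc, KEEP.OUT.ATTRS = FALSE)
  a <- dim$halfwidth_ap; b <- dim$halfwidth_lat
  in_disc <- (g$x / a)^2 + (g$y / b)^2 <= 1
  in_np <- (g$x / (dim$np_fraction * a))^2 +
    (g$y / (dim$np_fraction * b))^2 <= 1
  in_cep <- (g$x / (dim$cep_fraction * a))^2 +
    (g$y / (dim$cep_fraction * b))^2 <= 1
  H <- dim$height
  cep_h <- 2 * dim$cep_thickness              # both endplates
  core_h <- H - cep_h
  np_vol <- sum(in_disc & in_np) * core_h
  cep_vol <- sum(in_disc & in_cep) * cep_h
  af_vol <- sum(in_disc) * H - np_vol - cep_vol
  c(NP = np_vol, AF = af_vol, CEP = cep_vol) * h^2
}

#' Mid-height anterior-posterior node path
#'
#' Returns the node path along the anterior-posterior axis at mid-disc
#' height on the lateral symmetry plane, ordered from the outer AF surface
#' (normalized position 0) to the disc centre (position 1 for the quadrant
#' path). With `mirror = TRUE` the path continues through the centre to the
#' opposite AF surface (positions 0 to 1 across the full width), as used
#' for anterior-to-posterior concentration profiles.
#'
#' @param geometry a [build_idealized_disc()] result.
#' @param mirror reflect the quadrant path into a full-width path.
#' @return data.frame with columns `i`, `j`, `k` (node indices; mirrored
#'   half reuses the quadrant indices), `x_mm` (signed position), `s`
#'   (normalized position in \[0, 1\]) and `region`.
#' @export
extract_midheight_line <- function(geometry, mirror = FALSE) {
  k <- which.min(abs(geometry$z))
  j <- 1L
  tissue_i <- which(geometry$region[, j, k] != "EXTERIOR")
  i <- rev(tissue_i)                      # outer AF -> centre
  x <- geometry$x[i]
  if (mirror) {
    i <- c(i, rev(i[-length(i)]))
    x <- c(-x, rev(x[-length(x)]))
  }
  s <- (x - x[1]) / (x[length(x)] - x[1])
  data.frame(i = i, j = j, k = k, x_mm = x, s = s,
             region = geometry$region[cbind(i, j, k)])
}
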