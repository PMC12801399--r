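# shared fixtures; expensive objects are built lazily and cached per session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# laterally reduced disc keeping the default height/CEP; fast to solve on
small_disc_dims <- function(grid_spacing = 0.25) {
  disc_dimensions(halfwidth_ap = 5, halfwidth_lat = 6, height = 4,
                  cep_thickness = 0.6, grid_spacing = grid_spacing)
}

small_disc <- function() {
  cached("small_disc", build_idealized_disc(small_disc_dims()))
}

# representative per-cell rate sets; the degenerated per-cell OCR exceeds
# twice the healthy one so that the viability-scaled volumetric consumption
# is elevated in the degenerated state
rates_healthy <- function() metabolic_rates(ocr = 3.8, lpr = 16)
rates_degenerated <- function() metabolic_rates(ocr = 9.5, lpr = 30)

# single-region slab problem with a constant (unclamped) glucose sink
slab_problem <- function(L = 1, n = 101L, sink = 1, c0 = 4, D_NP = 0.45) {
  list(geometry = slab_geometry(L, n = n),
       diffusion = diffusion_table("healthy"),
       boundaries = {
         bt <- boundary_table("healthy")
         bt$values$glucose <- c(AF_OUTER = c0, CEP_FACE = c0)
         bt
       },
       sinks = list(base = list(glucose = c(NP = sink, AF = sink,
                                            CEP = sink)),
                    km = list(glucose = NULL)),
       exact = function(x) c0 - sink / (2 * D_NP) * x * (L - x))
}
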