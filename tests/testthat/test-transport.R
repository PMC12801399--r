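test_that("zero sinks with equal boundary values give a uniform field", {
  g <- small_disc()
  bt <- boundary_table("healthy")
  bt$values$oxygen <- c(AF_OUTER = 10, CEP_FACE = 10)
  sk <- list(base = list(oxygen = c(NP = 0, AF = 0, CEP = 0)),
             km = list(oxygen = NULL))
  f <- solve_steady_state(g, diffusion_table("healthy"), bt, sk,
                          species = "oxygen")
  v <- f$oxygen$value[!is.na(f$oxygen$value)]
  expect_lt(max(abs(v - 10)), 1e-8)
})

test_that("slab solution matches the constant-sink parabola", {
  pr <- slab_problem(L = 1, n = 101L)
  f <- solve_steady_state(pr$geometry, pr$diffusion, pr$boundaries,
                          pr$sinks, species = "glucose")
  exact <- pr$exact(pr$geometry$x)
  expect_lt(max(abs(f$glucose$value[, 1, 1] - exact) / exact), 0.005)
  # profile sampling reproduces the same parabola
  p <- field_profile(f$glucose, pr$geometry, mirror = FALSE)
  expect_lt(max(abs(p$value - pr$exact(rev(pr$geometry$x))) /
                  pr$exact(rev(pr$geometry$x))), 0.005)
})

test_that("boundary influx balances interior consumption", {
  g <- small_disc()
  dt <- diffusion_table("healthy")
  sk <- disc_sinks(rates_healthy(), cell_densities("healthy"))
  f <- solve_steady_state(g, dt, boundary_table("healthy"), sk)
  for (sp in c("oxygen", "glucose", "lactate")) {
    fb <- flux_balance(f[[sp]], g, dt)
    expect_lt(fb$imbalance, 1e-6)
  }
})

test_that("consumed species attain interior minima, produced interior maxima", {
  g <- small_disc()
  f <- solve_steady_state(g, diffusion_table("degenerated"),
                          boundary_table("degenerated"),
                          disc_sinks(rates_degenerated(),
                                     cell_densities("degenerated")))
  for (sp in c("oxygen", "glucose")) {
    p <- field_profile(f[[sp]], g)
    interior_min <- min(p$value)
    expect_lt(interior_min, min(p$value[c(1, nrow(p))]))
    expect_gt(which.min(p$value), 1)
    expect_lt(which.min(p$value), nrow(p))
  }
  p <- field_profile(f$lactate, g)
  expect_gt(max(p$value), max(p$value[c(1, nrow(p))]))
  # all concentrations non-negative
  for (sp in c("oxygen", "glucose", "lactate"))
    expect_true(all(f[[sp]]$value >= 0, na.rm = TRUE))
})

test_that("pH field is the monotone image of the lactate field", {
  g <- small_disc()
  f <- solve_steady_state(g, diffusion_table("degenerated"),
                          boundary_table("degenerated"),
                          disc_sinks(rates_degenerated(),
                                     cell_densities("degenerated")),
                          species = "lactate")
  ph <- derive_ph_field(f$lactate, ph_lactate_map())
  expect_identical(which.max(f$lactate$value), which.min(ph$value))
  lac0 <- f$lactate
  lac0$value[] <- ifelse(is.na(lac0$value), NA, 0)
  ph0 <- derive_ph_field(lac0)
  expect_equal(unique(ph0$value[!is.na(ph0$value)]),
               ph_lactate_map()$intercept)
})

test_that("NP-centre responses are monotone in the metabolic rates", {
  g <- small_disc()
  dt <- diffusion_table("healthy")
  bt <- boundary_table("healthy")
  dens <- cell_densities("healthy")
  centres <- sapply(c(2, 6, 18), function(ocr) {
    sk <- disc_sinks(metabolic_rates(ocr, 16), dens)
    f <- solve_steady_state(g, dt, bt, sk, species = "oxygen")
    np_centre_value(f$oxygen, g)
  })
  expect_true(all(diff(centres) < 0))
  centres <- sapply(c(4, 12, 36), function(lpr) {
    sk <- disc_sinks(metabolic_rates(3.8, lpr), dens)
    f <- solve_steady_state(g, dt, bt, sk, species = c("glucose", "lactate"))
    c(np_centre_value(f$glucose, g), np_centre_value(f$lactate, g))
  })
  expect_true(all(diff(centres[1, ]) < 0))  # glucose falls with GCR
  expect_true(all(diff(centres[2, ]) > 0))  # lactate rises with LPR
})

test_that("without the clamp, doubling the sink doubles the centre drop", {
  g <- small_disc()
  dt <- diffusion_table("healthy")
  bt <- boundary_table("healthy")
  bt$values$glucose <- c(AF_OUTER = 4, CEP_FACE = 4)  # homogeneous boundary
  drop_for <- function(scale) {
    sk <- list(base = list(glucose = c(NP = 0.002, AF = 0.006,
                                       CEP = 0) * scale),
               km = list(glucose = NULL))
    f <- solve_steady_state(g, dt, bt, sk, species = "glucose")
    4 - np_centre_value(f$glucose, g)
  }
  d1 <- drop_for(1)
  d2 <- drop_for(2)
  expect_equal(d2 / d1, 2, tolerance = 1e-8)
})

test_that("NP-centre values converge under grid refinement", {
  # interfaces (CEP plane at |z| = 1.5) aligned at both resolutions
  dims_c <- disc_dimensions(halfwidth_ap = 4, halfwidth_lat = 4.5,
                            height = 4, cep_thickness = 0.5,
                            grid_spacing = 0.25)
  dims_f <- disc_dimensions(halfwidth_ap = 4, halfwidth_lat = 4.5,
                            height = 4, cep_thickness = 0.5,
                            grid_spacing = 0.125)
  dt <- diffusion_table("healthy")
  bt <- boundary_table("healthy")
  sk <- disc_sinks(rates_healthy(), cell_densities("healthy"))
  cc <- sapply(list(dims_c, dims_f), function(d) {
    g <- build_idealized_disc(d)
    f <- solve_steady_state(g, dt, bt, sk, species = c("oxygen", "glucose"))
    c(np_centre_value(f$oxygen, g), np_centre_value(f$glucose, g))
  })
  expect_true(all(abs(cc[, 1] - cc[, 2]) / cc[, 2] < 0.01))
})

test_that("solver reports convergence metadata and fails loudly", {
  pr <- slab_problem()
  f <- solve_steady_state(pr$geometry, pr$diffusion, pr$boundaries, pr$sinks,
                          species = "glucose")
  expect_true(f$glucose$converged)
  expect_lt(f$glucose$residual, 1e-8)
  sk <- list(base = list(glucose = c(NP = 5, AF = 5, CEP = 5)),
             km = list(glucose = 0.05))
  expect_error(
    solve_steady_state(pr$geometry, pr$diffusion, pr$boundaries, sk,
                       species = "glucose", max_iter = 2L),
    "did not converge")
})
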