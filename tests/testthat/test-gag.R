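test_that("cumulative synthesis integrates the volumetric rate exactly", {
  st <- simulate_gag(gag_parameters("degenerated"), 2453.2, horizon = 10)
  S <- 25.9 * 2453.2 * 365 * 1e-6
  expect_equal(st$S, S)
  expect_identical(max(abs(st$trajectory$cumulative_ug_mm3 -
                             S * st$trajectory$t_years)), 0)
  expect_equal(tail(st$trajectory$cumulative_ug_mm3, 1), S * 10)
})

test_that("pure decay and the general closed form are reproduced", {
  # s = 0: exponential decay of the initial content
  p0 <- gag_parameters("healthy", synthesis_rate = 0, initial_content = 100)
  st0 <- simulate_gag(p0, active_density = 0, horizon = 10)
  expect_equal(tail(st0$trajectory$net_ug_mm3, 1), 100 * exp(-0.86),
               tolerance = 1e-8)
  # arbitrary parameter sets against G(t) = S/k + (G0 - S/k) exp(-kt)
  cases <- list(c(s = 25.9, rho = 2453.2, k = 0.086, G0 = 0),
                c(s = 25.4, rho = 4906.4, k = 0.086, G0 = 40),
                c(s = 10, rho = 1000, k = 0.3, G0 = 5))
  for (cs in cases) {
    p <- gag_parameters("healthy", synthesis_rate = cs[["s"]],
                        degradation_rate = cs[["k"]],
                        initial_content = cs[["G0"]])
    st <- simulate_gag(p, cs[["rho"]], horizon = 10, step = 1)
    S <- cs[["s"]] * cs[["rho"]] * 365 * 1e-6
    t <- st$trajectory$t_years
    exact <- S / cs[["k"]] + (cs[["G0"]] - S / cs[["k"]]) * exp(-cs[["k"]] * t)
    expect_lt(max(abs(st$trajectory$net_ug_mm3 - exact) / pmax(exact, 1e-9)),
              1e-6)
  }
})

test_that("degradation can be scaled by viability", {
  p <- gag_parameters("degenerated", degradation_viability_scaling = TRUE)
  st <- simulate_gag(p, 2453.2, horizon = 5, viability = 0.4)
  expect_equal(st$k, 0.086 * 0.4)
})

test_that("trajectory invariants hold", {
  st <- simulate_gag(gag_parameters("degenerated", initial_content = 20),
                     2453.2, horizon = 10)
  tr <- st$trajectory
  expect_true(all(diff(tr$cumulative_ug_mm3) >= 0))
  expect_true(all(tr$net_ug_mm3 >= 0))
  expect_true(all(tr$net_ug_mm3 <= 20 + tr$cumulative_ug_mm3 + 1e-9))
  # halving the step barely moves the 10-year value
  st2 <- simulate_gag(gag_parameters("degenerated", initial_content = 20),
                      2453.2, horizon = 10, step = 0.5)
  expect_lt(abs(tail(st$trajectory$net_ug_mm3, 1) -
                  tail(st2$trajectory$net_ug_mm3, 1)) /
              tail(st2$trajectory$net_ug_mm3, 1), 1e-4)
  # long-horizon equilibrium at S/k
  stl <- simulate_gag(gag_parameters("degenerated"), 2453.2, horizon = 200,
                      step = 5)
  expect_lt(abs(tail(stl$trajectory$net_ug_mm3, 1) - stl$S / stl$k) /
              (stl$S / stl$k), 0.01)
})

test_that("slope fitting is exact on lines and bounded by synthesis", {
  st <- simulate_gag(gag_parameters("degenerated"), 2453.2, horizon = 10)
  fake <- st
  fake$trajectory$net_ug_mm3 <- 5 + 3 * fake$trajectory$t_years
  expect_equal(fit_slope(fake, "net"), 3)
  expect_equal(fit_slope(st, "cumulative"), st$S)
  expect_lt(fit_slope(st, "net"), st$S)  # degradation lowers the net slope
  short <- st
  short$trajectory <- short$trajectory[1, , drop = FALSE]
  expect_error(fit_slope(short), "two time points")
})

test_that("snapshots paint the NP with the trajectory value", {
  g <- small_disc()
  st0 <- simulate_gag(gag_parameters("healthy", initial_content = 0),
                      4906.4, horizon = 5)
  snap0 <- gag_field_snapshot(st0, g, year = 0)
  expect_true(all(snap0[g$region == "NP"] == 0))
  expect_true(all(is.na(snap0[g$region != "NP"])))
  snap_end <- gag_field_snapshot(st0, g, year = 5)
  expect_equal(unique(snap_end[g$region == "NP"]),
               tail(st0$trajectory$net_ug_mm3, 1))
  # healthy exceeds degenerated everywhere in the NP at 5 years
  std <- simulate_gag(gag_parameters("degenerated"), 2453.2, horizon = 5)
  diff5 <- snap_end - gag_field_snapshot(std, g, year = 5)
  expect_true(all(diff5[g$region == "NP"] > 0))
  expect_error(gag_field_snapshot(st0, g, year = 6), "horizon")
  expect_error(simulate_gag(gag_parameters("healthy"), 100, horizon = 0.001,
                            step = 10), "exceeds")
})
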