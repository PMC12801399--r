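test_that("acellular wells hold their composition; oxygen relaxes to setpoint", {
  sys <- bead_system(cell_density = 0, incubator_oxygen = 2)
  run <- simulate_well(sys, condition = list(oxygen = 20, glucose = 0.5,
                                             ph = 6.5), days = 1)
  s <- run$series
  expect_lt(max(abs(s$glucose_media - 0.5)), 1e-9)
  expect_lt(max(abs(s$lactate_media)), 1e-9)
  # media O2 starts at 20% and relaxes toward 2% with tau = 2 h; the bead
  # equilibrates alongside and perturbs the pure exponential by < 2%
  expected <- 2 + 18 * exp(-s$time_h / sys$gas_tau)
  expect_lt(max(abs(s$oxygen_media - expected)) / 20, 0.02)
  expect_equal(unname(max_gradient(run)[c("glucose", "lactate")]),
               c(0, 0), tolerance = 1e-9)
})

test_that("with fast bead diffusion the media follows the reservoir balance", {
  rates <- metabolic_rates(ocr = 0, lpr = 20)  # gcr = 10
  sys <- bead_system(rates = rates, incubator_oxygen = 5,
                     diffusivity = c(oxygen = 1e4, glucose = 1e4,
                                     lactate = 1e4),
                     km = list(oxygen = NULL, glucose = NULL,
                               lactate = NULL))
  run <- simulate_well(sys, condition = list(oxygen = 5, glucose = 5,
                                             ph = 7.1), days = 3)
  s <- run$series
  n_cells <- sys$cell_density * sys$bead_volume_mL       # cells in the bead
  slope_expected <- n_cells / 1e6 * rates$gcr / (sys$media_volume * 1000)
  fit <- stats::coef(stats::lm(glucose_media ~ time_h, data = s))
  expect_equal(unname(-fit[2]), slope_expected, tolerance = 0.01)
  # lactate accumulates at twice the glucose consumption rate
  fitl <- stats::coef(stats::lm(lactate_media ~ time_h, data = s))
  expect_equal(unname(fitl[2]), 2 * slope_expected, tolerance = 0.01)
})

test_that("hypoxic acidic low-glucose conditions stay in band over 3 days", {
  sys <- bead_system(rates = metabolic_rates(3.8, 20), incubator_oxygen = 2)
  run <- simulate_well(sys, condition = list(oxygen = 2, glucose = 0.5,
                                             ph = 6.5), days = 3)
  s <- run$series
  expect_true(all(s$glucose_media > 0))
  expect_gt(min(s$glucose_media), 0.45)          # within the verified band
  expect_lt(abs(s$oxygen_media[nrow(s)] - 2), 0.1)
  expect_lt(max(abs(s$ph_media - 6.5)), 0.05)
})

test_that("spatial gradients grow with cell density", {
  grads <- vapply(c(1e6, 2.5e6, 5e6), function(d) {
    sys <- bead_system(cell_density = d, incubator_oxygen = 2)
    run <- simulate_well(sys, condition = list(oxygen = 2, glucose = 0.5,
                                               ph = 6.5), days = 1)
    max_gradient(run)[["oxygen"]]
  }, numeric(1))
  expect_true(all(diff(grads) > 0))
})

test_that("steady bead profile matches the spherical closed form", {
  sys <- bead_system(cell_density = 2.5e6, media_volume = 40, gas_tau = 1e9,
                     km = list(oxygen = NULL, glucose = NULL,
                               lactate = NULL),
                     rates = metabolic_rates(3.8, 20), n_shells = 40L)
  run <- simulate_well(sys, condition = list(oxygen = 5, glucose = 5,
                                             ph = 7.1), days = 4)
  R <- volumetric_sink(3.8, sys$cell_density / 1000) / sys$o2_factor
  c_s <- tail(run$series$oxygen_media, 1)
  exact <- spherical_profile(run$r_mm, sys$bead_radius, R,
                             sys$diffusivity[["oxygen"]], c_s)
  expect_lt(max(abs(run$profile$oxygen - exact) / exact), 0.01)
})

test_that("bead-media exchange conserves mass", {
  sys <- bead_system(cell_density = 2.5e6, gas_tau = 1e12,
                     km = list(oxygen = NULL, glucose = NULL,
                               lactate = NULL),
                     rates = metabolic_rates(0, 10), incubator_oxygen = 5)
  run <- simulate_well(sys, condition = list(oxygen = 5, glucose = 5,
                                             ph = 7.1), days = 2)
  vol <- run$shell_volumes_mm3
  total_end <- sum(run$profile$glucose * vol) +
    tail(run$series$glucose_media, 1) * run$media_volume_mm3
  consumed <- volumetric_sink(5, sys$cell_density / 1000) * sum(vol) * 48
  total_start <- 5 * (sum(vol) + run$media_volume_mm3)
  expect_lt(abs(total_end - (total_start - consumed)) / total_start, 1e-6)
})

test_that("media changes reset the reservoir and obey the horizon", {
  sys <- bead_system(rates = metabolic_rates(3.8, 20), incubator_oxygen = 2)
  run <- simulate_well(sys, condition = list(oxygen = 2, glucose = 0.5,
                                             ph = 6.5),
                       schedule = culture_schedule(interval_days = 3,
                                                   n_changes = 1),
                       days = 6)
  s <- run$series
  after <- s[s$time_h > 72 & s$time_h <= 72.5, ]
  # refresh exposes the media to ~20% oxygen, then it decays toward 2%
  expect_gt(max(after$oxygen_media), 15)
  expect_lt(abs(after$glucose_media[1] - 0.5), 0.01)
  expect_lt(after$lactate_media[1], 0.01)
  expect_error(
    simulate_well(sys, condition = list(oxygen = 2, glucose = 0.5, ph = 6.5),
                  schedule = culture_schedule(interval_days = 3,
                                              n_changes = 3),
                  days = 6),
    "outside the simulated horizon")
  expect_error(bead_system(bead_radius = 5, media_volume = 2), "small")
})
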