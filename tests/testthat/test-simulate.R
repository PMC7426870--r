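test_that("default design yields the canonical 8-curve, 2800-point series", {
  des <- simulation_design()
  expect_length(des$concentrations, 8)
  expect_true(0 %in% des$concentrations)
  ds <- simulate_dataset(lam8(), des)
  expect_equal(ds$n_curves, 8)
  expect_equal(ds$n_data, 2 * 175 * 8)
})

test_that("noiseless simulation equals the model exactly", {
  kin <- lam8()
  des <- small_design(noise = 0, samples = 12)
  nui <- curve_nuisance(0.8, 0.1, 0.7, 0.1)
  s <- simulate_sensorgram(kin, nui, 2, des)
  expect_equal(s$assoc_y, eval_binding(s$assoc_t, 2, kin, nui))
  expect_equal(s$dissoc_y, eval_unbinding(s$dissoc_t, kin, nui))
})

test_that("saturation amplitudes follow C/(C + K_D) with a flat control", {
  kin <- lam8()
  kd <- equilibrium_kd(kin)
  des <- simulation_design(concentrations = c(kd, 8, 0),
                           samples_per_phase = 10, noise_sigma = 0, seed = 2)
  ds <- simulate_dataset(kin, des, continuity = FALSE)
  # half-saturation at C = K_D: a_off = a_on = a_max/2 read off dissoc t=0
  expect_equal(ds$curves[[1]]$dissoc_y[1], des$a_max / 2, tolerance = 1e-12)
  # control curve is flat at baseline apart from leak (zero here)
  expect_true(all(abs(ds$curves[[3]]$assoc_y) < 1e-14))
})

test_that("dissociation starts where the noiseless association ends", {
  kin <- lam8()
  des <- small_design(noise = 0, samples = 15)
  ds <- simulate_dataset(kin, des, continuity = TRUE)
  for (s in ds$curves)
    expect_equal(s$dissoc_y[1], s$assoc_y[length(s$assoc_y)],
                 tolerance = 1e-12)
})

test_that("noise magnitude matches the design sigma", {
  kin <- lam8()
  des <- simulation_design(concentrations = c(4, 1), noise_sigma = 0.02,
                           samples_per_phase = 2500, seed = 13)
  ds <- simulate_dataset(kin, des)
  des0 <- des; des0$noise_sigma <- 0
  ds0 <- simulate_dataset(kin, des0)
  dev <- unlist(lapply(1:2, function(i)
    c(ds$curves[[i]]$assoc_y - ds0$curves[[i]]$assoc_y,
      ds$curves[[i]]$dissoc_y - ds0$curves[[i]]$dissoc_y)))
  expect_equal(sd(dev), 0.02, tolerance = 0.05)
  expect_equal(mean(dev), 0, tolerance = 0.002)
})

test_that("seeds are reproducible and per-curve substreams are stable", {
  kin <- lam8()
  d1 <- simulate_dataset(kin, small_design(seed = 4, noise = 0.01))
  d2 <- simulate_dataset(kin, small_design(seed = 4, noise = 0.01))
  d3 <- simulate_dataset(kin, small_design(seed = 5, noise = 0.01))
  expect_identical(d1$curves[[1]]$assoc_y, d2$curves[[1]]$assoc_y)
  expect_false(identical(d1$curves[[1]]$assoc_y, d3$curves[[1]]$assoc_y))

  # appending a concentration must not reshuffle existing curves' noise
  wide <- simulate_dataset(kin, small_design(
    seed = 4, noise = 0.01, concentrations = c(8, 2, 0.5, 0, 16)))
  for (i in 1:4)
    expect_identical(wide$curves[[i]]$assoc_y, d1$curves[[i]]$assoc_y)
})

test_that("the scenario library matches the reported affinities", {
  lib <- optonb_scenarios()
  expect_length(lib, 7)
  expect_equal(equilibrium_kd(lib[["LaM8"]]$kin), 0.26, tolerance = 0.02)
  expect_equal(equilibrium_kd(lib[["LaM8-AK74-lit"]]$kin), 7.6,
               tolerance = 0.01)
  # k_off/k_on agrees with each reported K_D within rounding of the
  # printed rates (half an ulp on each rate)
  for (e in lib) {
    # reported rates carry 2 significant digits; perturb by half their ulp
    half_ulp <- function(x) 0.5 * 10^(floor(log10(x)) - 1)
    lo <- (e$kin$k_off - half_ulp(e$kin$k_off)) /
      (e$kin$k_on + half_ulp(e$kin$k_on))
    hi <- (e$kin$k_off + half_ulp(e$kin$k_off)) /
      (e$kin$k_on - half_ulp(e$kin$k_on))
    expect_true(e$kd_reported >= lo && e$kd_reported <= hi,
                label = sprintf("%s K_D consistency", e$variant))
  }
  # affinity ordering: GG15 dark binds tighter, AK74 lit binds tighter
  expect_lt(equilibrium_kd(lib[["LaM8-GG15-dark"]]$kin),
            equilibrium_kd(lib[["LaM8-GG15-lit"]]$kin))
  expect_gt(equilibrium_kd(lib[["LaM8-AK74-dark"]]$kin),
            equilibrium_kd(lib[["LaM8-AK74-lit"]]$kin))
})

test_that("degenerate scenarios are rejected", {
  expect_error(simulate_dataset(kinetic_params(0, 0.1), small_design()),
               "degenerate")
  expect_error(simulation_design(concentrations = c(1, 1, 0)), "distinct")
})
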