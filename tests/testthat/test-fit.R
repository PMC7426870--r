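test_that("residuals vanish on noiseless data at the generating parameters", {
  kin <- lam8()
  ds <- simulate_dataset(kin, small_design(noise = 0))
  kd <- equilibrium_kd(kin)
  truth <- parameter_vector(kin, lapply(ds$curves, function(s) {
    C <- s$concentration
    a_on <- if (C > 0) C / (C + kd) else 0
    a_off <- s$dissoc_y[1] # noiseless: first dissoc sample is a_off + b_off
    curve_nuisance(a_on, 0, a_off, 0)
  }))
  r <- bli_residuals(ds, truth)
  expect_length(r, ds$n_data)
  expect_lt(max(abs(r)), 1e-12)
})

test_that("residuals recover the injected noise exactly at the truth", {
  kin <- lam8()
  des <- small_design(seed = 7, noise = 0.01, samples = 20,
                      concentrations = c(4, 1))
  ds_noisy <- simulate_dataset(kin, des)
  des0 <- des; des0$noise_sigma <- 0
  ds_clean <- simulate_dataset(kin, des0)
  kd <- equilibrium_kd(kin)
  truth <- parameter_vector(kin, lapply(ds_clean$curves, function(s) {
    C <- s$concentration
    curve_nuisance(C / (C + kd), 0, s$dissoc_y[1], 0)
  }))
  injected <- unlist(lapply(seq_along(ds_noisy$curves), function(i)
    c(ds_noisy$curves[[i]]$assoc_y - ds_clean$curves[[i]]$assoc_y,
      ds_noisy$curves[[i]]$dissoc_y - ds_clean$curves[[i]]$dissoc_y)))
  expect_equal(bli_residuals(ds_noisy, truth), injected, tolerance = 1e-10)
})

test_that("residual ordering is curve-major, association first, time-ascending", {
  t <- 0:4
  s1 <- sensorgram("c1", 1, t, rep(1, 5), t, rep(2, 5))
  s2 <- sensorgram("c2", 2, t, rep(3, 5), t, rep(4, 5))
  ds <- bli_dataset(list(s1, s2))
  p <- parameter_vector(kinetic_params(0, 0, 0),
                        list(curve_nuisance(0), curve_nuisance(0)))
  # with all parameters zero the model is 0 everywhere: residual = data
  expect_equal(bli_residuals(ds, p), rep(c(1, 2, 3, 4), each = 5))
})

test_that("sse equals a naive loop accumulation", {
  kin <- lam8()
  ds <- simulate_dataset(kin, small_design(seed = 3, noise = 0.02))
  p <- initial_guess(ds)
  r <- bli_residuals(ds, p)
  acc <- 0
  for (i in seq_along(r)) acc <- acc + r[i]^2
  expect_equal(bli_sse(ds, p), acc, tolerance = 1e-12)
  expect_equal(bli_sse(ds, p), sum(r^2))
  # structural error on mismatched nuisance count
  p_bad <- parameter_vector(kin, p$nuisances[1:2])
  expect_error(bli_sse(ds, p_bad), "nuisance")
})

test_that("initial guess lands near the truth and inside the bounds", {
  kin <- lam8()
  ds <- simulate_dataset(kin, simulation_design(seed = 1, noise_sigma = 0,
                                                samples_per_phase = 60))
  g <- initial_guess(ds)
  expect_lt(abs(g$kin$k_on - kin$k_on) / kin$k_on, 0.5)
  expect_lt(abs(g$kin$k_off - kin$k_off) / kin$k_off, 0.5)
  expect_true(all(vapply(g$nuisances, function(u)
    u$a_on >= 0 && u$a_off >= 0, logical(1))))
  expect_true(g$kin$k_on >= 0 && g$kin$k_off >= 0 && g$kin$k_leak >= 0)
})

test_that("degenerate designs are rejected by the guesser", {
  t <- 0:9
  same <- lapply(c("a", "b"), function(id)
    sensorgram(id, 2, t, exp(-t / 3), t, exp(-t / 3)))
  expect_error(initial_guess(bli_dataset(same)), "degenerate")
  # all-zero concentrations are equally degenerate
  zero <- lapply(c("a", "b"), function(id)
    sensorgram(id, 0, t, rep(0, 10), t, rep(0, 10)))
  expect_error(initial_guess(bli_dataset(zero)), "degenerate")
})

test_that("an 8-curve global fit exposes 4n + 3 = 35 free parameters", {
  ds <- simulate_dataset(lam8(), small_design(
    samples = 10, concentrations = c(8, 4, 2, 1, 0.5, 0.25, 0.125, 0)))
  expect_equal(length(initial_guess(ds)), 35L)
  fit <- fit_global(ds, opts = fit_options(tolerance = 1e-8))
  expect_equal(fit$n_params, 35L)
  expect_length(fit$residuals, ds$n_data)
})

test_that("the fit is idempotent at the optimum and honours fixed parameters", {
  ds <- simulate_dataset(lam8(), small_design(seed = 5, noise = 0.005))
  fit <- fit_global(ds)
  expect_true(fit$converged)
  refit <- fit_global(ds, start = fit$params_opt, opts = fit$opts)
  expect_equal(refit$params_opt$kin$k_on, fit$params_opt$kin$k_on,
               tolerance = 1e-6)
  expect_equal(refit$sse_opt, fit$sse_opt, tolerance = 1e-8)
  expect_lte(refit$sse_opt, fit$sse_opt * (1 + 1e-12)) # monotone descent

  cf <- fit_global(ds, start = fit$params_opt, opts = fit$opts,
                   fixed = c(k_on = 0.05))
  expect_equal(cf$params_opt$kin$k_on, 0.05)
  expect_equal(cf$n_params, fit$n_params - 1L)
  expect_gte(cf$sse_opt, fit$sse_opt)
})

test_that("curve order does not affect the shared-rate estimates", {
  ds <- simulate_dataset(lam8(), small_design(seed = 11, noise = 0.005))
  perm <- bli_dataset(ds$curves[c(3, 1, 4, 2)])
  f1 <- fit_global(ds)
  f2 <- fit_global(perm)
  expect_equal(f2$params_opt$kin$k_on, f1$params_opt$kin$k_on,
               tolerance = 1e-5)
  expect_equal(f2$params_opt$kin$k_off, f1$params_opt$kin$k_off,
               tolerance = 1e-5)
  expect_equal(f2$sse_opt, f1$sse_opt, tolerance = 1e-7)
})

test_that("a 2-curve rate fit matches an exhaustive grid-search argmin", {
  kin <- lam8()
  des <- small_design(seed = 9, noise = 0.01, samples = 25,
                      concentrations = c(4, 0.5))
  ds <- simulate_dataset(kin, des)
  des0 <- des; des0$noise_sigma <- 0
  ds0 <- simulate_dataset(kin, des0)
  kd <- equilibrium_kd(kin)
  nui_truth <- lapply(ds0$curves, function(s)
    curve_nuisance(s$concentration / (s$concentration + kd), 0,
                   s$dissoc_y[1], 0))
  truth <- parameter_vector(kin, nui_truth)

  # freeze the nuisances at truth and fit only (k_on, k_off)
  fx <- c(k_leak = kin$k_leak,
          unlist(lapply(seq_along(nui_truth), function(i)
            stats::setNames(unlist(nui_truth[[i]]),
                            paste0(c("a_on_", "b_on_", "a_off_", "b_off_"), i)))))
  fit <- fit_global(ds, start = truth, opts = quick_opts(), fixed = fx)
  expect_equal(fit$n_params, 2L)

  # independent oracle: exhaustive 200 x 200 grid over the rates
  kon_grid <- seq(0.5 * kin$k_on, 1.5 * kin$k_on, length.out = 200)
  koff_grid <- seq(0.5 * kin$k_off, 1.5 * kin$k_off, length.out = 200)
  sse_grid <- function(kon, koff) {
    p <- parameter_vector(kinetic_params(kon, koff, kin$k_leak), nui_truth)
    bli_sse(ds, p)
  }
  sses <- outer(kon_grid, koff_grid, Vectorize(sse_grid))
  idx <- which(sses == min(sses), arr.ind = TRUE)[1, ]
  cell_kon <- diff(kon_grid[1:2])
  cell_koff <- diff(koff_grid[1:2])
  expect_lt(abs(fit$params_opt$kin$k_on - kon_grid[idx[1]]), cell_kon)
  expect_lt(abs(fit$params_opt$kin$k_off - koff_grid[idx[2]]), cell_koff)
})
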