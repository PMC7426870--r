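test_that("normalized chi-squared is a pure SSE ratio", {
  expect_equal(normalized_chisq(1, 1), 1)
  expect_equal(normalized_chisq(2, 1), 2)
  # a common residual rescaling c > 0 cancels
  r <- c(0.3, -0.5, 1.2)
  for (c_ in c(0.1, 3, 100))
    expect_equal(normalized_chisq(sum((c_ * r)^2), sum((c_ * 0.8 * r)^2)),
                 normalized_chisq(sum(r^2), sum((0.8 * r)^2)))
  expect_error(normalized_chisq(1, 0), "perfect fit")
})

test_that("confidence threshold reproduces the F-quantile calibration", {
  thr <- confidence_threshold(35, 2800, 0.05)
  expect_equal(thr$f_quantile, 1.43, tolerance = 0.005)
  expect_equal(thr$chi2N_threshold, 1.018, tolerance = 1e-3)

  thr2 <- confidence_threshold(2, 10, 0.05)
  expect_equal(thr2$f_quantile, 4.10, tolerance = 0.001)
  expect_equal(thr2$chi2N_threshold, 1.821, tolerance = 0.001)

  # threshold -> 1 as the data dwarf the parameters
  expect_lt(confidence_threshold(35, 1e8, 0.05)$chi2N_threshold, 1.001)
  expect_error(confidence_threshold(100, 50), "n_params")
  expect_error(confidence_threshold(5, 100, alpha = 1.2), "alpha")
})

test_that("F quantile agrees with numeric CDF inversion on 20 triples", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(2:60, 1)
    df <- n + sample(20:3000, 1)
    a <- runif(1, 0.01, 0.2)
    # independent oracle: invert the F CDF by root finding
    oracle <- uniroot(function(q) stats::pf(q, n, df) - (1 - a),
                      c(1e-6, 1e3), tol = 1e-10)$root
    expect_equal(confidence_threshold(n, df, a)$f_quantile, oracle,
                 tolerance = 1e-6)
  }
})

test_that("CI extraction inverts a synthetic quadratic profile exactly", {
  grid <- exp(seq(log(1 / 4), log(4), length.out = 41))
  quad <- function(v) 1 + (v - 1)^2
  scan <- structure(list(parameter_name = "k_on", fixed_values = grid,
                         sse_values = quad(grid), chi2N_values = quad(grid),
                         best_value = 1, sse_opt = 1),
                    class = "profile_scan")
  thr <- structure(list(n_params = 35, n_data = 2800, alpha = 0.05,
                        f_quantile = 1.43, chi2N_threshold = 1.018),
                   class = "threshold_spec")
  ci <- ci_from_profile(scan, thr, refit = quad)
  # closed form: endpoints 1 +/- sqrt(0.018)
  expect_equal(ci$lower, 1 - sqrt(0.018), tolerance = 2e-3)
  expect_equal(ci$upper, 1 + sqrt(0.018), tolerance = 2e-3)
  expect_false(ci$censored_low || ci$censored_high)
  expect_equal(ci$half_width, max(1 - ci$lower, ci$upper - 1))
  # rendered in the conventional style
  expect_match(format_estimate(0.26, 0.021), "0.26 ± 0.02")
})

test_that("a flat profile censors both endpoints at the 4-fold range", {
  grid <- exp(seq(log(0.25), log(4), length.out = 21))
  scan <- structure(list(parameter_name = "k_off", fixed_values = grid,
                         sse_values = rep(1, 21), chi2N_values = rep(1, 21),
                         best_value = 1, sse_opt = 1),
                    class = "profile_scan")
  thr <- confidence_threshold(5, 100)
  ci <- ci_from_profile(scan, thr)
  expect_true(ci$censored_low && ci$censored_high)
  expect_equal(ci$lower, 0.25)
  expect_equal(ci$upper, 4)
})

test_that("profile refits reproduce the optimum and climb away from it", {
  kin <- lam8()
  ds <- simulate_dataset(kin, small_design(seed = 21, noise = 0.01))
  fit <- fit_global(ds)
  scan <- profile_parameter(ds, fit, "k_on", n_grid = 9)
  i0 <- which.min(abs(log(scan$fixed_values / scan$best_value)))
  # refit at the optimum reproduces it
  expect_equal(scan$chi2N_values[i0], 1, tolerance = 1e-6)
  # refits cannot beat the global optimum beyond numerical noise
  expect_true(all(scan$chi2N_values >= 1 - 1e-8))
  # chi2N rises moving outward on each side
  expect_true(all(diff(scan$chi2N_values[i0:length(scan$chi2N_values)]) > 0))
  expect_true(all(diff(scan$chi2N_values[i0:1]) > 0))
})

test_that("constrained SSE on noiseless data is monotone away from truth", {
  kin <- lam8()
  ds <- simulate_dataset(kin, small_design(noise = 0, samples = 30))
  fit <- fit_global(ds)
  scan <- profile_parameter(ds, fit, "k_off", n_grid = 7)
  i0 <- which.min(abs(log(scan$fixed_values / scan$best_value)))
  up <- scan$sse_values[i0:length(scan$sse_values)]
  dn <- scan$sse_values[i0:1]
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(dn) > 0))
})

test_that("fixing K_D is consistent with the direct-rate parameterization", {
  kin <- lam8()
  ds <- simulate_dataset(kin, small_design(seed = 31, noise = 0.01,
                                           samples = 25))
  fit <- fit_global(ds)
  # the same constraint set {k_on = a, k_off = a*kd} expressed both ways
  a <- fit$params_opt$kin$k_on * 1.1
  kd <- equilibrium_kd(fit$params_opt$kin) * 0.9
  f_rates <- fit_global(ds, start = fit$params_opt, opts = fit$opts,
                        fixed = c(k_on = a, k_off = a * kd))
  f_kd <- fit_global(ds, start = fit$params_opt, opts = fit$opts,
                     fixed = c(k_on = a), fixed_kd = kd)
  expect_equal(f_kd$sse_opt, f_rates$sse_opt, tolerance = 1e-8)
  expect_equal(f_kd$params_opt$kin$k_off, a * kd, tolerance = 1e-10)
})

test_that("CIs contain the best fit and tighten as noise drops", {
  kin <- lam8()
  widths <- vapply(c(0.02, 0.01, 0.005), function(sig) {
    ds <- simulate_dataset(kin, small_design(seed = 77, noise = sig,
                                             samples = 30))
    fit <- fit_global(ds)
    cis <- profile_confint(ds, fit, parameters = "k_on", n_grid = 11)
    ci <- cis[["k_on"]]
    expect_lte(ci$lower, ci$best_value)
    expect_gte(ci$upper, ci$best_value)
    ci$half_width
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
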