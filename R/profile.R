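#' Normalized chi-squared ratio
#'
#' \eqn{\chi^2_N = \chi^2(p) / \chi^2(p_{opt})}, implemented as the ratio
#' of sums of squared residuals. Any assumed data uncertainty sigma_data
#' scales numerator and denominator identically and cancels, which is why
#' profile confidence intervals here never depend on the noise scale
#' assumed for the instrument.
#'
#' @param sse_p sum of squared residuals of a constrained refit
#' @param sse_opt sum of squared residuals at the unconstrained optimum
#'   (must be positive)
#' @return the ratio \code{sse_p / sse_opt}
#' @export
normalized_chisq <- function(sse_p, sse_opt) {
  stopifnot(is.numeric(sse_p), is.numeric(sse_opt))
  if (any(sse_opt <= 0))
    stop("perfect fit (sse_opt = 0): the normalized chi-squared is undefined; for noiseless data compare raw SSE values instead",
         call. = FALSE)
  sse_p / sse_opt
}

#' F-statistic confidence threshold for profile intervals
#'
#' A constrained refit is accepted at level alpha while its normalized
#' chi-squared stays below
#' \deqn{\chi^2_{N,thr} = 1 + (n/DF)\, F_{\alpha}(n, DF)}
#' where n is the number of free parameters of the full fit and DF the
#' total number of data points, and F is the upper-alpha quantile of the F
#' distribution with (n, DF) degrees of freedom. For a typical 8-curve
#' global fit (n = 35, DF = 2800) at alpha = 0.05 the quantile is ~1.43
#' and the threshold ~1.018.
#'
#' @param n_params free-parameter count of the full fit
#' @param n_data total data-point count (must exceed n_params)
#' @param alpha significance level in (0, 1); default 0.05 for 95% CIs
#' @return an object of class \code{threshold_spec} with fields
#'   \code{n_params}, \code{n_data}, \code{alpha}, \code{f_quantile},
#'   \code{chi2N_threshold}
#' @export
confidence_threshold <- function(n_params, n_data, alpha = 0.05) {
  if (!is.numeric(n_params) || n_params < 1 ||
      !is.numeric(n_data) || n_data <= n_params)
    stop("need 1 <= n_params < n_data", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  fq <- stats::qf(1 - alpha, df1 = n_params, df2 = n_data)
  structure(list(n_params = n_params, n_data = n_data, alpha = alpha,
                 f_quantile = fq,
                 chi2N_threshold = 1 + (n_params / n_data) * fq),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("chi2N threshold %.4f (F_%.2f(%d, %d) = %.3f)\n",
              x$chi2N_threshold, x$alpha, x$n_params, x$n_data, x$f_quantile))
  invisible(x)
}

.refit_fixed <- function(dataset, fit, parameter_name, value) {
  start <- fit$params_opt
  if (parameter_name == "K_D") {
    fit_global(dataset, start = start, opts = fit$opts, fixed_kd = value)
  } else {
    fx <- stats::setNames(value, parameter_name)
    fit_global(dataset, start = start, opts = fit$opts, fixed = fx)
  }
}

## constrained SSE at a fixed parameter value, warm-started from the better
## of p_opt and a supplied alternative start
.profile_point <- function(dataset, fit, parameter_name, value,
                           alt_start = NULL) {
  f1 <- .refit_fixed(dataset, fit, parameter_name, value)
  if (!is.null(alt_start)) {
    f2 <- tryCatch({
      fit2 <- fit
      fit2$params_opt <- alt_start
      .refit_fixed(dataset, fit2, parameter_name, value)
    }, error = function(e) NULL)
    if (!is.null(f2) && f2$sse_opt < f1$sse_opt) f1 <- f2
  }
  f1
}

#' Profile one kinetic parameter over a 4-fold range
#'
#' Repeats the global fit with one of k_on, k_off, or K_D fixed to each
#' value of a log-spaced grid spanning best/4 to best*4 (all other
#' parameters refit, warm-started from the unconstrained optimum and,
#' as a pure improvement, from the neighboring grid point's solution when
#' that has lower SSE), and records the normalized chi-squared of each
#' constrained refit. Holding K_D fixed uses the (k_on, K_D, k_leak)
#' reparameterization with k_off := k_on * K_D.
#'
#' @param dataset the [bli_dataset()] that was fit
#' @param fit the unconstrained [fit_global()] result (must have converged)
#' @param parameter_name one of \code{"k_on"}, \code{"k_off"}, \code{"K_D"}
#' @param n_grid number of grid points (>= 5; default 41)
#' @return an object of class \code{profile_scan} with fields
#'   \code{parameter_name}, \code{fixed_values}, \code{sse_values},
#'   \code{chi2N_values}, \code{best_value}, \code{sse_opt}
#' @export
profile_parameter <- function(dataset, fit, parameter_name, n_grid = 41L) {
  stopifnot(inherits(fit, "bli_fit"))
  if (!fit$converged)
    stop("profile requires a converged fit", call. = FALSE)
  parameter_name <- match.arg(parameter_name, c("k_on", "k_off", "K_D"))
  if (n_grid < 5L) stop("'n_grid' must be >= 5", call. = FALSE)
  kin <- fit$params_opt$kin
  best <- switch(parameter_name,
                 k_on = kin$k_on, k_off = kin$k_off,
                 K_D = equilibrium_kd(kin))
  if (best <= 0)
    stop(sprintf("cannot profile '%s': best-fit value is not positive",
                 parameter_name), call. = FALSE)
  grid <- exp(seq(log(best / 4), log(best * 4), length.out = n_grid))
  i0 <- which.min(abs(log(grid / best)))

  sse <- numeric(n_grid)
  # sweep outward from the point nearest the optimum on each side so the
  # neighbor warm start is always available
  for (side in list(i0:1, if (i0 < n_grid) (i0 + 1L):n_grid else integer(0))) {
    prev <- NULL
    for (i in side) {
      res <- .profile_point(dataset, fit, parameter_name, grid[i],
                            alt_start = prev)
      sse[i] <- res$sse_opt
      prev <- res$params_opt
    }
  }
  structure(list(parameter_name = parameter_name, fixed_values = grid,
                 sse_values = sse,
                 chi2N_values = normalized_chisq(sse, fit$sse_opt),
                 best_value = best, sse_opt = fit$sse_opt),
            class = "profile_scan")
}

#' Confidence interval from a profile scan
#'
#' On each side of the best-fit value, finds the outermost fixed value
#' whose normalized chi-squared stays below the threshold; the crossing is
#' then refined to 1e-3 relative precision by bisection between the last
#' accepted and first rejected grid points when a \code{refit} closure is
#' supplied (as [profile_confint()] does), otherwise by monotone
#' interpolation on the grid. Sides whose entire 4-fold half-range stays
#' below threshold are censored at the range end. The reported
#' \code{half_width} is the maximum accepted deviation from the best-fit
#' value, matching the "best +/- half-width" reporting convention.
#'
#' @param scan a [profile_parameter()] result
#' @param threshold a [confidence_threshold()] for the same fit
#' @param refit optional function(value) returning the normalized
#'   chi-squared of a constrained refit at that fixed value
#' @return an object of class \code{confidence_interval} with fields
#'   \code{parameter_name}, \code{best_value}, \code{lower}, \code{upper},
#'   \code{half_width}, \code{censored_low}, \code{censored_high}
#' @export
ci_from_profile <- function(scan, threshold, refit = NULL) {
  stopifnot(inherits(scan, "profile_scan"),
            inherits(threshold, "threshold_spec"))
  thr <- threshold$chi2N_threshold
  grid <- scan$fixed_values
  chi <- scan$chi2N_values
  best <- scan$best_value
  i0 <- which.min(abs(log(grid / best)))
  if (chi[i0] >= thr)
    stop("inconsistent profile: the refit nearest the optimum exceeds the threshold",
         call. = FALSE)

  bisect <- function(acc, rej, chi_acc, chi_rej) {
    # crossing between an accepted and a rejected value, to 1e-3 relative
    if (!is.null(refit)) {
      while (abs(rej - acc) > 1e-3 * abs(acc)) {
        mid <- sqrt(acc * rej)
        if (refit(mid) < thr) acc <- mid else rej <- mid
      }
      acc
    } else {
      # linear interpolation of chi2N between the bracketing grid points
      acc + (thr - chi_acc) / (chi_rej - chi_acc) * (rej - acc)
    }
  }

  # upper side
  above <- which(seq_along(grid) > i0 & chi >= thr)
  if (length(above)) {
    j <- above[1]
    upper <- bisect(grid[j - 1L], grid[j], chi[j - 1L], chi[j])
    cens_hi <- FALSE
  } else {
    upper <- grid[length(grid)]
    cens_hi <- TRUE
  }
  # lower side
  below <- which(seq_along(grid) < i0 & chi >= thr)
  if (length(below)) {
    j <- below[length(below)]
    lower <- bisect(grid[j + 1L], grid[j], chi[j + 1L], chi[j])
    cens_lo <- FALSE
  } else {
    lower <- grid[1L]
    cens_lo <- TRUE
  }

  lower <- min(lower, best)
  upper <- max(upper, best)
  structure(list(parameter_name = scan$parameter_name, best_value = best,
                 lower = lower, upper = upper,
                 half_width = max(best - lower, upper - best),
                 censored_low = cens_lo, censored_high = cens_hi),
            class = "confidence_interval")
}

#' @export
print.confidence_interval <- function(x, ...) {
  cat(sprintf("%s: %s  [%.4g, %.4g]%s\n", x$parameter_name,
              format_estimate(x$best_value, x$half_width),
              x$lower, x$upper,
              if (x$censored_low || x$censored_high)
                " (censored at the 4-fold profiling range)" else ""))
  invisible(x)
}

#' Profile confidence intervals for the kinetic parameters
#'
#' Convenience wrapper: computes the F-statistic threshold from the fit's
#' free-parameter and data counts, profiles each requested parameter over
#' its 4-fold range, and extracts bisection-refined confidence intervals.
#'
#' @inheritParams profile_parameter
#' @param parameters which parameters to profile
#' @param alpha significance level (default 0.05 for 95% CIs)
#' @param n_grid grid points per parameter
#' @return a named list of [ci_from_profile()] results, with the
#'   \code{threshold_spec} attached as attribute \code{"threshold"}
#' @export
profile_confint <- function(dataset, fit,
                            parameters = c("k_on", "k_off", "K_D"),
                            alpha = 0.05, n_grid = 41L) {
  thr <- confidence_threshold(fit$n_params, fit$n_data, alpha)
  out <- lapply(parameters, function(pn) {
    scan <- profile_parameter(dataset, fit, pn, n_grid = n_grid)
    refit <- function(v)
      normalized_chisq(.profile_point(dataset, fit, pn, v)$sse_opt,
                       fit$sse_opt)
    ci_from_profile(scan, thr, refit = refit)
  })
  names(out) <- parameters
  attr(out, "threshold") <- thr
  out
}
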