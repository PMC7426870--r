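#' Full parameter vector for a global fit
#'
#' Bundles the shared kinetic rates with one set of per-curve nuisance
#' parameters per sensorgram. A dataset of n curves has 4n + 3 free
#' parameters in total: (k_on, k_off, k_leak) shared, plus (a_on, b_on,
#' a_off, b_off) for each curve.
#'
#' @param kin a [kinetic_params()] object
#' @param nuisances list of [curve_nuisance()] objects, one per curve, in
#'   dataset curve order
#' @return an object of class \code{parameter_vector}
#' @export
parameter_vector <- function(kin, nuisances) {
  stopifnot(inherits(kin, "kinetic_params"))
  if (!is.list(nuisances) ||
      !all(vapply(nuisances, inherits, logical(1), "curve_nuisance")))
    stop("'nuisances' must be a list of curve_nuisance objects", call. = FALSE)
  structure(list(kin = kin, nuisances = nuisances),
            class = "parameter_vector")
}

#' @export
length.parameter_vector <- function(x) 3L + 4L * length(x$nuisances)

## flat named-vector view used by the optimizer
.theta_names <- function(n_curves) {
  c("k_on", "k_off", "k_leak",
    as.vector(t(outer(seq_len(n_curves), c("a_on", "b_on", "a_off", "b_off"),
                      function(i, p) paste0(p, "_", i)))))
}

.pack <- function(params) {
  n <- length(params$nuisances)
  th <- c(params$kin$k_on, params$kin$k_off, params$kin$k_leak,
          unlist(lapply(params$nuisances, function(u)
            c(u$a_on, u$b_on, u$a_off, u$b_off))))
  names(th) <- .theta_names(n)
  th
}

.unpack <- function(theta, n_curves) {
  kin <- kinetic_params(max(theta[["k_on"]], 0), max(theta[["k_off"]], 0),
                        max(theta[["k_leak"]], 0))
  nuis <- lapply(seq_len(n_curves), function(i) {
    g <- function(p) theta[[paste0(p, "_", i)]]
    curve_nuisance(max(g("a_on"), 0), g("b_on"), max(g("a_off"), 0), g("b_off"))
  })
  parameter_vector(kin, nuis)
}

## raw residuals from the flat vector; no class checks, optimizer hot path
.resid_theta <- function(dataset, theta) {
  k_on <- theta[["k_on"]]; k_off <- theta[["k_off"]]; k_leak <- theta[["k_leak"]]
  out <- vector("list", 2L * dataset$n_curves)
  j <- 0L
  for (i in seq_len(dataset$n_curves)) {
    s <- dataset$curves[[i]]
    kobs <- k_on * s$concentration + k_off
    ma <- (theta[[paste0("a_on_", i)]] * (1 - exp(-kobs * s$assoc_t)) +
           theta[[paste0("b_on_", i)]]) * exp(-k_leak * s$assoc_t)
    md <- (theta[[paste0("a_off_", i)]] * exp(-k_off * s$dissoc_t) +
           theta[[paste0("b_off_", i)]]) * exp(-k_leak * s$dissoc_t)
    out[[j <- j + 1L]] <- s$assoc_y - ma
    out[[j <- j + 1L]] <- s$dissoc_y - md
  }
  unlist(out, use.names = FALSE)
}

## analytic Jacobian of the residual vector w.r.t. every named parameter,
## rows in residual order, columns in .theta_names() order; residual is
## (data - model), so entries are the negated model derivatives
.jac_theta <- function(dataset, theta) {
  n <- dataset$n_curves
  nms <- .theta_names(n)
  J <- matrix(0, nrow = dataset$n_data, ncol = length(nms),
              dimnames = list(NULL, nms))
  k_on <- theta[["k_on"]]; k_off <- theta[["k_off"]]; k_leak <- theta[["k_leak"]]
  row0 <- 0L
  for (i in seq_len(n)) {
    s <- dataset$curves[[i]]
    C <- s$concentration
    kobs <- k_on * C + k_off
    a_on <- theta[[paste0("a_on_", i)]]; b_on <- theta[[paste0("b_on_", i)]]
    a_off <- theta[[paste0("a_off_", i)]]; b_off <- theta[[paste0("b_off_", i)]]

    ta <- s$assoc_t
    E <- exp(-kobs * ta); L <- exp(-k_leak * ta)
    ya <- (a_on * (1 - E) + b_on) * L
    ra <- row0 + seq_along(ta)
    J[ra, "k_on"] <- -a_on * ta * E * C * L
    J[ra, "k_off"] <- -a_on * ta * E * L
    J[ra, "k_leak"] <- ta * ya
    J[ra, paste0("a_on_", i)] <- -(1 - E) * L
    J[ra, paste0("b_on_", i)] <- -L
    row0 <- row0 + length(ta)

    td <- s$dissoc_t
    D <- exp(-k_off * td); Ld <- exp(-k_leak * td)
    yd <- (a_off * D + b_off) * Ld
    rd <- row0 + seq_along(td)
    J[rd, "k_off"] <- a_off * td * D * Ld
    J[rd, "k_leak"] <- td * yd
    J[rd, paste0("a_off_", i)] <- -D * Ld
    J[rd, paste0("b_off_", i)] <- -Ld
    row0 <- row0 + length(td)
  }
  J
}

## box-constrained least squares for y ~ a*x1 + b*x2 with a in [0, span],
## b in [-span, span]; used to profile out each phase's amplitude/baseline
## pair for fixed rates (the model is linear in them)
.lsq2 <- function(x1, x2, y, span) {
  s11 <- sum(x1 * x1); s22 <- sum(x2 * x2); s12 <- sum(x1 * x2)
  det <- s11 * s22 - s12 * s12
  a <- if (s11 <= 1e-14 * s22 || det <= 1e-12 * s11 * s22) 0 else
    (sum(x1 * y) * s22 - sum(x2 * y) * s12) / det
  a <- min(max(a, 0), span)
  bb <- if (s22 > 0) sum(x2 * (y - a * x1)) / s22 else 0
  c(a, min(max(bb, -span), span))
}

#' Global-fit residual vector
#'
#' Concatenated (data - model) differences over every association and
#' dissociation sample of every curve, in a fixed documented order: curves
#' in dataset order, association phase before dissociation phase, samples
#' time-ascending. This ordering makes the sum of squares bit-reproducible.
#'
#' @param dataset a [bli_dataset()]
#' @param params a [parameter_vector()] with one nuisance set per curve
#' @return numeric vector of length \code{dataset$n_data}
#' @export
bli_residuals <- function(dataset, params) {
  stopifnot(inherits(dataset, "bli_dataset"),
            inherits(params, "parameter_vector"))
  if (length(params$nuisances) != dataset$n_curves)
    stop(sprintf("parameter vector has %d nuisance sets but dataset has %d curves",
                 length(params$nuisances), dataset$n_curves), call. = FALSE)
  .resid_theta(dataset, .pack(params))
}

#' Sum of squared residuals of a global fit
#'
#' The least-squares objective: the squared Euclidean norm of
#' [bli_residuals()]. The assumed data uncertainty sigma_data enters the
#' chi-squared only as a constant factor and cancels in the normalized
#' chi-squared ratio, so it plays no role in point estimation.
#'
#' @inheritParams bli_residuals
#' @return scalar >= 0
#' @export
bli_sse <- function(dataset, params) {
  r <- bli_residuals(dataset, params)
  sum(r * r)
}

#' Fitting options for the global least-squares fit
#'
#' @param max_iterations total optimizer iteration budget (default 5000)
#' @param tolerance relative SSE-change convergence threshold (default 1e-10)
#' @param rate_upper upper bound for all rates in their stated units
#'   (default 1e3); the lower bound for rates is 0 (positivity is physical)
#' @param bound_factor amplitudes are bounded in [0, bound_factor * max
#'   absolute signal], baselines in +/- the same span (default 10)
#' @param sigma_data optional assumed measurement noise scale, signal units,
#'   used for reporting only (it cancels in all inference ratios)
#' @param seed integer, recorded for provenance (the fit itself is
#'   deterministic)
#' @return an object of class \code{fit_options}
#' @export
fit_options <- function(max_iterations = 5000L, tolerance = 1e-10,
                        rate_upper = 1e3, bound_factor = 10,
                        sigma_data = NULL, seed = NULL) {
  stopifnot(tolerance > 0, max_iterations >= 1, rate_upper > 0,
            bound_factor > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, rate_upper = rate_upper,
                 bound_factor = bound_factor, sigma_data = sigma_data,
                 seed = seed),
            class = "fit_options")
}

.bounds <- function(dataset, opts) {
  n <- dataset$n_curves
  span <- opts$bound_factor * max_abs_signal(dataset)
  nms <- .theta_names(n)
  lower <- stats::setNames(rep(-span, length(nms)), nms)
  upper <- stats::setNames(rep(span, length(nms)), nms)
  lower[c("k_on", "k_off", "k_leak")] <- 0
  upper[c("k_on", "k_off", "k_leak")] <- opts$rate_upper
  amp <- grepl("^a_(on|off)_", nms)
  lower[amp] <- 0
  list(lower = lower, upper = upper)
}

#' Data-driven starting values for the global fit
#'
#' Per positive-concentration curve, a provisional observed rate is read off
#' the association phase from its half-rise time, and the observed rates are
#' regressed on concentration: the slope starts k_on and the intercept
#' starts k_off (both floored at small positive values). k_leak starts from
#' the terminal fractional slope of the zero-concentration control's
#' dissociation phase when that carries signal, else at 1e-4 s^-1.
#' Baselines start at the first sample of each phase and amplitudes at the
#' phase signal spans.
#'
#' @param dataset a [bli_dataset()] with at least two distinct
#'   concentrations, at least one nonzero
#' @return a [parameter_vector()] satisfying the default [fit_options()]
#'   bounds
#' @export
initial_guess <- function(dataset) {
  stopifnot(inherits(dataset, "bli_dataset"))
  conc <- concentrations(dataset)
  if (length(unique(conc)) < 2L)
    stop("degenerate design: all curves share one concentration; the observed-rate regression is undefined",
         call. = FALSE)
  if (all(conc == 0))
    stop("degenerate design: no nonzero concentration curve", call. = FALSE)

  # provisional observed rate: a per-curve single-exponential fit to the
  # association phase, a (1 - e^{-k t}) + b, started from the half-rise time
  half_rise_rate <- function(t, y) {
    b <- y[1]
    plateau <- mean(y[t >= stats::quantile(t, 0.9)])
    span <- plateau - b
    if (!is.finite(span) || abs(span) < 1e-12) return(NA_real_)
    idx <- which((y - b) / span >= 0.5)
    if (!length(idx)) return(NA_real_)
    t_half <- max(t[idx[1]], t[2])
    k0 <- log(2) / t_half
    fit <- tryCatch(minpack.lm::nls.lm(
      par = c(a = span, b = b, k = k0),
      lower = c(-Inf, -Inf, 1e-8), upper = c(Inf, Inf, 1e3),
      fn = function(p) y - (p[1] * (1 - exp(-p[3] * t)) + p[2]),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) k0 else unname(stats::coef(fit)[["k"]])
  }

  # single-exponential decay rate of a dissociation phase
  decay_rate <- function(t, y) {
    span <- y[1] - y[length(y)]
    if (!is.finite(span) || abs(span) < 1e-12) return(NA_real_)
    fit <- tryCatch(minpack.lm::nls.lm(
      par = c(a = span, b = y[length(y)], k = 0.01),
      lower = c(-Inf, -Inf, 1e-8), upper = c(Inf, Inf, 1e3),
      fn = function(p) y - (p[1] * exp(-p[3] * t) + p[2]),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) NA_real_ else unname(stats::coef(fit)[["k"]])
  }

  pos <- which(conc > 0)
  kobs <- vapply(pos, function(i) {
    s <- dataset$curves[[i]]
    half_rise_rate(s$assoc_t, s$assoc_y)
  }, numeric(1))
  # drop curves whose rise is unresolved by the sampling interval: their
  # rate estimates are unbounded upward and would wreck the regression
  dt <- vapply(pos, function(i)
    stats::median(diff(dataset$curves[[i]]$assoc_t)), numeric(1))
  ok <- is.finite(kobs) & kobs > 0 & kobs * dt <= 1
  if (sum(ok) < 2L) ok <- is.finite(kobs) & kobs > 0 & kobs * dt <= 5
  if (sum(ok) < 2L) ok <- is.finite(kobs) & kobs > 0
  floor_rate <- 1e-6

  # k_off read directly off the dissociation phases (robust even when the
  # association rises are barely resolved); fall back to the regression
  # intercept below when the dissociation spans carry no signal
  big <- pos[order(conc[pos], decreasing = TRUE)]
  kdis <- vapply(big[seq_len(min(3L, length(big)))], function(i) {
    s <- dataset$curves[[i]]
    decay_rate(s$dissoc_t, s$dissoc_y)
  }, numeric(1))
  k_off_dis <- if (any(is.finite(kdis))) stats::median(kdis[is.finite(kdis)])
               else NA_real_

  if (sum(ok) >= 2L && length(unique(conc[pos][ok])) >= 2L) {
    co <- stats::coef(stats::lm(kobs[ok] ~ conc[pos][ok]))
    k_off0 <- max(if (is.finite(k_off_dis)) k_off_dis else co[[1]],
                  floor_rate)
    k_on0 <- max(co[[2]], floor_rate)
  } else if (any(ok)) {
    i1 <- which(ok)[1]
    k_off0 <- max(if (is.finite(k_off_dis)) k_off_dis else kobs[i1] / 10,
                  floor_rate)
    k_on0 <- max((kobs[i1] - k_off0) / conc[pos][i1], floor_rate)
  } else {
    k_off0 <- max(if (is.finite(k_off_dis)) k_off_dis else 0.01, floor_rate)
    k_on0 <- 0.01
  }
  # the observed-rate slope can collapse when every curve saturates within
  # a few samples; rebuild k_on from the best-resolved curve in that case
  if (k_on0 <= 10 * floor_rate && any(ok)) {
    j <- which.min(kobs[ok] * dt[ok])
    k_on_curve <- (kobs[ok][j] - k_off0) / conc[pos][ok][j]
    if (is.finite(k_on_curve) && k_on_curve > 0) k_on0 <- k_on_curve
  }

  k_leak0 <- 1e-4
  z <- which(conc == 0)
  if (length(z)) {
    s <- dataset$curves[[z[1]]]
    mu <- mean(abs(s$dissoc_y))
    if (is.finite(mu) && mu > 1e-6) {
      sl <- stats::coef(stats::lm(s$dissoc_y ~ s$dissoc_t))[[2]]
      cand <- -sl / mean(s$dissoc_y)
      if (is.finite(cand)) k_leak0 <- min(max(cand, 0), 1e-2)
    }
  }

  nuis <- lapply(dataset$curves, function(s) {
    b_on <- s$assoc_y[1]
    a_on <- max(max(s$assoc_y) - b_on, 0)
    b_off <- s$dissoc_y[length(s$dissoc_y)]
    a_off <- max(s$dissoc_y[1] - b_off, 0)
    curve_nuisance(a_on, b_on, a_off, b_off)
  })
  parameter_vector(kinetic_params(k_on0, k_off0, k_leak0), nuis)
}

#' Global fit of a sensorgram concentration series
#'
#' Fits all curves simultaneously to the binding/unbinding model by bounded
#' Levenberg-Marquardt least squares, with the three rates shared across
#' curves and amplitudes/baselines free per curve. The optimizer accepts
#' only SSE-decreasing steps, so \code{sse_opt <= sse(start)} always holds,
#' and the result is deterministic for a given (dataset, start, options).
#'
#' @param dataset a [bli_dataset()]
#' @param start starting [parameter_vector()]; default [initial_guess()]
#' @param opts a [fit_options()] object
#' @param fixed optional named numeric vector/list of parameters held fixed
#'   at the given values, e.g. \code{c(k_on = 0.05)}; per-curve names use
#'   suffixes \code{a_on_1, b_on_1, ...} in dataset curve order
#' @param fixed_kd optional scalar: hold K_D fixed at this value by
#'   reparameterizing to (k_on, K_D, k_leak) with k_off := k_on * K_D
#'   (used when profiling K_D); cannot be combined with fixing k_off
#' @return an object of class \code{bli_fit} with elements
#'   \code{params_opt}, \code{sse_opt}, \code{residuals}, \code{n_data},
#'   \code{n_params} (free parameters), \code{converged},
#'   \code{n_iterations}, plus bookkeeping (\code{opts}, \code{fixed},
#'   \code{fixed_kd})
#' @export
fit_global <- function(dataset, start = initial_guess(dataset),
                       opts = fit_options(), fixed = NULL, fixed_kd = NULL) {
  stopifnot(inherits(dataset, "bli_dataset"),
            inherits(start, "parameter_vector"),
            inherits(opts, "fit_options"))
  if (length(start$nuisances) != dataset$n_curves)
    stop("start parameter vector does not match dataset curve count",
         call. = FALSE)
  n <- dataset$n_curves
  theta0 <- .pack(start)
  b <- .bounds(dataset, opts)

  fixed <- if (is.null(fixed)) numeric(0) else unlist(fixed)
  if (length(fixed)) {
    bad <- setdiff(names(fixed), names(theta0))
    if (length(bad))
      stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(fixed_kd)) {
    stopifnot(is.numeric(fixed_kd), length(fixed_kd) == 1L, fixed_kd > 0)
    if ("k_off" %in% names(fixed))
      stop("cannot fix both k_off and K_D", call. = FALSE)
    fixed <- c(fixed, k_off = NA_real_) # slot removed from free set below
  }
  free <- setdiff(names(theta0), names(fixed))
  if (!length(free))
    stop("fixing these parameters leaves no free parameters", call. = FALSE)

  expand <- function(p) {
    th <- theta0
    th[names(fixed)] <- fixed
    th[free] <- p
    if (!is.null(fixed_kd)) th[["k_off"]] <- th[["k_on"]] * fixed_kd
    th
  }

  total_iter <- 0L
  converged <- FALSE
  # warm-started nls.lm rounds (per-call iteration cap 1024), stopping when
  # a converged round no longer improves the SSE
  run_lm <- function(par, lower, upper, fn, jac) {
    sse_prev <- Inf
    repeat {
      round_iter <- min(1024L, max(opts$max_iterations - total_iter, 1L))
      res <- minpack.lm::nls.lm(
        par = par, lower = lower, upper = upper, fn = fn, jac = jac,
        control = minpack.lm::nls.lm.control(
          ftol = opts$tolerance, ptol = 1e-14, gtol = 0,
          maxiter = round_iter, maxfev = 100L * (length(par) + 1L) * 10L))
      par <- stats::coef(res)
      total_iter <<- total_iter + max(res$niter, 1L)
      sse_now <- res$deviance
      if (res$info %in% 1:4) {
        converged <<- TRUE
        if (sse_prev - sse_now <=
            max(opts$tolerance, 1e-12) * max(sse_now, 1e-300))
          break
      }
      if (total_iter >= opts$max_iterations) break
      sse_prev <- sse_now
    }
    par
  }

  rate_names <- c("k_on", "k_off", "k_leak")
  check_finite <- function(r, p) {
    if (any(!is.finite(r)))
      stop("non-finite model values at parameters: ",
           paste(sprintf("%s=%.6g", names(p), p), collapse = ", "),
           call. = FALSE)
    r
  }

  if (all(names(fixed) %in% rate_names)) {
    # separable least squares: for fixed rates the model is linear in the
    # per-curve amplitudes and baselines, so profile them out exactly and
    # run Levenberg-Marquardt on the (at most 3) free rates only
    rate_free <- setdiff(rate_names, names(fixed))
    expand_rates <- function(p) {
      k <- theta0[rate_names]
      k[intersect(names(fixed), rate_names)] <-
        fixed[intersect(names(fixed), rate_names)]
      k[rate_free] <- p
      if (!is.null(fixed_kd)) k[["k_off"]] <- k[["k_on"]] * fixed_kd
      k
    }
    lin_theta <- function(k) {
      th <- theta0
      th[rate_names] <- k[rate_names]
      span <- b$upper[[paste0("a_on_", 1L)]]
      for (i in seq_len(n)) {
        s <- dataset$curves[[i]]
        L <- exp(-k[["k_leak"]] * s$assoc_t)
        E <- exp(-(k[["k_on"]] * s$concentration + k[["k_off"]]) * s$assoc_t)
        cf <- .lsq2((1 - E) * L, L, s$assoc_y, span)
        th[[paste0("a_on_", i)]] <- cf[1]; th[[paste0("b_on_", i)]] <- cf[2]
        Ld <- exp(-k[["k_leak"]] * s$dissoc_t)
        D <- exp(-k[["k_off"]] * s$dissoc_t)
        cf <- .lsq2(D * Ld, Ld, s$dissoc_y, span)
        th[[paste0("a_off_", i)]] <- cf[1]; th[[paste0("b_off_", i)]] <- cf[2]
      }
      th
    }
    fn_r <- function(p)
      check_finite(.resid_theta(dataset, lin_theta(expand_rates(p))), p)
    jac_r <- function(p) {
      J <- .jac_theta(dataset, lin_theta(expand_rates(p)))
      if (!is.null(fixed_kd))
        J[, "k_on"] <- J[, "k_on"] + fixed_kd * J[, "k_off"]
      J[, rate_free, drop = FALSE]
    }
    p0 <- pmin(pmax(theta0[rate_free], b$lower[rate_free]),
               b$upper[rate_free])
    p_rates <- run_lm(p0, b$lower[rate_free], b$upper[rate_free], fn_r, jac_r)
    theta0 <- lin_theta(expand_rates(p_rates))  # joint optimum; polish below
  }

  fn <- function(p) check_finite(.resid_theta(dataset, expand(p)), p)
  jac <- function(p) {
    J <- .jac_theta(dataset, expand(p))
    if (!is.null(fixed_kd))  # chain rule for k_off = k_on * K_D
      J[, "k_on"] <- J[, "k_on"] + fixed_kd * J[, "k_off"]
    J[, free, drop = FALSE]
  }
  par <- run_lm(pmin(pmax(theta0[free], b$lower[free]), b$upper[free]),
                b$lower[free], b$upper[free], fn, jac)

  theta_opt <- expand(par)
  r_opt <- .resid_theta(dataset, theta_opt)
  sse_opt <- sum(r_opt * r_opt)
  # monotone-descent guard: never report worse than the start
  r0 <- .resid_theta(dataset, expand(pmin(pmax(theta0[free], b$lower[free]),
                                          b$upper[free])))
  if (sse_opt > sum(r0 * r0)) {
    theta_opt <- expand(theta0[free])
    r_opt <- r0
    sse_opt <- sum(r0 * r0)
  }

  structure(list(params_opt = .unpack(theta_opt, n),
                 theta_opt = theta_opt,
                 sse_opt = sse_opt,
                 residuals = r_opt,
                 n_data = dataset$n_data,
                 n_params = length(free),
                 converged = converged,
                 n_iterations = total_iter,
                 opts = opts, fixed = fixed, fixed_kd = fixed_kd),
            class = "bli_fit")
}

#' @export
print.bli_fit <- function(x, ...) {
  k <- x$params_opt$kin
  cat(sprintf("Global BLI fit: %d free parameters, %d data points\n",
              x$n_params, x$n_data))
  cat(sprintf("  k_on  = %.4g uM^-1 s^-1\n  k_off = %.4g s^-1\n  k_leak = %.4g s^-1\n",
              k$k_on, k$k_off, k$k_leak))
  if (k$k_on > 0) cat(sprintf("  K_D   = %.4g uM\n", k$k_off / k$k_on))
  cat(sprintf("  SSE = %.6g, converged = %s (%d iterations)\n",
              x$sse_opt, x$converged, x$n_iterations))
  invisible(x)
}
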