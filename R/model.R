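#' Kinetic rate parameters for the 1:1 binding model
#'
#' Container for the three rates shared across all curves of a global fit:
#' the association rate constant \code{k_on} (uM^-1 s^-1), the dissociation
#' rate constant \code{k_off} (s^-1), and the probe-leak rate \code{k_leak}
#' (s^-1) modelling the slow loss of His-tagged ligand from the Ni-NTA
#' sensor tip as a multiplicative exponential decay of the whole signal.
#'
#' Units are fixed package-wide: concentrations in uM, time in s, signal in
#' instrument units (nm shift) treated as an arbitrary linear scale.
#'
#' @param k_on association rate constant, uM^-1 s^-1, >= 0
#' @param k_off dissociation rate constant, s^-1, >= 0
#' @param k_leak probe-leak decay rate, s^-1, >= 0 (default 0)
#' @return an object of class \code{kinetic_params}
#' @seealso [equilibrium_kd()], [observed_rate()]
#' @export
#' @examples
#' kp <- kinetic_params(k_on = 0.072, k_off = 0.019)
#' equilibrium_kd(kp) # ~0.26 uM
kinetic_params <- function(k_on, k_off, k_leak = 0) {
  for (nm in c("k_on", "k_off", "k_leak")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
    if (v < 0)
      stop(sprintf("rate '%s' must be >= 0 (got %g)", nm, v), call. = FALSE)
  }
  structure(list(k_on = k_on, k_off = k_off, k_leak = k_leak),
            class = "kinetic_params")
}

#' Per-curve nuisance parameters (amplitudes and baselines)
#'
#' Each sensorgram carries its own association amplitude \code{a_on} (the
#' total signal change due to analyte binding), association baseline
#' \code{b_on}, dissociation amplitude \code{a_off}, and dissociation
#' baseline \code{b_off}. Amplitudes are non-negative; baselines are
#' unrestricted in sign.
#'
#' @param a_on association amplitude, signal units, >= 0
#' @param b_on association baseline, signal units
#' @param a_off dissociation amplitude, signal units, >= 0
#' @param b_off dissociation baseline, signal units
#' @return an object of class \code{curve_nuisance}
#' @export
curve_nuisance <- function(a_on, b_on = 0, a_off = a_on, b_off = 0) {
  for (nm in c("a_on", "b_on", "a_off", "b_off")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (a_on < 0) stop("amplitude 'a_on' must be >= 0", call. = FALSE)
  if (a_off < 0) stop("amplitude 'a_off' must be >= 0", call. = FALSE)
  structure(list(a_on = a_on, b_on = b_on, a_off = a_off, b_off = b_off),
            class = "curve_nuisance")
}

.check_time <- function(t) {
  if (any(!is.finite(t))) stop("time 't' must be finite", call. = FALSE)
  if (any(t < 0)) stop("time 't' must be >= 0", call. = FALSE)
}

#' Association-phase model signal
#'
#' Evaluates the binding-phase model
#' \deqn{y(t) = [a_{on} (1 - e^{-(k_{on} C + k_{off}) t}) + b_{on}]\,
#'       e^{-k_{leak} t}}
#' at phase-local times \code{t} (t = 0 at the start of the phase). The
#' exponential approach to saturation has observed rate
#' \eqn{k_{obs} = k_{on} C + k_{off}} (pseudo-first-order kinetics); the
#' trailing factor models the slow probe leak. Zero-concentration control
#' curves use the same expression (the observed rate reduces to k_off).
#'
#' @param t phase-local time(s), s, >= 0 (vectorized)
#' @param concentration analyte concentration C, uM, >= 0
#' @param kin a [kinetic_params()] object
#' @param nui a [curve_nuisance()] object
#' @return model signal, same length as \code{t}
#' @export
eval_binding <- function(t, concentration, kin, nui) {
  .check_time(t)
  if (concentration < 0)
    stop("'concentration' must be >= 0", call. = FALSE)
  stopifnot(inherits(kin, "kinetic_params"), inherits(nui, "curve_nuisance"))
  kobs <- kin$k_on * concentration + kin$k_off
  (nui$a_on * (1 - exp(-kobs * t)) + nui$b_on) * exp(-kin$k_leak * t)
}

#' Dissociation-phase model signal
#'
#' Evaluates the unbinding-phase model
#' \deqn{y(t) = [a_{off} e^{-k_{off} t} + b_{off}]\, e^{-k_{leak} t}}
#' at phase-local times \code{t} (the clock restarts at 0 at the start of
#' the dissociation phase, and the leak factor uses this phase-local time).
#'
#' @inheritParams eval_binding
#' @return model signal, same length as \code{t}
#' @export
eval_unbinding <- function(t, kin, nui) {
  .check_time(t)
  stopifnot(inherits(kin, "kinetic_params"), inherits(nui, "curve_nuisance"))
  (nui$a_off * exp(-kin$k_off * t) + nui$b_off) * exp(-kin$k_leak * t)
}

#' Observed (apparent) association rate
#'
#' The pseudo-first-order observed rate \eqn{k_{obs} = k_{on} C + k_{off}}:
#' affine in concentration with slope k_on and intercept k_off.
#'
#' @param kin a [kinetic_params()] object
#' @param concentration analyte concentration, uM, >= 0 (vectorized)
#' @return observed rate(s), s^-1
#' @export
observed_rate <- function(kin, concentration) {
  stopifnot(inherits(kin, "kinetic_params"))
  if (any(concentration < 0))
    stop("'concentration' must be >= 0", call. = FALSE)
  kin$k_on * concentration + kin$k_off
}

#' Equilibrium dissociation constant
#'
#' \eqn{K_D = k_{off} / k_{on}} in uM; smaller K_D means tighter binding.
#' Undefined when k_on is zero.
#'
#' @param kin a [kinetic_params()] object
#' @return K_D, uM
#' @export
equilibrium_kd <- function(kin) {
  stopifnot(inherits(kin, "kinetic_params"))
  if (kin$k_on <= 0)
    stop("K_D = k_off/k_on is undefined for k_on = 0", call. = FALSE)
  kin$k_off / kin$k_on
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("Kinetic parameters: k_on = %g uM^-1 s^-1, k_off = %g s^-1, k_leak = %g s^-1\n",
              x$k_on, x$k_off, x$k_leak))
  if (x$k_on > 0)
    cat(sprintf("  K_D = k_off/k_on = %g uM\n", x$k_off / x$k_on))
  invisible(x)
}
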