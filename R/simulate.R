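#' Design of a simulated BLI dilution-series experiment
#'
#' Defaults mirror a typical Octet run: a 7-point two-fold dilution series
#' from 8 uM plus a 0 uM buffer control (8 curves), 300 s association and
#' 300 s dissociation phases sampled at 175 points each, which gives
#' 2 x 175 x 8 = 2800 data points over the series. Noise is additive i.i.d.
#' Gaussian with standard deviation \code{noise_sigma}; the default 0.005
#' signal units is 0.5% of the default saturating amplitude
#' \code{a_max = 1}.
#'
#' @param concentrations analyte concentrations, uM (distinct; may include 0)
#' @param assoc_duration,dissoc_duration phase lengths, s
#' @param samples_per_phase samples per phase (uniform grid incl. t = 0)
#' @param noise_sigma additive Gaussian noise SD, signal units
#' @param a_max saturating association amplitude, signal units
#' @param baseline signal baseline for both phases
#' @param seed integer RNG seed; per-curve noise substreams are derived
#'   from it so adding curves never reshuffles existing curves' noise
#' @return an object of class \code{simulation_design}
#' @export
simulation_design <- function(concentrations = c(8, 4, 2, 1, 0.5, 0.25, 0.125, 0),
                              assoc_duration = 300, dissoc_duration = 300,
                              samples_per_phase = 175L, noise_sigma = 0.005,
                              a_max = 1, baseline = 0, seed = 1L) {
  stopifnot(assoc_duration > 0, dissoc_duration > 0,
            samples_per_phase >= 4L, noise_sigma >= 0, a_max > 0)
  if (anyDuplicated(concentrations))
    stop("concentrations must be distinct", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  structure(list(concentrations = as.numeric(concentrations),
                 assoc_duration = assoc_duration,
                 dissoc_duration = dissoc_duration,
                 samples_per_phase = as.integer(samples_per_phase),
                 noise_sigma = noise_sigma, a_max = a_max,
                 baseline = baseline, seed = as.integer(seed)),
            class = "simulation_design")
}

#' Simulate a single sensorgram
#'
#' Evaluates the binding and unbinding model on uniform phase-local time
#' grids and adds i.i.d. Gaussian noise of SD \code{design$noise_sigma}.
#' Reproducible for a given seed.
#'
#' @param kin [kinetic_params()]
#' @param nui [curve_nuisance()]
#' @param concentration analyte concentration, uM
#' @param design [simulation_design()]
#' @param curve_id label for the curve
#' @param seed optional seed overriding \code{design$seed} (used internally
#'   for per-curve substreams)
#' @return a [sensorgram()]
#' @export
simulate_sensorgram <- function(kin, nui, concentration, design,
                                curve_id = "curve1", seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  ta <- seq(0, design$assoc_duration, length.out = design$samples_per_phase)
  td <- seq(0, design$dissoc_duration, length.out = design$samples_per_phase)
  ya <- eval_binding(ta, concentration, kin, nui)
  yd <- eval_unbinding(td, kin, nui)
  if (design$noise_sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    ya <- ya + stats::rnorm(length(ya), 0, design$noise_sigma)
    yd <- yd + stats::rnorm(length(yd), 0, design$noise_sigma)
  }
  sensorgram(curve_id, concentration, ta, ya, td, yd)
}

#' Simulate a full dilution-series dataset
#'
#' One sensorgram per design concentration. Association amplitudes follow
#' the equilibrium-saturation model \eqn{a_{on} = a_{max} C / (C + K_D)}
#' (0 for the buffer control); with \code{continuity = TRUE} (default) the
#' dissociation amplitude matches the noiseless association signal at the
#' end of the binding phase, otherwise \code{a_off = a_on}. Baselines are
#' the design baseline.
#'
#' @param kin generating [kinetic_params()]; k_on must be positive so K_D
#'   (and hence the saturation amplitudes) are defined
#' @param design [simulation_design()]
#' @param continuity logical; tie a_off to the association endpoint
#' @return a [bli_dataset()]
#' @export
simulate_dataset <- function(kin, design = simulation_design(),
                             continuity = TRUE) {
  stopifnot(inherits(kin, "kinetic_params"),
            inherits(design, "simulation_design"))
  if (kin$k_on <= 0)
    stop("degenerate scenario: saturation amplitudes need k_on > 0",
         call. = FALSE)
  kd <- equilibrium_kd(kin)
  nconc <- length(design$concentrations)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(design$seed)
  curve_seeds <- sample.int(.Machine$integer.max, nconc)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  curves <- lapply(seq_len(nconc), function(i) {
    C <- design$concentrations[i]
    a_on <- if (C > 0) design$a_max * C / (C + kd) else 0
    nui0 <- curve_nuisance(a_on, design$baseline, a_on, design$baseline)
    a_off <- if (continuity) {
      max(eval_binding(design$assoc_duration, C, kin, nui0) - design$baseline, 0)
    } else a_on
    nui <- curve_nuisance(a_on, design$baseline, a_off, design$baseline)
    simulate_sensorgram(kin, nui, C, design,
                        curve_id = sprintf("C%02d_%guM", i, C),
                        seed = curve_seeds[i])
  })
  bli_dataset(curves)
}

#' Kinetic scenario library for the LaM8 OptoNB variant panel
#'
#' Named best-fit rate sets for wild-type LaM8 and the light-switchable
#' LaM8-GG15 / LaM8-AK74 OptoNB variants in their dark (C450V pseudo-dark),
#' lit (450 nm illumination), and pseudo-lit (I532E A536E) states, as
#' measured against mCherry. Each entry carries k_on (uM^-1 s^-1), k_off
#' (s^-1), a default probe-leak rate, and the reported K_D (uM) for
#' cross-checking: k_off/k_on reproduces the reported K_D within printed
#' rounding for every entry.
#'
#' @param k_leak default probe-leak rate applied to every scenario, s^-1
#' @return an object of class \code{scenario_library}: a named list with
#'   elements \code{kin} ([kinetic_params()]), \code{variant},
#'   \code{illumination}, and \code{kd_reported}
#' @export
#' @examples
#' sc <- optonb_scenarios()
#' equilibrium_kd(sc[["LaM8"]]$kin) # ~0.26 uM
optonb_scenarios <- function(k_leak = 5e-4) {
  rows <- list(
    list("LaM8",                "LaM8",      "none",   0.072, 0.019, 0.26),
    list("LaM8-GG15-dark",      "LaM8-GG15", "pseudo-dark (C450V)",
         0.039, 0.021, 0.53),
    list("LaM8-GG15-pseudolit", "LaM8-GG15", "pseudo-lit (I532E A536E)",
         0.038, 0.12, 3.1),
    list("LaM8-GG15-lit",       "LaM8-GG15", "450 nm light",
         0.038, 0.096, 2.5),
    list("LaM8-AK74-dark",      "LaM8-AK74", "pseudo-dark (C450V)",
         0.018, 0.52, 29),
    list("LaM8-AK74-pseudolit", "LaM8-AK74", "pseudo-lit (I532E A536E)",
         0.034, 0.14, 4.1),
    list("LaM8-AK74-lit",       "LaM8-AK74", "450 nm light",
         0.021, 0.16, 7.4))
  out <- lapply(rows, function(r)
    list(kin = kinetic_params(r[[4]], r[[5]], k_leak),
         variant = r[[2]], illumination = r[[3]], kd_reported = r[[6]]))
  names(out) <- vapply(rows, `[[`, character(1), 1)
  structure(out, class = "scenario_library")
}

#' @export
print.scenario_library <- function(x, ...) {
  cat("OptoNB kinetic scenarios:\n")
  for (nm in names(x)) {
    e <- x[[nm]]
    cat(sprintf("  %-22s k_on=%.3g k_off=%.3g  K_D=%.3g uM (reported %.3g)\n",
                nm, e$kin$k_on, e$kin$k_off, equilibrium_kd(e$kin),
                e$kd_reported))
  }
  invisible(x)
}
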