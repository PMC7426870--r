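# shared fixtures: small, fast simulation designs built in code

lam8 <- function() optonb_scenarios()[["LaM8"]]$kin

small_design <- function(seed = 1, noise = 0, samples = 40,
                         concentrations = c(8, 2, 0.5, 0)) {
  simulation_design(concentrations = concentrations,
                    samples_per_phase = samples, noise_sigma = noise,
                    seed = seed)
}

quick_opts <- function(...) fit_options(max_iterations = 2000, ...)

# suppress re-zeroing / progress chatter in tests
op <- options(blifit.verbose = FALSE)
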