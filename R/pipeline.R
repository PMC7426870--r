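## flag parsing: "--key value" pairs into a named list (values as strings)
.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--"))
      stop(sprintf("usage error: expected a --flag, got '%s'", a),
           call. = FALSE)
    key <- substring(a, 3)
    if (i + 1L > length(args))
      stop(sprintf("usage error: flag --%s needs a value", key),
           call. = FALSE)
    out[[key]] <- args[[i + 1L]]
    i <- i + 2L
  }
  out
}

.known_flags <- list(
  simulate = c("scenario", "seed", "out", "noise", "samples", "config"),
  fit      = c("in", "out", "sigma", "config"),
  profile  = c("in", "report", "params", "grid", "alpha", "config"),
  compare  = c("a", "b", "config"))

## merge: defaults < config file (flat YAML keys) < command-line flags
.resolve_config <- function(flags) {
  cfg <- list()
  if (!is.null(flags$config)) {
    if (!file.exists(flags$config))
      stop(sprintf("config file not found: %s", flags$config), call. = FALSE)
    cfg <- yaml::read_yaml(flags$config)
    if (!is.list(cfg)) cfg <- list()
  }
  flags$config <- NULL
  utils::modifyList(cfg, flags)
}

.write_manifest <- function(out_path, command, cfg, seed, inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(command = command, config = cfg, seed = seed,
         version = as.character(utils::packageVersion("blifit")),
         input_md5 = digests),
    paste0(out_path, ".manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
}

.cmd_simulate <- function(cfg) {
  scen_name <- cfg$scenario %||% stop("usage error: simulate needs --scenario",
                                      call. = FALSE)
  out <- cfg$out %||% stop("usage error: simulate needs --out", call. = FALSE)
  lib <- optonb_scenarios()
  if (!scen_name %in% names(lib))
    stop(sprintf("unknown scenario '%s' (available: %s)", scen_name,
                 paste(names(lib), collapse = ", ")), call. = FALSE)
  seed <- as.integer(cfg$seed %||% 1L)
  design <- simulation_design(
    noise_sigma = as.numeric(cfg$noise %||% 0.005),
    samples_per_phase = as.integer(cfg$samples %||% 175L),
    seed = seed)
  ds <- simulate_dataset(lib[[scen_name]]$kin, design)
  write_sensorgrams(ds, out)
  .write_manifest(out, "simulate", cfg, seed)
  bli_log("simulated %d curves (%d points) for scenario %s -> %s",
          ds$n_curves, ds$n_data, scen_name, out)
  0L
}

.cmd_fit <- function(cfg) {
  inp <- cfg[["in"]] %||% stop("usage error: fit needs --in", call. = FALSE)
  out <- cfg$out %||% stop("usage error: fit needs --out", call. = FALSE)
  ds <- read_sensorgrams(inp)
  opts <- fit_options(sigma_data = if (!is.null(cfg$sigma))
    as.numeric(cfg$sigma) else NULL)
  fit <- fit_global(ds, opts = opts)
  rep <- fit_report(list(report_record(basename(inp), fit)),
                    seed = NA_integer_,
                    input_digest = unname(tools::md5sum(inp)))
  write_report(rep, out, format = "json")
  .write_manifest(out, "fit", cfg, NA, inputs = inp)
  bli_log("fit %s: k_on=%.4g k_off=%.4g K_D=%.4g uM (SSE %.4g)", inp,
          fit$params_opt$kin$k_on, fit$params_opt$kin$k_off,
          equilibrium_kd(fit$params_opt$kin), fit$sse_opt)
  0L
}

.cmd_profile <- function(cfg) {
  inp <- cfg[["in"]] %||% stop("usage error: profile needs --in",
                               call. = FALSE)
  out <- cfg$report %||% stop("usage error: profile needs --report",
                              call. = FALSE)
  par_map <- c(kon = "k_on", koff = "k_off", kd = "K_D")
  keys <- tolower(strsplit(cfg$params %||% "kon,koff,kd", ",")[[1]])
  bad <- setdiff(keys, names(par_map))
  if (length(bad))
    stop(sprintf("usage error: unknown parameter(s) '%s' (use kon,koff,kd)",
                 paste(bad, collapse = ",")), call. = FALSE)
  ds <- read_sensorgrams(inp)
  fit <- fit_global(ds)
  cis <- profile_confint(ds, fit, parameters = unname(par_map[keys]),
                         alpha = as.numeric(cfg$alpha %||% 0.05),
                         n_grid = as.integer(cfg$grid %||% 41L))
  rep <- fit_report(list(report_record(basename(inp), fit, cis)),
                    seed = NA_integer_,
                    input_digest = unname(tools::md5sum(inp)))
  write_report(rep, out, format = "json")
  .write_manifest(out, "profile", cfg, NA, inputs = inp)
  for (ci in cis) bli_log("%s = %s", ci$parameter_name,
                          format_estimate(ci$best_value, ci$half_width))
  0L
}

.cmd_compare <- function(cfg) {
  pa <- cfg$a %||% stop("usage error: compare needs --a", call. = FALSE)
  pb <- cfg$b %||% stop("usage error: compare needs --b", call. = FALSE)
  ra <- read_report(pa)
  rb <- read_report(pb)
  if (!length(ra$records) || !length(rb$records))
    stop("compare: both reports need at least one record", call. = FALSE)
  cmp <- compare_states(ra$records[[1]], rb$records[[1]])
  cat(sprintf("K_D a = %.4g uM, K_D b = %.4g uM: %.2f-fold change (%s binds tighter)\n",
              cmp$kd_a, cmp$kd_b, cmp$fold_change,
              switch(cmp$tighter, a = "a", b = "b", equal = "neither")))
  0L
}

#' Run a pipeline command
#'
#' Thin command-layer over the package functions, mirroring the shell
#' entry point in \code{inst/scripts/blifit}:
#' \describe{
#'   \item{simulate}{\code{--scenario NAME --seed INT --out PATH
#'     [--noise SD] [--samples N]}: write a simulated sensorgram CSV}
#'   \item{fit}{\code{--in PATH --out PATH [--sigma SD]}: global fit,
#'     JSON report}
#'   \item{profile}{\code{--in PATH --report PATH [--params kon,koff,kd]
#'     [--grid N] [--alpha A]}: fit plus profile CIs, JSON report}
#'   \item{compare}{\code{--a REPORT --b REPORT}: affinity fold-change}
#' }
#' A YAML config file with the same flat keys may be given as
#' \code{--config PATH}; command-line flags override it. Every output file
#' gets a JSON run manifest (seed, version, config, input digests)
#' alongside it. Identical config and seed produce identical outputs.
#'
#' @param command one of "simulate", "fit", "profile", "compare"
#' @param args character vector of \code{--flag value} pairs
#' @return integer exit status, invisibly: 0 on success, 1 on a stage
#'   error, 2 on a usage error
#' @export
run_pipeline <- function(command, args = character(0)) {
  status <- tryCatch({
    if (!command %in% names(.known_flags))
      stop(sprintf("usage error: unknown command '%s' (use %s)", command,
                   paste(names(.known_flags), collapse = "|")),
           call. = FALSE)
    flags <- .parse_flags(args)
    bad <- setdiff(names(flags), .known_flags[[command]])
    if (length(bad))
      stop(sprintf("usage error: unknown flag(s) for %s: %s", command,
                   paste0("--", bad, collapse = ", ")), call. = FALSE)
    cfg <- .resolve_config(flags)
    switch(command,
           simulate = .cmd_simulate(cfg),
           fit = .cmd_fit(cfg),
           profile = .cmd_profile(cfg),
           compare = .cmd_compare(cfg))
  }, error = function(e) {
    msg <- conditionMessage(e)
    message("[blifit ERROR] ", msg)
    if (grepl("^usage error", msg)) 2L else 1L
  })
  invisible(status)
}
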