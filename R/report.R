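#' Format an estimate as "best +/- half-width"
#'
#' The conventional kinetics-table rendering: the half-width is rounded to
#' one significant digit and the best-fit value to the same decimal place
#' (e.g. 0.26 +/- 0.02, 29 +/- 10).
#'
#' @param best best-fit value
#' @param half_width maximum accepted deviation (may be NA)
#' @return a character string
#' @export
format_estimate <- function(best, half_width = NA) {
  if (!is.finite(half_width) || half_width <= 0)
    return(sprintf("%.3g", best))
  hw <- signif(half_width, 1)
  digits <- max(0, -floor(log10(hw)))
  sprintf("%.*f ± %.*f", digits, round(best, digits), digits, hw)
}

#' Assemble a kinetics fit report
#'
#' One record per variant: rates, K_D, confidence intervals, and fit
#' diagnostics, plus run provenance (seed, software version, input digest).
#'
#' @param records list of records; build each with [report_record()]
#' @param seed integer seed used for the run (or NA)
#' @param input_digest md5 digest of the input file(s) (or NA)
#' @return an object of class \code{fit_report}
#' @export
fit_report <- function(records = list(), seed = NA_integer_,
                       input_digest = NA_character_) {
  structure(list(records = records,
                 seed = seed,
                 version = as.character(utils::packageVersion("blifit")),
                 input_digest = input_digest),
            class = "fit_report")
}

#' Build one report record from a fit (and optionally its CIs)
#'
#' @param variant label for the record
#' @param fit a [fit_global()] result
#' @param cis optional [profile_confint()] result for the same fit
#' @return a named list (one report record)
#' @export
report_record <- function(variant, fit, cis = NULL) {
  stopifnot(inherits(fit, "bli_fit"))
  kin <- fit$params_opt$kin
  rec <- list(variant = variant,
              k_on = kin$k_on, k_off = kin$k_off, k_leak = kin$k_leak,
              kd = equilibrium_kd(kin),
              sse = fit$sse_opt, n_params = fit$n_params,
              n_data = fit$n_data, converged = fit$converged,
              n_iterations = fit$n_iterations)
  ci_fields <- function(ci) {
    if (is.null(ci)) list(half_width = NA_real_, lower = NA_real_,
                          upper = NA_real_, censored_low = NA,
                          censored_high = NA)
    else list(half_width = ci$half_width, lower = ci$lower, upper = ci$upper,
              censored_low = ci$censored_low, censored_high = ci$censored_high)
  }
  for (pn in c("k_on", "k_off", "K_D")) {
    key <- if (pn == "K_D") "kd" else pn
    f <- ci_fields(if (!is.null(cis)) cis[[pn]] else NULL)
    names(f) <- paste0(key, "_", names(f))
    rec <- c(rec, f)
  }
  thr <- if (!is.null(cis)) attr(cis, "threshold") else NULL
  rec$chi2N_threshold <- if (!is.null(thr)) thr$chi2N_threshold else NA_real_
  rec$f_quantile <- if (!is.null(thr)) thr$f_quantile else NA_real_
  rec
}

.report_df <- function(report) {
  if (!length(report$records)) {
    cols <- c("variant", "k_on", "k_off", "k_leak", "kd", "sse", "n_params",
              "n_data", "converged", "n_iterations")
    df <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                        cols))
    return(df)
  }
  do.call(rbind, lapply(report$records, function(r)
    as.data.frame(r[!vapply(r, is.null, logical(1))])))
}

#' Write a fit report to CSV or JSON
#'
#' JSON keeps full precision and all provenance fields; CSV is the flat
#' record table. Serialization is bit-stable for identical inputs.
#'
#' @param report a [fit_report()]
#' @param path output path
#' @param format "csv" or "json" (default: inferred from the extension)
#' @return \code{path}, invisibly
#' @export
write_report <- function(report, path,
                         format = if (grepl("\\.json$", path)) "json" else "csv") {
  stopifnot(inherits(report, "fit_report"))
  format <- match.arg(format, c("csv", "json"))
  if (format == "json") {
    jsonlite::write_json(
      list(records = report$records, seed = report$seed,
           version = report$version, input_digest = report$input_digest),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  } else {
    utils::write.csv(.report_df(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a JSON fit report back
#'
#' @param path a JSON report written by [write_report()]
#' @return a [fit_report()]
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  rep <- fit_report(records = lapply(x$records, function(r)
    lapply(r, function(v) if (is.null(v)) NA else v)),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    input_digest = if (is.null(x$input_digest)) NA_character_
                   else x$input_digest)
  rep$version <- x$version
  rep
}

#' Fold-change in affinity between two states
#'
#' Compares the K_D of two fit-report records (or bare K_D values): returns
#' the ratio weaker / tighter (always >= 1) and which record binds tighter
#' (smaller K_D). E.g. 29 uM vs 7.4 uM gives a ~3.9-fold change with the
#' second state tighter.
#'
#' @param record_a,record_b report records (lists with a \code{kd} field
#'   and optionally \code{variant}) or single positive numbers
#' @return a list with \code{fold_change}, \code{tighter} ("a", "b" or
#'   "equal"), \code{kd_a}, \code{kd_b}
#' @export
compare_states <- function(record_a, record_b) {
  get_kd <- function(r, which) {
    kd <- if (is.numeric(r) && length(r) == 1L) r else r$kd
    if (is.null(kd) || !is.finite(kd) || kd <= 0)
      stop(sprintf("record %s: K_D must be a positive finite number", which),
           call. = FALSE)
    kd
  }
  kd_a <- get_kd(record_a, "a")
  kd_b <- get_kd(record_b, "b")
  list(fold_change = max(kd_a, kd_b) / min(kd_a, kd_b),
       tighter = if (kd_a < kd_b) "a" else if (kd_b < kd_a) "b" else "equal",
       kd_a = kd_a, kd_b = kd_b)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("BLI fit report (v%s, seed %s): %d record(s)\n",
              x$version, x$seed, length(x$records)))
  for (r in x$records) {
    cat(sprintf("  %-22s k_on %s  k_off %s  K_D %s uM\n", r$variant,
                format_estimate(r$k_on, r$k_on_half_width),
                format_estimate(r$k_off, r$k_off_half_width),
                format_estimate(r$kd, r$kd_half_width)))
  }
  invisible(x)
}
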