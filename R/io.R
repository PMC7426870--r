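#' Write a dataset as canonical long-format sensorgram CSV
#'
#' Columns: \code{curve_id}, \code{phase} (association|dissociation),
#' \code{time_s} (phase-local), \code{signal}, \code{concentration_uM}.
#'
#' @param dataset a [bli_dataset()]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_sensorgrams <- function(dataset, path) {
  stopifnot(inherits(dataset, "bli_dataset"))
  df <- do.call(rbind, lapply(dataset$curves, function(s) {
    data.frame(
      curve_id = s$curve_id,
      phase = rep(c("association", "dissociation"),
                  c(length(s$assoc_t), length(s$dissoc_t))),
      time_s = c(s$assoc_t, s$dissoc_t),
      signal = c(s$assoc_y, s$dissoc_y),
      concentration_uM = s$concentration)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sensorgrams from canonical long-format CSV
#'
#' Expects a header naming the five canonical columns (\code{curve_id},
#' \code{phase}, \code{time_s}, \code{signal}, \code{concentration_uM});
#' the header is matched case- and order-insensitively. Each curve must
#' have both phases, times must increase strictly within each
#' (curve, phase) group, and the concentration must be constant within a
#' curve. Files carrying a global (run-wide) clock are re-zeroed to
#' phase-local time, with a note to the log.
#'
#' @param path CSV file path
#' @return a validated [bli_dataset()]
#' @export
read_sensorgrams <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("%s: cannot parse CSV (%s)", path,
                                conditionMessage(e)), call. = FALSE))
  if (nrow(df) == 0)
    stop(sprintf("%s: no data rows", path), call. = FALSE)
  want <- c("curve_id", "phase", "time_s", "signal", "concentration_uM")
  idx <- match(tolower(want), tolower(names(df)))
  if (anyNA(idx))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(want[is.na(idx)], collapse = ", ")), call. = FALSE)
  df <- df[, idx]
  names(df) <- want
  df$phase <- tolower(df$phase)
  bad_phase <- !df$phase %in% c("association", "dissociation")
  if (any(bad_phase))
    stop(sprintf("%s: line %d: unknown phase '%s'", path,
                 which(bad_phase)[1] + 1L, df$phase[which(bad_phase)[1]]),
         call. = FALSE)
  if (any(!is.finite(df$time_s)) || any(!is.finite(df$signal)) ||
      any(!is.finite(df$concentration_uM)))
    stop(sprintf("%s: non-numeric or missing values in time/signal/concentration",
                 path), call. = FALSE)

  curves <- lapply(unique(df$curve_id), function(id) {
    d <- df[df$curve_id == id, ]
    conc <- unique(d$concentration_uM)
    if (length(conc) != 1L)
      stop(sprintf("%s: curve '%s': inconsistent concentration (%s)", path,
                   id, paste(signif(conc, 6), collapse = ", ")),
           call. = FALSE)
    for (ph in c("association", "dissociation"))
      if (!any(d$phase == ph))
        stop(sprintf("%s: curve '%s' lacks the %s phase", path, id, ph),
             call. = FALSE)
    get_phase <- function(ph) {
      p <- d[d$phase == ph, ]
      if (any(diff(p$time_s) <= 0))
        stop(sprintf("%s: curve '%s' %s: times must strictly increase",
                     path, id, ph), call. = FALSE)
      if (p$time_s[1] > 0) {
        bli_log("re-zeroing %s phase of curve '%s' to phase-local time (started at %g s)",
                ph, id, p$time_s[1])
        p$time_s <- p$time_s - p$time_s[1]
      }
      p
    }
    a <- get_phase("association")
    u <- get_phase("dissociation")
    sensorgram(id, conc, a$time_s, a$signal, u$time_s, u$signal)
  })
  bli_dataset(curves)
}
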