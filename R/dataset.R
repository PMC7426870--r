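#' A single BLI sensorgram (one concentration, two phases)
#'
#' One association/dissociation curve pair recorded at a known analyte
#' concentration. Times are phase-local (each phase starts at 0) and must be
#' strictly increasing; each phase needs at least 4 samples.
#'
#' @param curve_id label, unique within a dataset
#' @param concentration analyte concentration, uM, >= 0
#' @param assoc_t,assoc_y association-phase time (s) and signal samples
#' @param dissoc_t,dissoc_y dissociation-phase time (s) and signal samples
#' @return an object of class \code{sensorgram}
#' @export
sensorgram <- function(curve_id, concentration, assoc_t, assoc_y,
                       dissoc_t, dissoc_y) {
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    stop(sprintf("curve '%s': concentration must be a single number >= 0",
                 curve_id), call. = FALSE)
  check_phase <- function(t, y, phase) {
    if (length(t) != length(y))
      stop(sprintf("curve '%s' %s: time and signal lengths differ",
                   curve_id, phase), call. = FALSE)
    if (length(t) < 4L)
      stop(sprintf("curve '%s' %s: needs >= 4 samples (got %d)",
                   curve_id, phase, length(t)), call. = FALSE)
    if (any(!is.finite(t)) || any(!is.finite(y)))
      stop(sprintf("curve '%s' %s: non-finite values", curve_id, phase),
           call. = FALSE)
    if (t[1] < 0 || any(diff(t) <= 0))
      stop(sprintf("curve '%s' %s: times must start >= 0 and strictly increase",
                   curve_id, phase), call. = FALSE)
  }
  check_phase(assoc_t, assoc_y, "association")
  check_phase(dissoc_t, dissoc_y, "dissociation")
  structure(list(curve_id = as.character(curve_id),
                 concentration = concentration,
                 assoc_t = as.numeric(assoc_t), assoc_y = as.numeric(assoc_y),
                 dissoc_t = as.numeric(dissoc_t), dissoc_y = as.numeric(dissoc_y)),
            class = "sensorgram")
}

#' A concentration series of sensorgrams fit jointly
#'
#' @param curves list of [sensorgram()] objects with unique curve_ids;
#'   at least 2 are needed for a global fit
#' @return an object of class \code{bli_dataset} with elements
#'   \code{curves}, \code{n_curves}, and \code{n_data} (the total number of
#'   residual points across both phases of all curves)
#' @export
bli_dataset <- function(curves) {
  if (!is.list(curves) || length(curves) < 2L)
    stop("a global fit needs >= 2 sensorgrams", call. = FALSE)
  if (!all(vapply(curves, inherits, logical(1), "sensorgram")))
    stop("'curves' must be a list of sensorgram objects", call. = FALSE)
  ids <- vapply(curves, `[[`, character(1), "curve_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate curve_id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  n_data <- sum(vapply(curves, function(s)
    length(s$assoc_t) + length(s$dissoc_t), integer(1)))
  structure(list(curves = curves, n_curves = length(curves), n_data = n_data),
            class = "bli_dataset")
}

concentrations <- function(dataset) {
  vapply(dataset$curves, `[[`, numeric(1), "concentration")
}

curve_ids <- function(dataset) {
  vapply(dataset$curves, `[[`, character(1), "curve_id")
}

max_abs_signal <- function(dataset) {
  m <- max(abs(unlist(lapply(dataset$curves, function(s)
    c(s$assoc_y, s$dissoc_y)))))
  if (!is.finite(m) || m == 0) 1 else m
}

#' @export
print.bli_dataset <- function(x, ...) {
  cat(sprintf("BLI dataset: %d curves, %d data points\n", x$n_curves, x$n_data))
  cat("  concentrations (uM):", paste(signif(concentrations(x), 4),
                                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("Sensorgram '%s': C = %g uM, %d assoc + %d dissoc samples\n",
              x$curve_id, x$concentration, length(x$assoc_t), length(x$dissoc_t)))
  invisible(x)
}
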