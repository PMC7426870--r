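## lightweight stderr logging with levels; silenced via
## options(blifit.verbose = FALSE)
bli_log <- function(fmt, ..., level = "INFO") {
  if (isFALSE(getOption("blifit.verbose", TRUE))) return(invisible())
  message(sprintf("[blifit %s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
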