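# Classed conditions so the CLI can map failures onto exit codes:
# input/validation problems -> "icgquant_input_error" (exit 2),
# numerical/state problems  -> "icgquant_compute_error" (exit 3).

abort_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("icgquant_input_error", "icgquant_error")))
}

abort_compute <- function(...) {
  stop(errorCondition(paste0(...), class = c("icgquant_compute_error", "icgquant_error")))
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort_input(name, " must be a single positive finite number")
  invisible(x)
}
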