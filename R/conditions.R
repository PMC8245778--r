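#' @keywords internal
#' @name conditions
#' @title Classed error conditions
#'
#' @description Two condition classes separate "your data is bad"
#' (`vascreen_data_error`, CLI exit code 2) from "your settings are bad"
#' (`vascreen_config_error`, CLI exit code 3). All user-facing validation in
#' the package raises one of the two so callers (and the CLI) can map them
#' deterministically.
NULL

abort_data <- function(msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = NULL),
    class = c("vascreen_data_error", "vascreen_error", "error", "condition")
  ))
}

abort_config <- function(msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = NULL),
    class = c("vascreen_config_error", "vascreen_error", "error", "condition")
  ))
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort_config("'%s' must be a single finite number in [%s, %s]", name, lo, hi)
  }
  invisible(x)
}
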