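#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with the caller's message if cond is not
# a single TRUE.
stopifnot_msg <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Toggle pipeline logging
#'
#' Pipeline stages (reading, simulation, bootstrap) log row counts, dropped
#' records and the RNG seed in use via [message()] when logging is enabled.
#'
#' @param on logical; `TRUE` enables logging for the session.
#' @return The previous setting, invisibly.
#' @export
cea_logging <- function(on = TRUE) {
  old <- getOption("strokecea.verbose", FALSE)
  options(strokecea.verbose = isTRUE(on))
  invisible(old)
}

cea_log <- function(stage, ...) {
  if (isTRUE(getOption("strokecea.verbose", FALSE))) {
    message(sprintf("[%s] %s", stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}

# Draw independent sub-seeds from one master seed without disturbing the
# caller's RNG more than one set.seed call. Kept below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
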