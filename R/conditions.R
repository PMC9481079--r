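# Classed conditions so callers (and the CLI) can distinguish bad input
# from bugs.  Every user-facing failure is an `ls_error`; subclasses mark
# the contract that was broken.

ls_abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "ls_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

ls_format_error     <- function(msg, ...) ls_abort(msg, "ls_format_error", ...)
ls_validation_error <- function(msg, ...) ls_abort(msg, "ls_validation_error", ...)
ls_schedule_error   <- function(msg, ...) ls_abort(msg, "ls_schedule_error", ...)
ls_domain_error     <- function(msg, ...) ls_abort(msg, "ls_domain_error", ...)
ls_saturation_error <- function(msg, ...) ls_abort(msg, "ls_saturation_error", ...)
ls_consistency_error <- function(msg, ...) ls_abort(msg, "ls_consistency_error", ...)
ls_alignment_error  <- function(msg, ...) ls_abort(msg, "ls_alignment_error", ...)
ls_io_error         <- function(msg, ...) ls_abort(msg, "ls_io_error", ...)

# proportions are validated, not silently clipped; `field` names the offender
check_proportion <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    ls_domain_error(sprintf("%s must be a proportion in [0, 1], got %s",
                            field, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# diagnostics go to the message stream only when logging is switched on
# (options(livessaved.verbose = TRUE), or --log-level info in the CLI)
ls_log <- function(fmt, ...) {
  if (isTRUE(getOption("livessaved.verbose", FALSE)))
    message(sprintf(fmt, ...))
  invisible(NULL)
}
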