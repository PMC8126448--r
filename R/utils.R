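# Internal condition helpers: every user-facing failure is a classed error so
# callers (and tests) can distinguish design problems from bad values.

mdnm_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mdnm_error")))
}

design_error  <- function(msg) mdnm_error(msg, "mdnm_design_error")
value_error   <- function(msg) mdnm_error(msg, "mdnm_value_error")
format_error  <- function(msg) mdnm_error(msg, "mdnm_format_error")
config_error  <- function(msg) mdnm_error(msg, "mdnm_config_error")
align_error   <- function(msg) mdnm_error(msg, "mdnm_alignment_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    value_error(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
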