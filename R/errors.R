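# Named condition classes so callers can distinguish failure modes with
# tryCatch(..., pf_length_mismatch = ...) instead of grepping messages.

pf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pf_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' @keywords internal
assert_that <- function(ok, class, msg, ...) {
  if (!isTRUE(ok)) pf_stop(class, msg, ...)
  invisible(TRUE)
}
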