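# Classed conditions so callers (and tests) can distinguish failure modes.

bg_stop <- function(class, msg, ..., call. = FALSE) {
  cond <- structure(
    class = c(class, "bg_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL, ...)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
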