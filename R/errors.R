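# Classed conditions so callers (and tests) can distinguish failure modes.
plsvip_error <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "plsvip_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
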