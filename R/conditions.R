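# Structured error helpers. Every user-facing failure mode raises a
# condition whose class starts with "codonlm_", so callers (and the CLI)
# can dispatch on it.

cl_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "codonlm_error"), call = call))
}

cl_assert <- function(ok, msg, class) {
  if (!isTRUE(ok)) cl_stop(msg, class, call = sys.call(-1))
  invisible(TRUE)
}
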