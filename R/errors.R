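# classed conditions so callers and tests can distinguish failure modes
.stop <- function(class, msg, ...) {
  abort(sprintf(msg, ...), class = paste0("semgadapt_error_", class))
}
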