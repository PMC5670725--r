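# The full-resolution phantom sweep is shared by several acceptance checks;
# run it once per test session.
.sweep_cache <- new.env(parent = emptyenv())

default_sweep <- function() {
  if (is.null(.sweep_cache$sw)) {
    t0 <- proc.time()[["elapsed"]]
    .sweep_cache$sw <- run_phantom_sweep()
    .sweep_cache$elapsed <- proc.time()[["elapsed"]] - t0
  }
  .sweep_cache$sw
}

default_sweep_elapsed <- function() {
  default_sweep()
  .sweep_cache$elapsed
}
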