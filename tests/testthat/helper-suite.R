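# Six-phantom validation suite results, computed once per test session.
suite_results <- function(seed = 1L) {
  cached(paste0("suite_", seed), {
    lapply(phantom_suite_specs(seed), function(sp) {
      suppressWarnings(reconstruct_phantom(sp))
    })
  })
}
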