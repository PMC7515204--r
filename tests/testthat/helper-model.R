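# shared fixtures, computed once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, fn(), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

basal_ss <- function(prx3_total = 62) {
  cached(paste0("basal_", prx3_total),
         function() find_steady_state(prx3_total = prx3_total))
}

table5_sweep <- function() {
  cached("table5", function() perturbation_sweep()$summary)
}
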