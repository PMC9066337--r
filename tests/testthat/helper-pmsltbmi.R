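# Shared fixtures: the synthetic bundle and expected-value runs are expensive
# (~1 s each), so they are computed once per session and memoised here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

test_bundle <- function(seed = 42) {
  memo(paste0("bundle_", seed), generate_bundle(seed))
}

base_run <- function() {
  memo("base_run", run_pmslt(test_bundle()))
}

scenario_run <- function(id) {
  memo(paste0("scenario_", id), run_scenario(test_bundle(), id))
}

lifetime_qalys <- function(run, discount_rate = run$discount_rate) {
  s <- summarize_run(run, horizons = Inf, discount_rate = discount_rate)
  s$qalys_gained
}

lifetime_net_cost <- function(run, discount_rate = run$discount_rate) {
  s <- summarize_run(run, horizons = Inf, discount_rate = discount_rate)
  s$net_cost_nzd
}
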