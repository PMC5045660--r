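# Small shared simulation fixtures, built once per test run.

tiny_config <- function(seed = 101, ...) {
  sim_config(seed = seed,
             n_pairs = c(I = 6, II = 6, III = 6),
             n_udp = 24,
             chromosome_length = 5e5,
             reads_per_mark = 4e4,
             ...)
}

.fixture_env <- new.env(parent = emptyenv())

shared_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_bdp_data(tiny_config())
  .fixture_env$sim
}
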