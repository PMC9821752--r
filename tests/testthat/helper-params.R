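# shared objects built once per test run
ref_params <- nvc_params()

# short stimulated trajectory reused by several conservation/observable tests
ref_sim_long <- simulate_nvc(ref_params, build_paradigm("drew", "long"),
                             seq(0, 75, 0.25), budget = TRUE)

random_state <- function(seed) {
  set.seed(seed)
  rest <- nvc_initial_state(ref_params)
  pmax(rest * exp(rnorm(length(rest), 0, 0.1)), 1e-6)
}
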