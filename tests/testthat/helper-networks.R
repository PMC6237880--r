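# Scaled-down circuit used by unit tests: same architecture and parameter
# ratios as the defaults, smaller populations so a trial costs ~1 ms.
small_config <- function(...) {
  network_config(dg_ensemble_size = 100, ca3_size = 120, ca1_size = 160, ...)
}

# Default Table-1 layer parameters at an arbitrary size.
tbl1_params <- function(n = 100, kwta_frac = 0.1, ...) {
  layer_params(n = n, kwta_frac = kwta_frac, ...)
}

# One trained association: returns (net, stim, problem) after n encoding
# trials of problem `i` in context A.
trained_single <- function(seed = 7, n_trials = 15, i = 1,
                           cfg = small_config()) {
  set.seed(seed)
  stim <- make_experiment_stimuli()
  net <- build_network(cfg)
  set_context(net, "A")
  prob <- stim$list1[[i]]
  for (t in seq_len(n_trials)) {
    run_trial(net, stim$codes[[prob$a]], stim$codes[[prob$b]],
              stim$codes[[c(prob$a, prob$b)[prob$rewarded]]],
              mode = "encode")
  }
  list(net = net, stim = stim, prob = prob)
}
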