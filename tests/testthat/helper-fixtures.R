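# shared small fixtures, built in code at test time

tiny_array <- function(n = 24) make_sensor_array(n)

# two-condition config at desk scale; amplitude 0 gives an exchangeable null
tiny_config <- function(amplitude = 0.6, onset = 100, seed = 1,
                        n_trials = 50, sfreq = 150,
                        window = c(-0.2, 0.5), duration = 300) {
  simulation_config(
    n_subjects = 1, n_trials_per_condition = n_trials,
    conditions = c("angry", "neutral"), sfreq = sfreq,
    epoch_window = window,
    effect_spec = list(list(pair = c("angry", "neutral"), onset = onset,
                            duration = duration, amplitude = amplitude,
                            seed = 201)),
    seed = seed)
}

tiny_epochs <- function(...) {
  simulate_dataset(tiny_config(...), tiny_array())[[1]]$epochs
}

# deterministic 6-point 2-D fixture used for the dual-QP oracle checks
svm_fixture <- function() {
  list(x = matrix(c(1.0, 1.0,
                    2.0, 2.5,
                    1.5, 0.5,
                    -1.0, -1.0,
                    -2.0, -1.5,
                    -0.5, -2.0), ncol = 2, byrow = TRUE),
       y = rep(c("a", "b"), each = 3))
}
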