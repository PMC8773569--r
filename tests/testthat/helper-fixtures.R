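# shared fixtures: small protocols and stimuli used across test files

# activation protocol restricted to the analysis range used throughout
act_protocol <- function() {
  subset_protocol(preset_protocol("activation"), seq(-90, 70, 10))
}

# one short step sweep: hold, test pulse, hold
mini_protocol <- function(v_test = 50, t_hold = 20, t_test = 100,
                          v_hold = -80) {
  voltage_protocol(
    "mini",
    list(rbind(segment("step", v_hold, duration = t_hold),
               segment("step", v_test, duration = t_test),
               segment("step", v_hold, duration = t_hold))),
    sweep_labels = v_test)
}

# a few-sweep step protocol for identification tests
mini_family <- function(v_tests = c(-20, 20, 50), t_hold = 20,
                        t_test = 100) {
  voltage_protocol(
    "mini_family",
    lapply(v_tests, function(v)
      rbind(segment("step", -80, duration = t_hold),
            segment("step", v, duration = t_test),
            segment("step", -80, duration = t_hold))),
    sweep_labels = v_tests)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * abs(expected))
}
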