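Package: kv11sim
Title: Kinetic Models of the Kv1.1 Voltage-Gated Potassium Channel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and comparison of three kinetic formalisms for the
    shaker-related voltage-gated potassium channel Kv1.1 at physiological
    temperature: a temperature-dependent Hodgkin-Huxley model, an 8-state
    hidden Markov (continuous-time Markov chain) model with slow and fast
    inactivation, and a Hammerstein-Wiener block-structured (system
    theory-based) model. Includes the standard patch-clamp voltage protocols
    (activation, deactivation, inactivation, ramp), deterministic and
    stochastic multi-channel simulation, extraction of electrophysiological
    features (conductance-voltage Boltzmann fits, activation, deactivation
    and inactivation time constants, RMSE model comparison), parameter
    identification (prediction-error minimization for Hammerstein-Wiener
    models, particle swarm optimization for Markov rate constants, channel
    count estimation), and a synthetic whole-cell recording generator with
    quality-control filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
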