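test_that("a cell with no noise and no artifacts equals the clean simulation", {
  proto <- mini_family(c(0, 50), t_hold = 10, t_test = 40)
  cell <- generate_cell(hh_params(), proto, noise_sd = 0,
                        spike_amplitude = 0, dt = 0.25, seed = 4)
  expect_equal(cell$traces$current, cell$clean$current)
})

test_that("cells are reproducible from their seed", {
  proto <- mini_protocol(v_test = 40, t_hold = 10, t_test = 40)
  a <- generate_cell(hh_params(), proto, noise_sd = 0.05, dt = 0.25,
                     seed = 42)
  b <- generate_cell(hh_params(), proto, noise_sd = 0.05, dt = 0.25,
                     seed = 42)
  expect_identical(a$traces$current, b$traces$current)
  c2 <- generate_cell(hh_params(), proto, noise_sd = 0.05, dt = 0.25,
                      seed = 43)
  expect_false(identical(a$traces$current, c2$traces$current))
})

test_that("the injected noise has the requested scale", {
  proto <- mini_protocol(v_test = 40, t_hold = 10, t_test = 40)
  cell <- generate_cell(hh_params(), proto, noise_sd = 0.05,
                        spike_amplitude = 0, dt = 0.05, seed = 8)
  resid <- cell$traces$current - cell$clean$current
  n <- length(resid)
  # chi-square bound: sd of the sample sd is about sigma/sqrt(2n)
  expect_lt(abs(stats::sd(resid) - 0.05), 3 * 0.05 / sqrt(2 * n))
})

test_that("capacitive spikes appear at step edges, scaled by step size", {
  proto <- mini_protocol(v_test = 20, t_hold = 10, t_test = 40)
  cell <- generate_cell(hh_params(), proto, noise_sd = 0,
                        spike_amplitude = 1, spike_tau = 0.3, dt = 0.05,
                        seed = 1)
  resid <- cell$traces$current - cell$clean$current
  t <- cell$traces$time
  # onset edge is +100 mV, offset edge is -100 mV
  expect_gt(resid[1, which(t == 10)], 0.5)
  expect_lt(resid[1, which(t == 50)], -0.5)
  expect_equal(max(abs(resid[1, t < 9.9])), 0)
  # amplitude scales with the edge size
  half <- generate_cell(hh_params(), mini_protocol(v_test = -30,
                                                   t_hold = 10,
                                                   t_test = 40),
                        noise_sd = 0, spike_amplitude = 1, dt = 0.05,
                        seed = 1)
  r2 <- half$traces$current - half$clean$current
  expect_equal(r2[1, which(t == 10)] / resid[1, which(t == 10)], 0.5,
               tolerance = 1e-9)
})

test_that("population generation honors the spec distributions", {
  proto <- mini_protocol(v_test = 30, t_hold = 5, t_test = 10)
  pop <- generate_population(hh_params(), proto,
                             population_spec(n_cells = 60, N_c_sigma = 0.3,
                                             noise_sd = 0, seed = 2),
                             dt = 0.5)
  expect_length(pop, 60)

  pop0 <- generate_population(hh_params(), proto,
                              population_spec(n_cells = 5, N_c_sigma = 0,
                                              N_c_median = 2588,
                                              noise_sd = 0, seed = 2),
                              dt = 0.5)
  expect_true(all(vapply(pop0, function(cl) cl$N_c, numeric(1)) == 2588))

  big <- generate_population(hh_params(), proto,
                             population_spec(n_cells = 200,
                                             N_c_median = 2588,
                                             N_c_sigma = 0.3,
                                             noise_sd = 0, seed = 9),
                             dt = 0.5)
  med <- stats::median(vapply(big, function(cl) cl$N_c, numeric(1)))
  expect_lt(abs(med - 2588) / 2588, 0.1)
})

test_that("qc_filter partitions cells by the published seal threshold", {
  proto <- mini_protocol(v_test = 30, t_hold = 5, t_test = 10)
  mk <- function(rseal, seed) generate_cell(hh_params(), proto,
                                            noise_sd = 0, R_seal = rseal,
                                            dt = 0.5, seed = seed)
  cells <- list(mk(500, 1), mk(250, 2), mk(400, 3))
  res <- qc_filter(cells)
  expect_length(res$kept, 2)
  expect_length(res$excluded, 1)
  expect_equal(res$excluded[[1]]$R_seal, 250)
  expect_equal(length(res$kept) + length(res$excluded), length(cells))

  all_pass <- qc_filter(list(mk(500, 4), mk(500, 5)))
  expect_length(all_pass$excluded, 0)
  none_pass <- qc_filter(cells, min_R_seal = 0)
  expect_length(none_pass$excluded, 0)
})

test_that("end-to-end pipeline recovers the generating activation midpoint", {
  # population -> QC -> average -> conductance fit, against the noise-free
  # value computed by the same pipeline
  proto <- act_protocol()
  noise <- 0.002
  pop <- generate_population(hh_params(), proto,
                             population_spec(n_cells = 6, N_c_sigma = 0,
                                             noise_sd = noise,
                                             spike_amplitude = 0,
                                             seed = 12), dt = 0.5)
  kept <- qc_filter(pop)$kept
  avg <- average_cells(kept)
  gv <- conductance_curve(avg, proto)
  f <- fit_boltzmann_activation(gv$V, gv$G_norm)

  clean <- conductance_curve(pop[[1]]$clean, proto)
  f0 <- fit_boltzmann_activation(clean$V, clean$G_norm)
  # noise-induced SE on the midpoint, propagated from the fit
  Vv <- gv$V; Gn <- gv$G_norm
  ref <- stats::nls(Gn ~ 1 / (1 + exp((v_half - Vv) / k)),
                    start = list(v_half = f0$v_half, k = f0$k))
  se <- summary(ref)$coefficients["v_half", "Std. Error"]
  expect_lt(abs(f$v_half - f0$v_half), 3 * se + 0.05)
})
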