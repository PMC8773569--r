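test_that("Boltzmann fits recover exact generating parameters", {
  V <- seq(-80, 60, 10)
  G <- 1 / (1 + exp((-20 - V) / 10))
  f <- fit_boltzmann_activation(V, G)
  expect_true(f$converged)
  expect_equal(f$v_half, -20, tolerance = 1e-6)
  expect_equal(f$k, 10, tolerance = 1e-6)

  I <- 0.2 + (0.95 - 0.2) / (1 + exp((V + 35) / 6))
  fi <- fit_boltzmann_inactivation(V, I, fix_top = FALSE)
  expect_true(fi$converged)
  expect_equal(fi$v_half, -35, tolerance = 1e-6)
  expect_equal(fi$k, 6, tolerance = 1e-6)
  expect_equal(fi$A1, 0.2, tolerance = 1e-6)
  expect_equal(fi$A2, 0.95, tolerance = 1e-6)

  # fixed-top variant on top-normalized data
  I2 <- 0.3 + (1 - 0.3) / (1 + exp((V + 30) / 5))
  fi2 <- fit_boltzmann_inactivation(V, I2)
  expect_equal(fi2$v_half, -30, tolerance = 1e-6)
  expect_equal(fi2$k, 5, tolerance = 1e-6)
  expect_equal(fi2$A2, 1)
})

test_that("Boltzmann fit recovers parameters within 3 SE under seeded noise", {
  set.seed(101)
  V <- seq(-80, 60, 10)
  G <- 1 / (1 + exp((-20 - V) / 10)) + rnorm(length(V), 0, 0.02)
  f <- fit_boltzmann_activation(V, G)
  # independent SE estimate from the same nonlinear regression
  ref <- stats::nls(G ~ 1 / (1 + exp((v_half - V) / k)),
                    start = list(v_half = -20, k = 10))
  se <- summary(ref)$coefficients[, "Std. Error"]
  expect_lt(abs(f$v_half - (-20)), 3 * se[["v_half"]])
  expect_lt(abs(f$k - 10), 3 * se[["k"]])
})

test_that("exponential fits recover exact and noisy generating parameters", {
  t <- seq(0, 8, 0.01)
  y <- 1 - exp(-t / 0.5)
  f <- fit_tau_activation(t, y, onset = 0, peak_time = 8)
  expect_rel_equal(f$tau, 0.5, 1e-4)

  t2 <- seq(0, 600, 0.5)
  y2 <- 3 * exp(-t2 / 100) + 0.4
  f2 <- fit_tau_decay(t2, y2)
  expect_true(f2$converged)
  expect_rel_equal(f2$tau, 100, 1e-4)
  expect_rel_equal(f2$A1, 3, 1e-4)
  expect_rel_equal(f2$A2, 0.4, 1e-3)

  set.seed(7)
  y3 <- y2 + rnorm(length(t2), 0, 0.02)
  f3 <- fit_tau_decay(t2, y3)
  ref <- stats::nls(y3 ~ a * exp(-t2 / tau) + b,
                    start = list(a = 3, tau = 100, b = 0.4))
  se <- summary(ref)$coefficients["tau", "Std. Error"]
  expect_lt(abs(f3$tau - 100), 3 * se)

  flat <- rep(1, 200)
  ff <- fit_tau_decay(seq_len(200), flat)
  expect_false(ff$converged)
})

test_that("degenerate fit inputs are rejected or flagged", {
  expect_error(fit_tau_activation(0:10, 0:10, onset = 0, peak_time = 0),
               "strictly after")
  expect_error(fit_tau_activation(c(0, 1, 2), c(0, 1, 2), onset = 0),
               "5 samples")
  expect_error(fit_boltzmann_activation(1:3, 1:3))
  expect_error(fit_tau_decay(1:3, 1:3), "5 samples")
})

test_that("conductance curve self-normalizes and rises monotonically for HH", {
  proto <- act_protocol()
  tr <- simulate_hh(sample_protocol(proto, 0.1))
  gv <- conductance_curve(tr, proto)
  expect_equal(gv$G_norm[gv$V == 70], 1)
  expect_true(all(diff(gv$G_norm) > 0))
  expect_equal(max(gv$G_norm), 1)
})

test_that("sweeps at the reversal potential are skipped with a warning", {
  proto <- voltage_protocol("ek", lapply(c(-65, 0), function(v)
    rbind(segment("step", -80, duration = 10),
          segment("step", v, duration = 50),
          segment("step", -80, duration = 10))),
    sweep_labels = c(-65, 0))
  tr <- simulate_hh(sample_protocol(proto, 0.1))
  expect_warning(gv <- conductance_curve(tr, proto, normalize_at = 0),
                 "E_K")
  expect_equal(gv$V, 0)
})

test_that("v_max_cond finds the rising-ramp peak voltage", {
  proto <- preset_protocol("ramp")
  st <- sample_protocol(proto, 0.5)
  # linear conductance: current proportional to (V - E_K) peaks at ramp top
  lin <- trace_set(st$time, (st$voltage + 65) * 0.01, voltage = st$voltage,
                   sweep_labels = st$sweep_labels, protocol_name = "ramp")
  expect_equal(v_max_cond(lin, proto), 50)

  # synthetic current peaking at a known mid-ramp voltage
  peak_v <- -20
  bump <- exp(-(st$voltage - peak_v)^2 / 50)
  bump[st$time > 300] <- 0  # restrict to the first excursion
  tr2 <- trace_set(st$time, bump, voltage = st$voltage,
                   sweep_labels = st$sweep_labels, protocol_name = "ramp")
  expect_equal(v_max_cond(tr2, proto), peak_v, tolerance = 1)

  flatp <- voltage_protocol("s", list(segment("step", 0, duration = 10)),
                            sweep_labels = 0)
  stf <- sample_protocol(flatp, 1)
  trf <- trace_set(stf$time, stf$voltage * 0, voltage = stf$voltage,
                   sweep_labels = 0, protocol_name = "s")
  expect_error(v_max_cond(trf, flatp), "rising ramp")
})

test_that("rmse is a symmetric premetric with the expected closed forms", {
  st <- sample_protocol(mini_family(c(0, 40)), 0.5)
  a <- simulate_hh(st)
  expect_equal(rmse_traces(a, a), 0)
  b <- a
  b$current <- a$current + 0.25
  expect_equal(rmse_traces(a, b), 0.25, tolerance = 1e-12)
  expect_equal(rmse_traces(b, a), rmse_traces(a, b))
  set.seed(5)
  sigma <- 0.1
  cc <- a
  cc$current <- a$current + matrix(rnorm(length(a$current), 0, sigma),
                                   nrow(a$current))
  n <- length(a$current)
  expect_lt(abs(rmse_traces(a, cc) - sigma), 3 * sigma / sqrt(n / 2))
  d <- a
  d$current <- a$current[, 1:10]
  expect_error(rmse_traces(a, trace_set(a$time[1:10], d$current,
                                        sweep_labels = a$sweep_labels)),
               "shapes")
})

test_that("normalized rmse uses the 70 mV sweep convention", {
  st <- sample_protocol(mini_family(c(0, 70)), 0.5)
  a <- simulate_hh(st)
  b <- a
  b$current <- 2 * a$current  # pure scale difference
  expect_equal(rmse_traces(a, b, mode = "norm"), 0, tolerance = 1e-12)
  expect_gt(rmse_traces(a, b, mode = "abs"), 0)
})

test_that("the feature table aggregates per-voltage constants coherently", {
  tab <- suppressWarnings(feature_table(list(hh = hh_params()), dt = 0.5))
  taus <- tab[grepl("^tau_inact_.*mV_ms$", tab$parameter), "hh"]
  mean_row <- tab[tab$parameter == "tau_inact_mean_ms", "hh"]
  expect_equal(mean_row, mean(taus, na.rm = TRUE), tolerance = 1e-12)
  expect_true("act_v_half_mV" %in% tab$parameter)

  # a model against itself as reference scores zero RMSE
  st <- sample_protocol(preset_protocol("deactivation"), 0.5)
  ref <- list(deactivation = simulate_hh(st))
  attr(ref$deactivation, "stimulus") <- st
  tab2 <- suppressWarnings(
    feature_table(list(hh = hh_params()), reference = ref, dt = 0.5))
  rmse_rows <- tab2[grepl("^rmse_", tab2$parameter), "hh"]
  expect_true(all(rmse_rows == 0))
})
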