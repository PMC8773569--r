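test_that("rates reproduce the published table at 0 mV and scale exponentially", {
  r0 <- hmm_rates(0)
  expect_equal(r0$alpha, 951.2464)
  expect_equal(r0$beta, 395.7896)
  expect_equal(r0$c, 799720)
  expect_equal(r0$y, 0.0822)
  # one e-fold per alpha2 volts: V = 30 mV = 0.03 V
  expect_equal(hmm_rates(30)$alpha, 951.2464 * exp(1), tolerance = 1e-12)
  expect_equal(hmm_rates(30)$alpha, 2585.8, tolerance = 1e-4)
  # backward rates fall with depolarization
  expect_lt(hmm_rates(50)$beta, r0$beta)
})

test_that("the generator conserves probability and matches the open-state equation", {
  sch <- kv11_scheme()
  for (V in c(-90, -30, 0, 50)) {
    Q <- hmm_generator(V, scheme = sch)
    expect_lt(max(abs(rowSums(Q))), 1e-12 * max(abs(Q)))
    r <- hmm_rates(V)
    # all probability in O: dP_O/dt = -(d + lambda + 2x)
    expect_equal(Q["O", "O"], -(r$d + r$lambda + 2 * r$x),
                 tolerance = 1e-12)
    # inflow terms of the open state
    expect_equal(Q["C4", "O"], r$c)
    expect_equal(Q["IC2", "O"], r$y)
    expect_equal(Q["IN", "O"], r$eta)
  }
})

test_that("scheme validation guards the open-state row and connectivity", {
  ed <- kv11_scheme()$edges
  # drop the O -> IN edge: O row no longer matches the master equation
  bad <- ed[!(ed$from == "O" & ed$to == "IN"), ]
  expect_error(kv11_scheme(bad), "master equation")
  # unknown state
  bad2 <- rbind(ed, data.frame(from = "O", to = "Z9", rate = "x", mult = 1))
  expect_error(kv11_scheme(bad2))
})

test_that("stationary distribution solves t(Q) p = 0 and rests closed", {
  Q <- hmm_generator(-80)
  p <- stationary_distribution(Q)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_lt(max(abs(t(Q) %*% p)) / max(abs(Q)), 1e-9)
  closed <- sum(p[c("C1", "C2", "C3", "C4")])
  expect_gt(closed, 0.5)
  expect_gt(p["C1"], p["O"])
})

test_that("deterministic simulation conserves probability and obeys E_K", {
  st <- sample_protocol(mini_family(c(-20, 50), t_hold = 20, t_test = 80),
                        0.1)
  sim <- simulate_hmm(st)
  for (occ in sim$extra$occupancy) {
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-8)
    expect_true(all(occ >= 0 & occ <= 1 + 1e-12))
  }
  pk <- voltage_protocol("ek", list(
    rbind(segment("step", -65, duration = 10),
          segment("step", -65, duration = 10))), sweep_labels = -65)
  sim2 <- simulate_hmm(sample_protocol(pk, 0.1))
  expect_true(all(sim2$current == 0))
})

test_that("matrix-exponential and stiff-ODE propagation agree", {
  st <- sample_protocol(mini_protocol(v_test = 50, t_hold = 10,
                                      t_test = 50), 0.1)
  a <- simulate_hmm(st, method = "expm")
  b <- simulate_hmm(st, method = "ode")
  expect_lt(max(abs(a$extra$occupancy[[1]] - b$extra$occupancy[[1]])),
            1e-6)
})

test_that("long-time integration converges to the null-space vector", {
  Q <- hmm_generator(-30)
  p_null <- stationary_distribution(Q)
  p_long <- as.numeric(as.matrix(Matrix::expm(t(Q) * 1000)) %*%
                         rep(1 / 8, 8))
  expect_lt(max(abs(p_long - p_null)), 1e-6)
})

test_that("stochastic simulation is seed-reproducible and converges to the master equation", {
  st <- sample_protocol(mini_protocol(v_test = 50, t_hold = 20,
                                      t_test = 150), 0.25)
  s1 <- simulate_hmm_stochastic(st, n_channels = 500, seed = 42)
  s2 <- simulate_hmm_stochastic(st, n_channels = 500, seed = 42)
  expect_identical(s1$current, s2$current)
  s3 <- simulate_hmm_stochastic(st, n_channels = 500, seed = 43)
  expect_false(identical(s1$current, s3$current))

  det <- simulate_hmm(st)
  sto <- simulate_hmm_stochastic(st, n_channels = 2000, seed = 7)
  po_det <- det$extra$occupancy[[1]][, "O"]
  po_sto <- sto$extra$occupancy[[1]][, "O"]
  check_at <- vapply(c(30, 60, 100, 150), function(tt)
    which.min(abs(st$time - tt)), integer(1))
  for (j in check_at) {
    se <- sqrt(po_det[j] * (1 - po_det[j]) / 2000)
    expect_lt(abs(po_sto[j] - po_det[j]), 3 * se + 1e-9)
  }
})

test_that("a single channel's long-run state frequencies are ergodic", {
  p <- voltage_protocol("hold", list(segment("step", -20, duration = 4000)),
                        sweep_labels = -20)
  st <- sample_protocol(p, 1)
  sim <- simulate_hmm_stochastic(st, n_channels = 1, seed = 11)
  freq <- colMeans(sim$extra$occupancy[[1]])
  stat <- stationary_distribution(hmm_generator(-20))
  expect_lt(max(abs(freq - stat)), 0.12)
})

test_that("model bundle round-trips through JSON", {
  path <- tempfile(fileext = ".json")
  m <- hmm_model()
  write_hmm_model(m, path)
  m2 <- read_hmm_model(path)
  expect_equal(unclass(m2$params), unclass(m$params))
  st <- sample_protocol(mini_protocol(), 0.5)
  expect_equal(simulate_hmm(st, m2$params, m2$scheme)$current,
               simulate_hmm(st, m$params, m$scheme)$current)
})
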