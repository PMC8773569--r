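test_that("the published Kv1.1 cascade has the printed structure", {
  m <- kv11_hw_model()
  expect_equal(length(m$linear$num), 3)
  expect_equal(length(m$linear$den), 4)
  expect_equal(hw_dc_gain(m), -6.268e8 / 1.596e9)
  expect_equal(hw_dc_gain(m), -0.3927, tolerance = 1e-4)
  p <- hw_poles(m)
  expect_true(p$stable)
  expect_true(all(Re(p$poles) < 0))
  expect_equal(m$input_nl$slopes, c(1.2, 0.2, 0.1))
  expect_equal(m$output_nl$slopes, c(-0.3, -0.1, -0.01))
})

test_that("piecewise maps switch gains by region with right-closed ties", {
  id <- piecewise_linear(c(1, 1, 1), c(-1, 1))
  x <- seq(-3, 3, 0.5)
  expect_equal(apply_piecewise(x, id), x)
  g2 <- piecewise_linear(2)
  expect_equal(apply_piecewise(x, g2), 2 * x)
  m <- kv11_hw_model()
  expect_equal(apply_piecewise(10, m$input_nl), 1.2 * 10)
  pw <- piecewise_linear(c(1, 5), 2)
  expect_equal(apply_piecewise(c(1.999, 2, 2.001), pw),
               c(1.999, 10, 10.005))
  # continuous mode offset-matches the pieces
  pwc <- piecewise_linear(c(1, 5), 2, continuous = TRUE)
  y <- apply_piecewise(c(2 - 1e-9, 2 + 1e-9), pwc)
  expect_lt(abs(diff(y)), 1e-6)
})

test_that("pole computation handles the reference cases", {
  triple <- transfer_function(1, c(1, 3, 3, 1))
  p <- hw_poles(triple)
  expect_equal(sort(Re(p$poles)), rep(-1, 3), tolerance = 1e-6)
  expect_true(p$stable)
  unstable <- transfer_function(1, c(1, 0, -1, 0))
  expect_false(hw_poles(unstable)$stable)
})

test_that("the linear block obeys zero-input, superposition and time invariance", {
  tf <- transfer_function(c(2, 10), c(1, 3, 2))
  zero <- voltage_protocol("z", list(segment("step", 0, duration = 50)),
                           sweep_labels = 0)
  m_id <- hw_model(piecewise_linear(1), tf, piecewise_linear(1))
  st <- sample_protocol(zero, 0.5)
  expect_true(all(simulate_hw(st, m_id)$current == 0))

  step1 <- voltage_protocol("s", list(
    rbind(segment("step", 0, duration = 10),
          segment("step", 1, duration = 100))), sweep_labels = 1)
  step2 <- voltage_protocol("s2", list(
    rbind(segment("step", 0, duration = 10),
          segment("step", 2, duration = 100))), sweep_labels = 2)
  y1 <- simulate_hw(sample_protocol(step1, 0.1), m_id)$current
  y2 <- simulate_hw(sample_protocol(step2, 0.1), m_id)$current
  expect_equal(2 * y1, y2, tolerance = 1e-10)

  # shifting the input shifts the output identically
  stepA <- voltage_protocol("a", list(
    rbind(segment("step", 0, duration = 10),
          segment("step", 1, duration = 110))), sweep_labels = 1)
  stepB <- voltage_protocol("b", list(
    rbind(segment("step", 0, duration = 40),
          segment("step", 1, duration = 80))), sweep_labels = 1)
  ya <- simulate_hw(sample_protocol(stepA, 0.1), m_id)$current[1, ]
  yb <- simulate_hw(sample_protocol(stepB, 0.1), m_id)$current[1, ]
  shift <- 300  # 30 ms / 0.1 ms
  expect_equal(yb[(shift + 1):1201], ya[1:(1201 - shift)],
               tolerance = 1e-10)
})

test_that("ZOH simulation matches the partial-fraction step response", {
  # well-separated poles, on the published model's time scale
  tfs <- list(transfer_function(c(2, 10), c(1, 3, 2)),
              kv11_hw_model()$linear)
  for (tf in tfs) {
    step <- voltage_protocol("s", list(
      rbind(segment("step", 0, duration = 1),
            segment("step", 5, duration = 49))), sweep_labels = 5)
    st <- sample_protocol(step, 0.05)
    m <- hw_model(piecewise_linear(1), tf, piecewise_linear(1))
    y <- simulate_hw(st, m)$current[1, ]
    idx <- st$time >= 1
    t_s <- (st$time[idx] - 1) * 1e-3
    oracle <- tf_step_response(tf, t_s, amp = 5)
    scale <- max(abs(oracle))
    expect_lt(max(abs(y[idx] - oracle)) / scale, 1e-6)
  }
})

test_that("a long simulation reaches the DC gain (final-value theorem)", {
  tf <- kv11_hw_model()$linear
  # slowest pole of the published cubic is ~ -3.9 1/s: hold 2 s
  step <- voltage_protocol("s", list(
    rbind(segment("step", 0, duration = 10),
          segment("step", 10, duration = 1990))), sweep_labels = 10)
  st <- sample_protocol(step, 1)
  m <- hw_model(piecewise_linear(1), tf, piecewise_linear(1))
  y <- simulate_hw(st, m)$current[1, ]
  expect_rel_equal(y[length(y)], hw_dc_gain(tf) * 10, 5e-3)
})

test_that("identity nonlinearities reduce the cascade to the linear block", {
  tf <- transfer_function(c(1, 4), c(1, 2, 3))
  m_id <- hw_model(piecewise_linear(1), tf, piecewise_linear(1))
  m_pw <- hw_model(piecewise_linear(c(1, 1), 0.5), tf,
                   piecewise_linear(c(1, 1), -2))
  st <- sample_protocol(mini_protocol(v_test = -60, t_hold = 5,
                                      t_test = 40), 0.5)
  expect_equal(simulate_hw(st, m_pw)$current,
               simulate_hw(st, m_id)$current, tolerance = 1e-12)
})

test_that("an unstable model triggers a warning", {
  m <- hw_model(piecewise_linear(1), transfer_function(1, c(1, 0, -1, 0)),
                piecewise_linear(1))
  st <- sample_protocol(mini_protocol(v_test = -70, t_hold = 1,
                                      t_test = 5), 0.5)
  expect_warning(simulate_hw(st, m), "pole")
})

test_that("models round-trip through JSON", {
  path <- tempfile(fileext = ".json")
  m <- kv11_hw_model()
  write_hw_model(m, path)
  m2 <- read_hw_model(path)
  expect_equal(m2$linear, m$linear)
  expect_equal(m2$input_nl$slopes, m$input_nl$slopes)
  expect_equal(m2$output_nl$breakpoints, m$output_nl$breakpoints)
})
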