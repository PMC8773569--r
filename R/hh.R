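#' Hodgkin-Huxley Kv1.1 model parameters
#'
#' The published temperature-dependent Hodgkin-Huxley description of the
#' Kv1.1 current, `I = g * m^p * h^q * (V - E_K)`, with a single activation
#' gate m and a single inactivation gate h (p = q = 1). The steady-state
#' activation `m_inf(V)` is a rising Boltzmann; the steady-state availability
#' `h_inf(V)` is a falling Boltzmann with a temperature-dependent
#' non-inactivating floor; both time constants carry Q10-style temperature
#' scaling calibrated between 15 and 35 degC. All defaults are the published
#' Kv1.1 values; the model was fitted to normalized currents, so the default
#' maximal conductance is 1 (dimensionless).
#'
#' @param T_C Temperature in degrees Celsius (default 35).
#' @param g_bar Maximal conductance scale (default 1, normalized units).
#' @param E_K Reversal potential in mV (default -65).
#' @param p,q Gate exponents (defaults 1).
#' @param m_inf `list(v_half, slope)` of the activation Boltzmann (mV).
#' @param h_inf `list(v_half, slope, A_coeff, A_offset)`: availability
#'   Boltzmann midpoint/slope (mV) and the linear temperature law
#'   `A = A_coeff * T_C - A_offset` for the inactivating fraction.
#' @param tau_m Named list of activation time-constant parameters:
#'   two sigmoid components blended by a switching sigmoid, divided by a
#'   voltage- and temperature-dependent Q10 factor (see vignette).
#' @param tau_h Named list `A, B, c, d, q10_base` for the inactivation time
#'   constant `(A + B / (1 + exp((V - c)/d))) / q10_base^((T_C - 25)/10)`.
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(T_C = 35, g_bar = 1, E_K = -65, p = 1, q = 1,
                      m_inf = list(v_half = -14.16, slope = 10.15),
                      h_inf = list(v_half = -31.0, slope = 5.256,
                                   A_coeff = 0.032, A_offset = 0.365),
                      tau_m = list(scale = 7.54, v_decay = 379.7,
                                   t_decay = 35.66, switch_v = -46.7,
                                   switch_slope = 3, amp1 = 52.7,
                                   v1_half = -49.87, slope1 = 5.0,
                                   amp2 = 15.98, v2_half = -41.64,
                                   slope2 = 24.99, offset = 0.9),
                      tau_h = list(A = 86.86, B = 408.78, c = -13.6,
                                   d = 7.46, q10_base = 2.7)) {
  stopifnot(m_inf$slope != 0, h_inf$slope != 0, tau_h$q10_base > 0,
            p >= 0, q >= 0)
  structure(list(T_C = T_C, g_bar = g_bar, E_K = E_K, p = p, q = q,
                 m_inf = m_inf, h_inf = h_inf, tau_m = tau_m,
                 tau_h = tau_h),
            class = "hh_params")
}

#' @export
print.hh_params <- function(x, ...) {
  cat(sprintf(paste0("<hh_params> Kv1.1 Hodgkin-Huxley model at %g degC\n",
                     "  I = %g * m^%g * h^%g * (V - (%g mV))\n",
                     "  m_inf: V1/2 = %g mV, k = %g mV\n",
                     "  h_inf: V1/2 = %g mV, k = %g mV, A(T) = %g*T - %g\n"),
              x$T_C, x$g_bar, x$p, x$q, x$E_K, x$m_inf$v_half,
              x$m_inf$slope, x$h_inf$v_half, x$h_inf$slope,
              x$h_inf$A_coeff, x$h_inf$A_offset))
  invisible(x)
}

#' Steady-state gating variables of the Hodgkin-Huxley Kv1.1 model
#'
#' @param V Voltage(s) in mV.
#' @param params An [hh_params()] object.
#' @return List with vectors `m_inf` and `h_inf` in [0, 1].
#' @export
hh_steady_state <- function(V, params = hh_params()) {
  stopifnot(all(is.finite(V)))
  m <- 1 / (1 + exp(-(V - params$m_inf$v_half) / params$m_inf$slope))
  A <- params$h_inf$A_coeff * params$T_C - params$h_inf$A_offset
  if (A < 0 || A > 1)
    warning("inactivating fraction A = ", signif(A, 4),
            " lies outside [0, 1]; the model is extrapolated beyond its ",
            "15-35 degC calibration range")
  h <- (1 - A) + A / (1 + exp((V - params$h_inf$v_half) /
                                params$h_inf$slope))
  list(m_inf = m, h_inf = h)
}

#' Voltage-dependent time constants of the Hodgkin-Huxley Kv1.1 model
#'
#' @inheritParams hh_steady_state
#' @return List with vectors `tau_m` and `tau_h` in ms (both > 0).
#' @export
hh_time_constants <- function(V, params = hh_params()) {
  stopifnot(all(is.finite(V)))
  T_C <- params$T_C
  tm <- params$tau_m
  sw <- 1 / (1 + exp((V - tm$switch_v) / tm$switch_slope))
  sig1 <- sw * tm$amp1 / (1 + exp(-(V - tm$v1_half) / tm$slope1))
  sig2 <- (1 - sw) *
    (tm$offset + (tm$amp2 - tm$offset) /
       (1 + exp((V - tm$v2_half) / tm$slope2)))
  m_q10 <- (tm$scale * exp(-V / tm$v_decay) *
              exp(-T_C / tm$t_decay))^((T_C - 25) / 10)
  th <- params$tau_h
  h_q10 <- th$q10_base^((T_C - 25) / 10)
  list(tau_m = (sig1 + sig2) / m_q10,
       tau_h = (th$A + th$B / (1 + exp((V - th$c) / th$d))) / h_q10)
}

#' Simulate the Hodgkin-Huxley Kv1.1 model under a sampled stimulus
#'
#' Integrates `dm/dt = (m_inf - m)/tau_m`, `dh/dt = (h_inf - h)/tau_h` per
#' sweep and returns the current `I = g * m^p * h^q * (V - E_K)` together
#' with the gate trajectories. Gates start at the steady state of the first
#' sample's voltage (the experimental holding level).
#'
#' @param stimulus A [sample_protocol()] result.
#' @param params An [hh_params()] object.
#' @param method `"exact"` (default) advances each gate with the exact
#'   exponential relaxation for the voltage held over each sample interval;
#'   this is exact for step protocols and a piecewise-constant approximation
#'   at resolution `dt` for ramps. `"ode"` uses a stiff adaptive solver
#'   (deSolve::lsoda) with linear voltage interpolation, as a general
#'   fallback and cross-check.
#' @return A [trace_set()] with `extra = list(m = , h = )` gate matrices.
#' @export
simulate_hh <- function(stimulus, params = hh_params(),
                        method = c("exact", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(stimulus, "sampled_stimulus"))
  V <- stimulus$voltage
  n <- ncol(V)
  dt <- stimulus$dt
  cur <- m_mat <- h_mat <- matrix(NA_real_, nrow(V), n)
  warned <- FALSE
  for (i in seq_len(nrow(V))) {
    v <- V[i, ]
    ss0 <- hh_steady_state(v[1], params)
    if (method == "exact") {
      ss <- hh_steady_state(v, params)
      tc <- hh_time_constants(v, params)
      # the exponential update is exact while the voltage is constant, so
      # dt only limits accuracy where the voltage changes within a segment
      # (ramps): warn there if dt is coarse relative to the fastest gate
      chg <- diff(v) != 0
      ramp_like <- any(chg[-1] & chg[-length(chg)])
      if (!warned && ramp_like && dt > min(tc$tau_m) / 2) {
        warning("dt = ", dt, " ms is coarse relative to the fastest ",
                "activation time constant (", signif(min(tc$tau_m), 3),
                " ms) on a ramp stimulus; consider a smaller dt")
        warned <- TRUE
      }
      em <- exp(-dt / tc$tau_m)
      eh <- exp(-dt / tc$tau_h)
      m <- h <- numeric(n)
      m[1] <- ss0$m_inf
      h[1] <- ss0$h_inf
      # gate value at sample j+1 from relaxation toward the target at the
      # voltage held over [t_j, t_j+1)
      for (j in seq_len(n - 1L)) {
        m[j + 1L] <- ss$m_inf[j] - (ss$m_inf[j] - m[j]) * em[j]
        h[j + 1L] <- ss$h_inf[j] - (ss$h_inf[j] - h[j]) * eh[j]
      }
    } else {
      # left-constant hold matches the half-open segment convention of
      # the exact updater
      vfun <- stats::approxfun(stimulus$time, v, method = "constant",
                               f = 0, rule = 2)
      rhs <- function(t, y, parms) {
        vv <- vfun(t)
        ss <- hh_steady_state(vv, params)
        tc <- hh_time_constants(vv, params)
        list(c((ss$m_inf - y[1]) / tc$tau_m, (ss$h_inf - y[2]) / tc$tau_h))
      }
      sol <- deSolve::lsoda(c(m = ss0$m_inf, h = ss0$h_inf), stimulus$time,
                            rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
      m <- sol[, "m"]
      h <- sol[, "h"]
    }
    m_mat[i, ] <- m
    h_mat[i, ] <- h
    cur[i, ] <- params$g_bar * m^params$p * h^params$q * (v - params$E_K)
  }
  trace_set(stimulus$time, cur, voltage = V,
            sweep_labels = stimulus$sweep_labels,
            unit = if (params$g_bar == 1) "norm" else "nA",
            protocol_name = stimulus$protocol_name,
            extra = list(m = m_mat, h = h_mat))
}

#' Write / read Hodgkin-Huxley parameters as JSON
#' @param params An [hh_params()] object.
#' @param path File path.
#' @return `read_hh_params` returns an [hh_params()] object.
#' @export
write_hh_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_hh_params
#' @export
read_hh_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(hh_params, c(obj[c("T_C", "g_bar", "E_K", "p", "q")],
                       list(m_inf = as.list(obj$m_inf),
                            h_inf = as.list(obj$h_inf),
                            tau_m = as.list(obj$tau_m),
                            tau_h = as.list(obj$tau_h))))
}
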