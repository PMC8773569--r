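#' Peak-conductance curve from an activation-style trace set
#'
#' For each sweep, the peak current within the test segment is converted to
#' a conductance `G = I_peak / (V - E_K)` and normalized by the conductance
#' at the `normalize_at` sweep (the published convention normalizes at the
#' +70 mV step). A blanking interval after the step edge is excluded from
#' the peak search so capacitive artifacts in recorded data do not
#' contaminate the peak.
#'
#' @param traces A [trace_set()].
#' @param protocol The generating [voltage_protocol()] (used to locate the
#'   test segment in time).
#' @param E_K Reversal potential (mV).
#' @param segment_index Which segment of each sweep is the test pulse
#'   (default 2: holding, test, re-pulse).
#' @param blank Blanking interval after the segment edge excluded from the
#'   peak search (ms, default 0.5).
#' @param normalize_at Sweep label whose conductance defines `G_max`
#'   (default 70). If that sweep is absent, the maximum G is used.
#' @return `data.frame` with columns `V`, `G`, `G_norm` (sweeps at
#'   `V == E_K` are dropped with a warning).
#' @export
conductance_curve <- function(traces, protocol, E_K = -65,
                              segment_index = 2, blank = 0.5,
                              normalize_at = 70) {
  stopifnot(inherits(traces, "trace_set"),
            inherits(protocol, "voltage_protocol"))
  V <- traces$sweep_labels
  G <- vapply(seq_along(V), function(i) {
    sw <- protocol$sweeps[[i]]
    t0 <- c(0, cumsum(sw$duration))[segment_index]
    t1 <- cumsum(sw$duration)[segment_index]
    # right boundary excluded: that sample already belongs to the next
    # segment (half-open segment convention)
    idx <- traces$time >= t0 + blank & traces$time < t1 - 1e-9
    y <- traces$current[i, idx]
    pk <- y[which.max(abs(y))]
    pk / (V[i] - E_K)
  }, numeric(1))
  keep <- V != E_K
  if (!all(keep))
    warning("dropping sweep(s) at V == E_K (conductance undefined): ",
            paste(V[!keep], collapse = ", "))
  V <- V[keep]; G <- G[keep]
  gmax <- if (normalize_at %in% V) G[V == normalize_at] else max(G)
  data.frame(V = V, G = G, G_norm = G / gmax)
}

new_boltzmann_fit <- function(v_half, k, A1, A2, rss, converged) {
  structure(list(v_half = v_half, k = k, A1 = A1, A2 = A2, rss = rss,
                 converged = converged), class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("<boltzmann_fit> V1/2 = %.4g mV, k = %.4g mV (A1 = %.4g, A2 = %.4g), rss = %.3g%s\n",
              x$v_half, x$k, x$A1, x$A2, x$rss,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

nls_or_na <- function(expr) {
  f <- try(suppressWarnings(expr), silent = TRUE)
  if (inherits(f, "try-error")) NULL else f
}

#' Boltzmann fit of a normalized conductance-voltage curve
#'
#' Least-squares fit of `G/Gmax = 1 / (1 + exp((V_half - V)/k))`, the
#' standard rising Boltzmann for channel activation.
#'
#' @param V Voltages (mV), at least 4 points.
#' @param G Normalized conductances.
#' @return A `boltzmann_fit` with `v_half`, `k` (mV), `rss`, `converged`.
#' @export
fit_boltzmann_activation <- function(V, G) {
  stopifnot(length(V) == length(G), length(V) >= 4)
  v0 <- V[which.min(abs(G - 0.5))]
  starts <- list(list(v_half = v0, k = 10),
                 list(v_half = v0 - 15, k = 5),
                 list(v_half = v0 + 15, k = 20))
  best <- NULL
  for (st in starts) {
    f <- nls_or_na(minpack.lm::nlsLM(
      G ~ 1 / (1 + exp((v_half - V) / k)), start = st,
      control = minpack.lm::nls.lm.control(maxiter = 500)))
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(f), rss = rss)
  }
  if (is.null(best))
    return(new_boltzmann_fit(NA_real_, NA_real_, 0, 1, NA_real_, FALSE))
  new_boltzmann_fit(best$coef[["v_half"]], best$coef[["k"]], 0, 1,
                    best$rss, TRUE)
}

#' Boltzmann fit of a steady-state inactivation (availability) curve
#'
#' Fits `I/Imax = A1 + (A2 - A1) / (1 + exp((V - V_half)/k))` to normalized
#' test-pulse peak currents. By default the hyperpolarized plateau `A2` is
#' fixed at 1 (the curve is normalized to its maximum), which is the
#' published analysis convention; set `fix_top = FALSE` for the free
#' four-parameter fit.
#'
#' @param V Conditioning voltages (mV), at least 5 points.
#' @param I Normalized peak currents.
#' @param fix_top Fix `A2 = 1` (default `TRUE`).
#' @return A `boltzmann_fit` with `v_half`, `k`, `A1`, `A2`.
#' @export
fit_boltzmann_inactivation <- function(V, I, fix_top = TRUE) {
  stopifnot(length(V) == length(I), length(V) >= 5)
  v0 <- V[which.min(abs(I - (max(I) + min(I)) / 2))]
  starts <- list(list(v_half = v0, k = 5), list(v_half = v0 - 10, k = 10),
                 list(v_half = v0 + 10, k = 3))
  best <- NULL
  for (st in starts) {
    f <- if (fix_top)
      nls_or_na(minpack.lm::nlsLM(
        I ~ A1 + (1 - A1) / (1 + exp((V - v_half) / k)),
        start = c(list(A1 = min(I)), st),
        control = minpack.lm::nls.lm.control(maxiter = 500)))
    else
      nls_or_na(minpack.lm::nlsLM(
        I ~ A1 + (A2 - A1) / (1 + exp((V - v_half) / k)),
        start = c(list(A1 = min(I), A2 = max(I)), st),
        control = minpack.lm::nls.lm.control(maxiter = 500)))
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = stats::coef(f), rss = rss)
  }
  if (is.null(best))
    return(new_boltzmann_fit(NA_real_, NA_real_, NA_real_, NA_real_,
                             NA_real_, FALSE))
  co <- best$coef
  new_boltzmann_fit(co[["v_half"]], co[["k"]], co[["A1"]],
                    if (fix_top) 1 else co[["A2"]], best$rss, TRUE)
}

new_exp_fit <- function(tau, A1, A2, rss, converged) {
  structure(list(tau = tau, A1 = A1, A2 = A2, rss = rss,
                 converged = converged), class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> tau = %.4g ms (A1 = %.4g, A2 = %.4g), rss = %.3g%s\n",
              x$tau, x$A1, x$A2, x$rss,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Rising-exponential fit of the activation time course
#'
#' Fits `y = 1 - exp(-t/tau)` to the peak-normalized current between
#' stimulus onset and the current peak.
#'
#' @param time Time axis (ms).
#' @param current Current trace (same length).
#' @param onset Stimulus onset time (ms).
#' @param peak_time Optional end of the fit window; default is the time of
#'   the absolute peak after onset.
#' @return An `exp_fit` (with `A1 = 1`, `A2 = 0` by construction).
#' @export
fit_tau_activation <- function(time, current, onset, peak_time = NULL) {
  idx0 <- which(time >= onset)
  if (is.null(peak_time))
    peak_time <- time[idx0][which.max(abs(current[idx0]))]
  if (peak_time <= onset) stop("peak must lie strictly after onset")
  win <- time >= onset & time <= peak_time
  if (sum(win) < 5) stop("fewer than 5 samples between onset and peak")
  tt <- time[win] - onset
  pk <- current[win][length(tt)]
  if (abs(pk) < .Machine$double.eps)
    return(new_exp_fit(NA_real_, 1, 0, NA_real_, FALSE))
  y <- current[win] / pk
  f <- nls_or_na(minpack.lm::nlsLM(
    y ~ 1 - exp(-tt / tau), start = list(tau = max(tt) / 5),
    lower = 1e-9, control = minpack.lm::nls.lm.control(maxiter = 500)))
  if (is.null(f)) return(new_exp_fit(NA_real_, 1, 0, NA_real_, FALSE))
  new_exp_fit(stats::coef(f)[["tau"]], 1, 0, sum(stats::residuals(f)^2),
              TRUE)
}

#' Single-exponential decay fit (deactivation / inactivation)
#'
#' Fits `y = A1 * exp(-t/tau) + A2` from the peak inside the window to the
#' window end. The offset is initialized from the final 5% of the window
#' (the steady state) and `tau` from a log-linear regression of the
#' offset-subtracted decay, then refined by Levenberg-Marquardt.
#'
#' @param time Time axis (ms).
#' @param current Current trace.
#' @param window `c(t_start, t_end)` in ms; the fit runs from the peak
#'   found inside this window to `t_end`.
#' @return An `exp_fit` with `tau` (ms), `A1`, `A2`.
#' @export
fit_tau_decay <- function(time, current, window = range(time)) {
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) < 5) stop("fewer than 5 samples in the fit window")
  tt <- time[idx]; yy <- current[idx]
  ip <- which.max(abs(yy))
  tt <- tt[ip:length(tt)] - tt[ip]
  yy <- yy[ip:length(yy)]
  if (length(yy) < 5) stop("fewer than 5 samples between peak and window end")
  A2 <- mean(utils::tail(yy, max(5, round(0.05 * length(yy)))))
  A1 <- yy[1] - A2
  if (abs(A1) <= 1e-12 * max(abs(yy), 1e-300))
    return(new_exp_fit(NA_real_, A1, A2, NA_real_, FALSE))
  z <- (yy - A2) / A1
  sel <- is.finite(z) & z > 0.05
  tau0 <- if (sum(sel) > 5) {
    sl <- stats::coef(stats::lm(log(z[sel]) ~ tt[sel]))[[2]]
    if (is.finite(sl) && sl < 0) -1 / sl else max(tt) / 5
  } else max(tt) / 5
  tau0 <- min(max(tau0, 10 * (tt[2] - tt[1])), 100 * max(tt))
  f <- nls_or_na(minpack.lm::nlsLM(
    yy ~ a * exp(-tt / tau) + b, start = list(a = A1, tau = tau0, b = A2),
    lower = c(-Inf, 1e-9, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000)))
  if (is.null(f)) {
    # multi-start fallback over a tau grid
    best <- NULL
    for (tg in max(tt) * c(0.02, 0.1, 0.5, 2)) {
      f2 <- nls_or_na(minpack.lm::nlsLM(
        yy ~ a * exp(-tt / tau) + b,
        start = list(a = A1, tau = tg, b = A2), lower = c(-Inf, 1e-9, -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 1000)))
      if (is.null(f2)) next
      rss <- sum(stats::residuals(f2)^2)
      if (is.null(best) || rss < best$rss) best <- list(f = f2, rss = rss)
    }
    if (is.null(best))
      return(new_exp_fit(NA_real_, A1, A2, NA_real_, FALSE))
    f <- best$f
  }
  co <- stats::coef(f)
  new_exp_fit(co[["tau"]], co[["a"]], co[["b"]],
              sum(stats::residuals(f)^2), TRUE)
}

#' Voltage of maximal conductance from a ramp trace
#'
#' Returns the command voltage at the current peak within the first rising
#' ramp segment of the protocol.
#'
#' @param traces A [trace_set()] with a voltage channel.
#' @param protocol The generating [voltage_protocol()].
#' @param sweep Sweep index (default 1).
#' @return Voltage (mV).
#' @export
v_max_cond <- function(traces, protocol, sweep = 1) {
  stopifnot(inherits(traces, "trace_set"), !is.null(traces$voltage))
  sw <- protocol$sweeps[[sweep]]
  rising <- which(sw$kind == "ramp" & sw$v_end > sw$v_start)
  if (length(rising) == 0) stop("protocol has no rising ramp segment")
  j <- rising[1]
  t0 <- c(0, cumsum(sw$duration))[j]
  t1 <- cumsum(sw$duration)[j]
  idx <- which(traces$time >= t0 & traces$time <= t1)
  ipk <- idx[which.max(abs(traces$current[sweep, idx]))]
  traces$voltage[sweep, ipk]
}

#' Root-mean-square error between two trace sets
#'
#' Per-sweep RMSE, averaged over sweeps. In `"norm"` mode both trace sets
#' are first normalized: by the maximum absolute current of the sweep
#' labelled `normalize_at` (the published convention normalizes to the
#' maximum measured current at the +70 mV step), or by the maximum of the
#' entire trace set when that sweep is absent (the ramp convention).
#'
#' @param model_traces,reference_traces [trace_set()]s with matching
#'   dimensions.
#' @param mode `"abs"` or `"norm"`.
#' @param normalize_at Sweep label defining the normalization (default 70).
#' @return Scalar RMSE.
#' @export
rmse_traces <- function(model_traces, reference_traces,
                        mode = c("abs", "norm"), normalize_at = 70) {
  mode <- match.arg(mode)
  a <- model_traces$current
  b <- reference_traces$current
  if (!all(dim(a) == dim(b)))
    stop("trace sets have different shapes: ",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  if (mode == "norm") {
    norm_of <- function(tr) {
      lbl <- tr$sweep_labels
      if (normalize_at %in% lbl)
        max(abs(tr$current[lbl == normalize_at, ]))
      else max(abs(tr$current))
    }
    a <- a / norm_of(model_traces)
    b <- b / norm_of(reference_traces)
  }
  mean(sqrt(rowMeans((a - b)^2)))
}

#' Extract the standard electrophysiological feature set from one model
#'
#' Simulates (or accepts pre-simulated traces for) the four standard
#' protocols and extracts: activation Boltzmann midpoint/slope, per-voltage
#' activation time constants, per-voltage deactivation time constants,
#' steady-state inactivation midpoint/slope, per-voltage inactivation time
#' constants, and the ramp `V_max_cond`.
#'
#' @param model A model object accepted by [simulate_model()].
#' @param dt Sampling interval (ms).
#' @param E_K Reversal potential used for conductances (mV).
#' @param blank Peak-search blanking interval (ms).
#' @param activation_range Sweep labels of the activation protocol to
#'   simulate and fit (default -90 to 70 mV, the published analysis range).
#' @param protocols Optional named list of protocols to use instead of the
#'   presets (`activation`, `deactivation`, `inactivation`, `ramp`); any
#'   missing entry falls back to the preset.
#' @return Named list of features (see Details).
#' @export
extract_features <- function(model, dt = 0.05, E_K = -65, blank = 0.5,
                             activation_range = seq(-90, 70, 10),
                             protocols = list()) {
  get_proto <- function(name) protocols[[name]] %||% preset_protocol(name)
  out <- list()

  act_proto <- get_proto("activation")
  act_proto <- subset_protocol(act_proto,
                               intersect(act_proto$sweep_labels,
                                         activation_range))
  act <- simulate_model(model, sample_protocol(act_proto, dt))
  gv <- conductance_curve(act, act_proto, E_K = E_K, blank = blank)
  bf <- fit_boltzmann_activation(gv$V, gv$G_norm)
  out$act_v_half <- bf$v_half
  out$act_k <- bf$k
  onset <- act_proto$sweeps[[1]]$duration[1]
  out$tau_act <- vapply(seq_len(nrow(act$current)), function(i) {
    f <- try(fit_tau_activation(act$time, act$current[i, ] -
                                  act$current[i, act$time <= onset][1],
                                onset = onset + blank), silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) NA_real_ else f$tau
  }, numeric(1))
  names(out$tau_act) <- act_proto$sweep_labels

  de_proto <- get_proto("deactivation")
  de <- simulate_model(model, sample_protocol(de_proto, dt))
  sw <- de_proto$sweeps[[1]]
  t_tail <- c(0, cumsum(sw$duration))[3]
  t_end <- cumsum(sw$duration)[3]
  out$tau_deact <- vapply(seq_len(nrow(de$current)), function(i) {
    f <- try(fit_tau_decay(de$time, de$current[i, ],
                           window = c(t_tail + blank, t_end - de$dt)),
             silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) NA_real_ else f$tau
  }, numeric(1))
  names(out$tau_deact) <- de_proto$sweep_labels

  in_proto <- get_proto("inactivation")
  ina <- simulate_model(model, sample_protocol(in_proto, dt))
  swi <- in_proto$sweeps[[1]]
  t_cond0 <- c(0, cumsum(swi$duration))[2]
  t_cond1 <- cumsum(swi$duration)[2]
  t_test1 <- cumsum(swi$duration)[3]
  out$tau_inact <- vapply(seq_len(nrow(ina$current)), function(i) {
    f <- try(fit_tau_decay(ina$time, ina$current[i, ],
                           window = c(t_cond0 + blank, t_cond1 - ina$dt)),
             silent = TRUE)
    if (inherits(f, "try-error") || !f$converged) NA_real_ else f$tau
  }, numeric(1))
  names(out$tau_inact) <- in_proto$sweep_labels
  pk <- vapply(seq_len(nrow(ina$current)), function(i) {
    idx <- ina$time >= t_cond1 + blank & ina$time < t_test1 - 1e-9
    max(abs(ina$current[i, idx]))
  }, numeric(1))
  bi <- fit_boltzmann_inactivation(in_proto$sweep_labels, pk / max(pk))
  out$inact_v_half <- bi$v_half
  out$inact_k <- bi$k

  ramp_proto <- get_proto("ramp")
  rmp <- simulate_model(model, sample_protocol(ramp_proto, dt))
  out$v_max_cond <- v_max_cond(rmp, ramp_proto)
  out
}

#' Assemble a feature comparison table across models
#'
#' Regenerates the published comparison layout: one column per model, one
#' row per electrophysiological parameter (activation V1/2 and k, mean and
#' per-voltage activation/deactivation/inactivation time constants,
#' inactivation V1/2 and k, V_max_cond, and optional normalized/absolute
#' RMSE against a reference trace set per protocol).
#'
#' @param models Named list of model objects ([hh_params()], [hmm_model()],
#'   [hw_model()], ...).
#' @param reference Optional named list of reference [trace_set()]s (names
#'   `activation`, `deactivation`, `inactivation`, `ramp`) to compute RMSE
#'   rows against.
#' @param ... Passed to [extract_features()].
#' @return `data.frame` with a `parameter` column and one column per model.
#' @export
feature_table <- function(models, reference = NULL, ...) {
  stopifnot(is.list(models), !is.null(names(models)))
  cols <- lapply(models, function(mod) {
    ft <- extract_features(mod, ...)
    rows <- c(
      act_v_half_mV = ft$act_v_half, act_k_mV = ft$act_k,
      tau_act_mean_ms = mean(ft$tau_act, na.rm = TRUE),
      stats::setNames(ft$tau_act, paste0("tau_act_", names(ft$tau_act),
                                         "mV_ms")),
      tau_deact_mean_ms = mean(ft$tau_deact, na.rm = TRUE),
      stats::setNames(ft$tau_deact,
                      paste0("tau_deact_", names(ft$tau_deact), "mV_ms")),
      inact_v_half_mV = ft$inact_v_half, inact_k_mV = ft$inact_k,
      tau_inact_mean_ms = mean(ft$tau_inact, na.rm = TRUE),
      stats::setNames(ft$tau_inact,
                      paste0("tau_inact_", names(ft$tau_inact), "mV_ms")),
      v_max_cond_mV = ft$v_max_cond)
    rows
  })
  tab <- data.frame(parameter = names(cols[[1]]))
  for (nm in names(cols)) tab[[nm]] <- unname(cols[[nm]])
  if (!is.null(reference)) {
    for (proto in names(reference)) {
      for (mode in c("norm", "abs")) {
        row <- c(parameter = sprintf("rmse_%s_%s", mode, proto))
        for (nm in names(models)) {
          ref <- reference[[proto]]
          stim <- attr(ref, "stimulus")
          if (is.null(stim))
            stim <- sample_protocol(preset_protocol(proto),
                                    ref$time[2] - ref$time[1])
          sim <- simulate_model(models[[nm]], stim)
          row[nm] <- rmse_traces(sim, ref, mode = mode)
        }
        tab <- rbind(tab, as.data.frame(as.list(row)))
      }
    }
    for (nm in names(models))
      tab[[nm]] <- as.numeric(tab[[nm]])
  }
  tab
}

#' Dispatch simulation over the three model families
#'
#' @param model An [hh_params()], [hmm_model()], or [hw_model()] object.
#' @param stimulus A [sample_protocol()] result.
#' @param ... Passed to the family-specific simulator.
#' @return A [trace_set()].
#' @export
simulate_model <- function(model, stimulus, ...) UseMethod("simulate_model")

#' @export
simulate_model.hh_params <- function(model, stimulus, ...)
  simulate_hh(stimulus, model, ...)

#' @export
simulate_model.hmm_model <- function(model, stimulus, ...)
  simulate_hmm(stimulus, model$params, model$scheme, ...)

#' @export
simulate_model.hw_model <- function(model, stimulus, ...)
  simulate_hw(stimulus, model, ...)
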