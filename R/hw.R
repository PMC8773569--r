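#' Piecewise-linear static map
#'
#' Gain-switched piecewise-linear nonlinearity: the output is
#' `slope_j * x` where `j` is the region containing `x`. Regions partition
#' the input axis at the breakpoints; a value equal to a breakpoint belongs
#' to the higher region (right-closed tie-break). Note this is a switched
#' gain, not an offset-matched (continuous) piecewise map; continuity is
#' not enforced. An optional `continuous` mode offset-matches the pieces.
#'
#' @param slopes Numeric vector of gains (>= 1 entry).
#' @param breakpoints Strictly increasing thresholds,
#'   `length(slopes) - 1` of them.
#' @param continuous If `TRUE`, pieces are offset-matched so the map is
#'   continuous; default `FALSE` (pure gain switching).
#' @return An object of class `piecewise_linear`.
#' @export
piecewise_linear <- function(slopes, breakpoints = numeric(0),
                             continuous = FALSE) {
  stopifnot(length(slopes) >= 1, all(is.finite(slopes)),
            length(breakpoints) == length(slopes) - 1)
  if (length(breakpoints) > 1 && any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  structure(list(slopes = as.numeric(slopes),
                 breakpoints = as.numeric(breakpoints),
                 continuous = isTRUE(continuous)),
            class = "piecewise_linear")
}

#' Apply a piecewise-linear map to a signal
#'
#' @param x Numeric vector.
#' @param map A [piecewise_linear()] object.
#' @return Numeric vector, same length as `x`.
#' @export
apply_piecewise <- function(x, map) {
  stopifnot(inherits(map, "piecewise_linear"))
  if (length(map$breakpoints) == 0) return(map$slopes[1] * x)
  # region j for x in [bp_{j-1}, bp_j); values at a breakpoint go up
  j <- findInterval(x, map$breakpoints) + 1L
  if (!map$continuous) return(map$slopes[j] * x)
  # offset-matched variant: piece j passes through the previous piece's
  # value at the lower breakpoint
  offs <- numeric(length(map$slopes))
  for (r in seq_along(map$breakpoints)) {
    b <- map$breakpoints[r]
    offs[r + 1] <- offs[r] + (map$slopes[r] - map$slopes[r + 1]) * b
  }
  map$slopes[j] * x + offs[j]
}

#' Third-order (or general) continuous-time transfer function
#'
#' `G(s) = num(s) / den(s)` with polynomial coefficients in decreasing
#' powers of s. The numerator degree must be strictly less than the
#' denominator degree (proper rational function).
#'
#' @param num Numerator coefficients, decreasing powers.
#' @param den Denominator coefficients, decreasing powers; leading
#'   coefficient nonzero.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(num, den) {
  stopifnot(length(den) >= 2, den[1] != 0, length(num) >= 1,
            length(num) < length(den))
  structure(list(num = as.numeric(num), den = as.numeric(den)),
            class = "transfer_function")
}

#' Hammerstein-Wiener model: static input map, linear block, output map
#'
#' @param input_nl,output_nl [piecewise_linear()] maps.
#' @param linear A [transfer_function()].
#' @return An object of class `hw_model`.
#' @export
hw_model <- function(input_nl, linear, output_nl) {
  stopifnot(inherits(input_nl, "piecewise_linear"),
            inherits(linear, "transfer_function"),
            inherits(output_nl, "piecewise_linear"))
  structure(list(input_nl = input_nl, linear = linear,
                 output_nl = output_nl), class = "hw_model")
}

#' @export
print.hw_model <- function(x, ...) {
  cat("<hw_model> Hammerstein-Wiener cascade\n")
  cat("  input slopes:", paste(signif(x$input_nl$slopes, 6),
                               collapse = ", "),
      if (length(x$input_nl$breakpoints))
        paste0("(breakpoints ",
               paste(signif(x$input_nl$breakpoints, 6), collapse = ", "),
               ")") else "(single region)", "\n")
  cat("  G(s): num [", paste(signif(x$linear$num, 6), collapse = ", "),
      "] / den [", paste(signif(x$linear$den, 6), collapse = ", "), "]\n")
  cat("  output slopes:", paste(signif(x$output_nl$slopes, 6),
                                collapse = ", "), "\n")
  p <- hw_poles(x)
  cat("  poles:", paste(format(signif(p$poles, 6)), collapse = ", "),
      if (p$stable) "(stable)" else "(UNSTABLE)", "\n")
  invisible(x)
}

#' The published Hammerstein-Wiener Kv1.1 model
#'
#' The system-theory-based Kv1.1 model: piecewise-linear input and output
#' nonlinearities with two breakpoints around a third-order transfer
#' function. The transfer-function coefficients and the six slopes are the
#' published values; the breakpoint positions are not printed in the main
#' text, so the defaults here are placeholder values (not published values)
#' chosen near the operating range boundaries of the deviation signals, and
#' should be treated as configuration.
#'
#' @param input_breakpoints,output_breakpoints Breakpoints of the two maps
#'   (placeholder defaults, see Details).
#' @return An [hw_model()].
#' @export
kv11_hw_model <- function(input_breakpoints = c(50, 120),
                          output_breakpoints = c(-4, -1)) {
  hw_model(
    piecewise_linear(c(1.2, 0.2, 0.1), input_breakpoints),
    transfer_function(num = c(-1.269e4, -1.754e8, -6.268e8),
                      den = c(1, 4321, 4.104e8, 1.596e9)),
    piecewise_linear(c(-0.3, -0.1, -0.01), output_breakpoints))
}

#' Poles and stability of a Hammerstein-Wiener model's linear block
#'
#' @param model An [hw_model()] or [transfer_function()].
#' @return List with `poles` (complex vector, roots of the denominator) and
#'   `stable` (`TRUE` iff all real parts are < 0).
#' @export
hw_poles <- function(model) {
  tf <- if (inherits(model, "hw_model")) model$linear else model
  stopifnot(inherits(tf, "transfer_function"))
  # polyroot takes increasing powers
  poles <- polyroot(rev(tf$den))
  list(poles = poles, stable = all(Re(poles) < 0))
}

#' DC gain of the linear block
#' @inheritParams hw_poles
#' @return `num[last]/den[last]`, the zero-frequency gain.
#' @export
hw_dc_gain <- function(model) {
  tf <- if (inherits(model, "hw_model")) model$linear else model
  tf$num[length(tf$num)] / tf$den[length(tf$den)]
}

# controllable-canonical state-space realization of a proper TF
tf_to_ss <- function(tf) {
  den <- tf$den / tf$den[1]
  num <- tf$num / tf$den[1]
  n <- length(den) - 1L
  b <- c(rev(num), rep(0, n - length(num)))  # increasing powers, padded
  a <- rev(den[-1])                          # a0 ... a_{n-1}
  A <- rbind(cbind(matrix(0, n - 1, 1), diag(1, n - 1, n - 1)), -a)
  B <- matrix(c(rep(0, n - 1), 1), ncol = 1)
  C <- matrix(b, nrow = 1)
  list(A = A, B = B, C = C)
}

# zero-order-hold discretization at dt (time unit of A must match dt)
ss_zoh <- function(ss, dt) {
  n <- nrow(ss$A)
  M <- as.matrix(Matrix::expm(rbind(cbind(ss$A, ss$B),
                                    matrix(0, 1, n + 1)) * dt))
  list(Ad = M[seq_len(n), seq_len(n), drop = FALSE],
       Bd = M[seq_len(n), n + 1, drop = FALSE], C = ss$C)
}

# simulate the linear block alone: u in sample units, time in ms.
# The TF is expressed in seconds, so dt is converted.
simulate_linear_tf <- function(tf, u, dt_ms) {
  ss <- tf_to_ss(tf)
  dz <- ss_zoh(ss, dt_ms * 1e-3)
  n <- length(u)
  x <- matrix(0, nrow(dz$Ad), 1)
  y <- numeric(n)
  y[1] <- as.numeric(dz$C %*% x)
  for (j in seq_len(n - 1L)) {
    x <- dz$Ad %*% x + dz$Bd * u[j]
    y[j + 1L] <- as.numeric(dz$C %*% x)
  }
  y
}

#' Simulate a Hammerstein-Wiener model under a sampled stimulus
#'
#' The cascade is `v' = input_nl(v - v_hold)`, `i' = G(s) applied to v'`
#' (zero-order-hold state-space simulation from zero initial state), and
#' `i = output_nl(i')`. The transfer-function formalism assumes zero
#' initial conditions, so the linear block operates on deviations from the
#' holding level (the first sample of each sweep) rather than raw voltages.
#'
#' @param stimulus A [sample_protocol()] result.
#' @param model An [hw_model()].
#' @param subtract_holding If `TRUE` (default), the input operating point
#'   (first-sample voltage) is subtracted before the cascade.
#' @return A [trace_set()] (unit `"nA"`) with `extra$intermediate`: per
#'   sweep, the linear-block output `i'`.
#' @export
simulate_hw <- function(stimulus, model, subtract_holding = TRUE) {
  stopifnot(inherits(stimulus, "sampled_stimulus"),
            inherits(model, "hw_model"))
  if (!hw_poles(model)$stable)
    warning("linear block has a pole with non-negative real part; ",
            "the simulation may diverge")
  V <- stimulus$voltage
  n <- ncol(V)
  cur <- matrix(NA_real_, nrow(V), n)
  inter <- vector("list", nrow(V))
  for (i in seq_len(nrow(V))) {
    v <- V[i, ]
    if (subtract_holding) v <- v - v[1]
    vprime <- apply_piecewise(v, model$input_nl)
    iprime <- simulate_linear_tf(model$linear, vprime, stimulus$dt)
    cur[i, ] <- apply_piecewise(iprime, model$output_nl)
    inter[[i]] <- iprime
  }
  trace_set(stimulus$time, cur, voltage = stimulus$voltage,
            sweep_labels = stimulus$sweep_labels, unit = "nA",
            protocol_name = stimulus$protocol_name,
            extra = list(intermediate = inter))
}

#' Analytic step response of a transfer function
#'
#' Closed-form response to a unit step of amplitude `amp` via partial
#' fractions over the (assumed distinct) poles:
#' `y(t) = amp * (G(0) + sum_i N(p_i)/(p_i D'(p_i)) exp(p_i t))`.
#' Used as an independent oracle for the discretized simulation.
#'
#' @param tf A [transfer_function()].
#' @param t Times (seconds).
#' @param amp Step amplitude.
#' @return Numeric vector `y(t)`.
#' @export
tf_step_response <- function(tf, t, amp = 1) {
  poles <- polyroot(rev(tf$den))
  if (min(abs(outer(poles, poles, "-")[lower.tri(diag(length(poles)))])) <
      1e-9 * max(abs(poles)))
    stop("repeated poles; analytic step response not implemented")
  polyval <- function(coef, s) {
    # coef decreasing powers
    out <- 0 + 0i
    for (cf in coef) out <- out * s + cf
    out
  }
  dden <- tf$den[-length(tf$den)] *
    rev(seq_len(length(tf$den) - 1L))  # derivative, decreasing powers
  y <- rep(tf$num[length(tf$num)] / tf$den[length(tf$den)] + 0i, length(t))
  for (p in poles) {
    res <- polyval(tf$num, p) / (p * polyval(dden, p))
    y <- y + res * exp(p * t)
  }
  amp * Re(y)
}

#' Write / read a Hammerstein-Wiener model as JSON
#' @param model An [hw_model()].
#' @param path File path.
#' @return `read_hw_model` returns an [hw_model()].
#' @export
write_hw_model <- function(model, path) {
  jsonlite::write_json(list(
    input_nl = unclass(model$input_nl),
    linear = unclass(model$linear),
    output_nl = unclass(model$output_nl)), path, auto_unbox = TRUE,
    digits = NA)
  invisible(path)
}

#' @rdname write_hw_model
#' @export
read_hw_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hw_model(
    piecewise_linear(obj$input_nl$slopes,
                     obj$input_nl$breakpoints %||% numeric(0),
                     isTRUE(obj$input_nl$continuous)),
    transfer_function(obj$linear$num, obj$linear$den),
    piecewise_linear(obj$output_nl$slopes,
                     obj$output_nl$breakpoints %||% numeric(0),
                     isTRUE(obj$output_nl$continuous)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
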