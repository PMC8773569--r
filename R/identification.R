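#' Fit configuration for identification routines
#'
#' @param bounds Named list of `c(lower, upper)` per free parameter.
#' @param max_iterations Iteration budget (PSO iterations / PEM restarts x
#'   optimizer iterations).
#' @param swarm_size PSO swarm size (>= 2).
#' @param seed Integer seed.
#' @param objective `"rmse_norm"` or `"rmse_abs"`.
#' @param sweeps Optional sweep labels to include per protocol (named list).
#' @return A `fit_config` list.
#' @export
fit_config <- function(bounds = NULL, max_iterations = 200, swarm_size = 50,
                       seed = 1, objective = c("rmse_abs", "rmse_norm"),
                       sweeps = NULL) {
  objective <- match.arg(objective)
  if (!is.null(bounds)) {
    ok <- vapply(bounds, function(b) length(b) == 2 && b[1] < b[2],
                 logical(1))
    if (!all(ok)) stop("each bound must be c(lower, upper) with lower < upper")
  }
  stopifnot(swarm_size >= 2, max_iterations >= 1)
  structure(list(bounds = bounds, max_iterations = max_iterations,
                 swarm_size = swarm_size, seed = seed,
                 objective = objective, sweeps = sweeps),
            class = "fit_config")
}

new_fit_report <- function(par, objective, trace, seed, wall_time) {
  structure(list(par = par, objective = objective, trace = trace,
                 seed = seed, wall_time = wall_time),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> objective = %.6g after %d iterations (%.2f s)\n",
              x$objective, length(x$trace), x$wall_time))
  if (length(x$par)) {
    cat("best parameters:\n")
    print(unlist(x$par))
  }
  invisible(x)
}

# canonical constriction-coefficient particle swarm optimizer with
# reflecting bounds; deterministic under seed
pso_minimize <- function(fn, lower, upper, swarm_size = 50, iters = 200,
                         seed = 1, inertia = 0.729, c_cog = 1.49445,
                         c_soc = 1.49445) {
  set.seed(seed)
  d <- length(lower)
  span <- upper - lower
  X <- matrix(stats::runif(swarm_size * d), swarm_size, d) *
    rep(span, each = swarm_size) + rep(lower, each = swarm_size)
  Vv <- matrix(stats::runif(swarm_size * d, -1, 1), swarm_size, d) *
    rep(span, each = swarm_size) * 0.1
  fx <- apply(X, 1, function(p) {
    v <- fn(p)
    if (!is.finite(v)) Inf else v
  })
  # re-seed non-finite particles within bounds
  bad <- !is.finite(fx)
  while (any(bad)) {
    X[bad, ] <- matrix(stats::runif(sum(bad) * d), sum(bad), d) *
      rep(span, each = sum(bad)) + rep(lower, each = sum(bad))
    fx[bad] <- apply(X[bad, , drop = FALSE], 1, fn)
    fx[!is.finite(fx)] <- Inf
    bad <- !is.finite(fx)
  }
  P <- X; fp <- fx
  g <- which.min(fp)
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    Vv <- inertia * Vv + c_cog * r1 * (P - X) +
      c_soc * r2 * (X[rep(g, swarm_size), , drop = FALSE] - X)
    X <- X + Vv
    # reflecting bounds
    for (j in seq_len(d)) {
      lo <- X[, j] < lower[j]
      hi <- X[, j] > upper[j]
      X[lo, j] <- pmin(2 * lower[j] - X[lo, j], upper[j])
      X[hi, j] <- pmax(2 * upper[j] - X[hi, j], lower[j])
      X[, j] <- pmin(pmax(X[, j], lower[j]), upper[j])
      Vv[lo | hi, j] <- -Vv[lo | hi, j]
    }
    fx <- apply(X, 1, function(p) {
      v <- fn(p)
      if (!is.finite(v)) Inf else v
    })
    better <- fx < fp
    P[better, ] <- X[better, , drop = FALSE]
    fp[better] <- fx[better]
    g <- which.min(fp)
    trace[it] <- fp[g]
  }
  list(par = P[g, ], value = fp[g], trace = trace)
}

#' Fit Markov rate parameters by particle swarm optimization
#'
#' Minimizes the summed per-protocol RMSE between deterministic Markov
#' simulations and target trace sets over a subset of free parameters, with
#' the canonical constriction-coefficient swarm (inertia 0.729,
#' cognitive/social 1.49445) and reflecting bounds. Particles whose
#' objective is non-finite are re-seeded within bounds. The run is
#' reproducible given `config$seed`.
#'
#' @param stimuli List of [sample_protocol()] stimuli (one per protocol).
#' @param targets List of target [trace_set()]s matching `stimuli`.
#' @param free_params Character vector of [hmm_params()] field names to fit.
#' @param params Baseline [hmm_params()]; non-free fields stay fixed.
#' @param scheme A [kv11_scheme()].
#' @param config A [fit_config()]; default bounds are a factor-10 window
#'   around each baseline value.
#' @return List with `params` (fitted [hmm_params()]) and `report`
#'   (a `fit_report`).
#' @export
fit_hmm_pso <- function(stimuli, targets, free_params,
                        params = hmm_params(), scheme = kv11_scheme(),
                        config = fit_config()) {
  stopifnot(length(stimuli) == length(targets), length(stimuli) >= 1)
  stopifnot(all(free_params %in% names(params)))
  t0 <- proc.time()[3]
  mode <- if (config$objective == "rmse_norm") "norm" else "abs"
  make_params <- function(theta) {
    p <- unclass(params)
    p[free_params] <- as.list(theta)
    do.call(hmm_params, p)
  }
  objective <- function(theta) {
    p <- try(make_params(theta), silent = TRUE)
    if (inherits(p, "try-error")) return(Inf)
    tot <- 0
    for (i in seq_along(stimuli)) {
      sim <- try(suppressWarnings(simulate_hmm(stimuli[[i]], p, scheme)),
                 silent = TRUE)
      if (inherits(sim, "try-error")) return(Inf)
      tot <- tot + rmse_traces(sim, targets[[i]], mode = mode)
    }
    tot
  }
  if (length(free_params) == 0) {
    val <- objective(numeric(0))
    return(list(params = params,
                report = new_fit_report(list(), val, val, config$seed,
                                        proc.time()[3] - t0)))
  }
  base <- unlist(unclass(params)[free_params])
  bounds <- config$bounds
  lower <- vapply(free_params, function(nm)
    if (!is.null(bounds[[nm]])) bounds[[nm]][1] else base[[nm]] / 10,
    numeric(1))
  upper <- vapply(free_params, function(nm)
    if (!is.null(bounds[[nm]])) bounds[[nm]][2] else base[[nm]] * 10,
    numeric(1))
  res <- pso_minimize(objective, lower, upper,
                      swarm_size = config$swarm_size,
                      iters = config$max_iterations, seed = config$seed)
  best <- stats::setNames(as.list(res$par), free_params)
  list(params = make_params(res$par),
       report = new_fit_report(best, res$value, res$trace, config$seed,
                               proc.time()[3] - t0))
}

#' Estimate the whole-cell channel count from absolute currents
#'
#' One-dimensional least squares: the scale factor between the per-channel
#' simulated current (`N_c = 1`) and the measured current, rounded to the
#' nearest integer (at least 1).
#'
#' @param traces Measured [trace_set()] in nA.
#' @param stimulus The matching [sample_protocol()] stimulus.
#' @param params An [hmm_params()]; its `N_c` is ignored.
#' @param scheme A [kv11_scheme()].
#' @return Integer channel count.
#' @export
estimate_channel_count <- function(traces, stimulus,
                                   params = hmm_params(),
                                   scheme = kv11_scheme()) {
  p1 <- do.call(hmm_params, utils::modifyList(unclass(params),
                                              list(N_c = 1)))
  sim <- simulate_hmm(stimulus, p1, scheme)
  s <- as.numeric(sim$current)
  m <- as.numeric(traces$current)
  ss <- sum(s^2)
  if (ss <= .Machine$double.eps)
    stop("simulated per-channel current is identically zero")
  max(1L, as.integer(round(sum(s * m) / ss)))
}

#' Fit a Hammerstein-Wiener model by prediction-error minimization
#'
#' Estimates a continuous-time Hammerstein-Wiener cascade from one
#' stimulus/response record by minimizing the RMS simulation error. The
#' identifiability normalization fixes the first input slope to 1 (the
#' cascade has a three-way scale ambiguity between the input map, transfer
#' function gain, and output map; the remaining scale is carried by the
#' transfer function and output slopes).
#'
#' The search is separable: for a candidate stable denominator (positive
#' coefficients, optimized on a log scale by Nelder-Mead from several
#' seeded restarts) the numerator follows by ordinary least squares on the
#' states of `1/D(s)` driven by the mapped input. With a single region and
#' identity output map this inner step is exactly the linear output-error
#' regression; with multiple regions the input/output slopes join the
#' nonlinear search.
#'
#' @param stimulus A [sample_protocol()] result (single sweep).
#' @param target Numeric vector: observed output, aligned with
#'   `stimulus$time`.
#' @param orders `c(n_poles, n_zeros, n_regions)`; `n_poles >= 1`,
#'   `n_zeros < n_poles`, `n_regions >= 1`.
#' @param input_breakpoints,output_breakpoints Fixed breakpoints when
#'   `n_regions > 1`.
#' @param config A [fit_config()]; `max_iterations` caps each Nelder-Mead
#'   run and `seed` drives the restarts.
#' @param n_restarts Number of seeded multi-starts (default 5).
#' @return List with `model` (an [hw_model()]) and `report`
#'   (a `fit_report`; `objective` is the output RMSE).
#' @export
fit_hw_pem <- function(stimulus, target, orders = c(3, 2, 1),
                       input_breakpoints = numeric(0),
                       output_breakpoints = numeric(0),
                       config = fit_config(), n_restarts = 5) {
  stopifnot(inherits(stimulus, "sampled_stimulus"),
            nrow(stimulus$voltage) == 1,
            length(target) == ncol(stimulus$voltage))
  np <- orders[1]; nz <- orders[2]; nr <- orders[3]
  stopifnot(np >= 1, nz >= 0, nz < np, nr >= 1,
            length(input_breakpoints) == nr - 1,
            length(output_breakpoints) == nr - 1)
  t0 <- proc.time()[3]
  v <- stimulus$voltage[1, ] - stimulus$voltage[1, 1]
  dt_s <- stimulus$dt * 1e-3
  n <- length(v)

  # states of 1/D(s): basis signals whose C-combination is any numerator
  basis_states <- function(den, u) {
    ss <- tf_to_ss(transfer_function(c(rep(0, np - 1), 1), den))
    dz <- ss_zoh(ss, dt_s)
    X <- matrix(0, n, np)
    x <- matrix(0, np, 1)
    for (j in seq_len(n - 1L)) {
      x <- dz$Ad %*% x + dz$Bd * u[j]
      X[j + 1L, ] <- x
    }
    X
  }
  # theta layout: log(den coefs a_{n-1}..a_0) [np], then extra input slopes
  # (nr-1), then output slopes (nr) when nr > 1
  unpack <- function(theta) {
    den <- c(1, exp(theta[seq_len(np)]))
    in_slopes <- c(1, theta[np + seq_len(nr - 1)])
    out_slopes <- if (nr > 1) theta[np + nr - 1 + seq_len(nr)] else 1
    list(den = den, in_slopes = in_slopes, out_slopes = out_slopes)
  }
  evaluate <- function(theta, return_model = FALSE) {
    pp <- unpack(theta)
    if (any(!is.finite(pp$den))) return(Inf)
    inl <- piecewise_linear(pp$in_slopes, input_breakpoints)
    u <- apply_piecewise(v, inl)
    X <- basis_states(pp$den, u)
    if (nr == 1) {
      sel <- seq_len(nz + 1)
      fitX <- X[, sel, drop = FALSE]
      b <- tryCatch(stats::lsfit(fitX, target, intercept = FALSE)$coef,
                    error = function(e) rep(NA_real_, nz + 1))
      if (anyNA(b)) return(Inf)
      pred <- as.numeric(fitX %*% b)
      num <- rev(b)
      onl <- piecewise_linear(1)
    } else {
      # with output regions the numerator is found against the
      # slope-1 output, then the output map is applied
      sel <- seq_len(nz + 1)
      onl <- piecewise_linear(pp$out_slopes, output_breakpoints)
      # approximate inner solve: regress target on mapped basis columns
      Xm <- apply(X[, sel, drop = FALSE], 2, function(col)
        apply_piecewise(col, onl))
      b <- tryCatch(stats::lsfit(Xm, target, intercept = FALSE)$coef,
                    error = function(e) rep(NA_real_, nz + 1))
      if (anyNA(b)) return(Inf)
      iprime <- as.numeric(X[, sel, drop = FALSE] %*% b)
      pred <- apply_piecewise(iprime, onl)
      num <- rev(b)
    }
    rmse <- sqrt(mean((pred - target)^2))
    if (!return_model) return(rmse)
    list(rmse = rmse,
         model = hw_model(piecewise_linear(pp$in_slopes,
                                           input_breakpoints),
                          transfer_function(num, pp$den), onl))
  }

  set.seed(config$seed)
  span <- max(stimulus$time) * 1e-3  # record length, s
  best <- NULL
  trace <- numeric(0)
  for (r in seq_len(n_restarts)) {
    # random stable pole rates between 1/record and 1/(4 dt)
    rates <- exp(stats::runif(np, log(1 / span), log(1 / (4 * dt_s))))
    den0 <- Re(rev(coef_from_roots(-rates)))   # decreasing powers, monic
    theta0 <- log(den0[-1])
    if (nr > 1) theta0 <- c(theta0, rep(1, nr - 1), rep(1, nr))
    opt <- stats::optim(theta0, evaluate, method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations * 10,
                                       reltol = 1e-15))
    # polish
    opt2 <- stats::optim(opt$par, evaluate, method = "Nelder-Mead",
                         control = list(maxit = config$max_iterations * 10,
                                        reltol = 1e-15))
    cand <- if (opt2$value < opt$value) opt2 else opt
    trace <- c(trace, cand$value)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || !is.finite(best$value))
    stop("all PEM restarts diverged")
  fin <- evaluate(best$par, return_model = TRUE)
  list(model = fin$model,
       report = new_fit_report(list(den = fin$model$linear$den,
                                    num = fin$model$linear$num),
                               fin$rmse, trace, config$seed,
                               proc.time()[3] - t0))
}

# monic polynomial coefficients (increasing powers) from roots
coef_from_roots <- function(roots) {
  cf <- 1
  for (r in roots) cf <- c(0, cf) - c(r * cf, 0)
  cf  # increasing powers? build: (x - r) products, cf[1] = constant
}
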