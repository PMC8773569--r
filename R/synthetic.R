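#' Generate one synthetic whole-cell recording
#'
#' Produces a surrogate patch-clamp measurement from a channel model:
#' the simulated current plus i.i.d. Gaussian noise and biphasic capacitive
#' spike artifacts at every step edge (amplitude proportional to the step
#' size, sign following the step direction), together with quality-control
#' metadata (seal resistance, series resistance, offset voltage, membrane
#' capacitance). Reproducible given `seed`.
#'
#' @param model A model accepted by [simulate_model()]. For Markov models
#'   the per-cell channel count `N_c` scales the current.
#' @param protocol A [voltage_protocol()].
#' @param N_c Channel count for this cell (applied to [hmm_model()]s only).
#' @param noise_sd Gaussian noise s.d. (nA).
#' @param spike_amplitude Capacitive spike amplitude per 100 mV of step
#'   (nA); 0 disables artifacts.
#' @param spike_tau Spike decay time constant (ms, default 0.3).
#' @param R_seal,R_series,V_offset,C_slow QC metadata values; defaults draw
#'   typical passing values.
#' @param dt Sampling interval (ms).
#' @param seed Integer seed.
#' @return An object of class `synthetic_cell`: list with `traces`
#'   ([trace_set()]), `clean` (noise-free traces), `N_c`, `noise_sd`,
#'   `spike_amplitude`, `R_seal`, `R_series`, `V_offset`, `C_slow`, `seed`.
#' @export
generate_cell <- function(model, protocol, N_c = NULL, noise_sd = 0.05,
                          spike_amplitude = 0.5, spike_tau = 0.3,
                          R_seal = 500, R_series = 8, V_offset = 10,
                          C_slow = 20, dt = 0.05, seed = 1) {
  set.seed(seed)
  if (!is.null(N_c) && inherits(model, "hmm_model")) {
    p <- utils::modifyList(unclass(model$params), list(N_c = N_c))
    model <- hmm_model(do.call(hmm_params, p), model$scheme)
  }
  stim <- sample_protocol(protocol, dt)
  clean <- simulate_model(model, stim)
  cur <- clean$current
  if (spike_amplitude > 0) {
    for (i in seq_len(nrow(cur))) {
      sw <- protocol$sweeps[[i]]
      edges <- cumsum(sw$duration)[-nrow(sw)]
      v_before <- sw$v_end[-nrow(sw)]
      v_after <- sw$v_start[-1]
      for (e in seq_along(edges)) {
        dV <- v_after[e] - v_before[e]
        if (dV == 0) next
        idx <- which(stim$time >= edges[e] &
                       stim$time <= edges[e] + 8 * spike_tau)
        tt <- stim$time[idx] - edges[e]
        amp <- spike_amplitude * dV / 100
        # biphasic: fast main lobe, slower opposite-sign rebound
        cur[i, idx] <- cur[i, idx] + amp * (exp(-tt / spike_tau) -
                                              0.4 * exp(-tt / (2 * spike_tau)))
      }
    }
  }
  if (noise_sd > 0)
    cur <- cur + matrix(stats::rnorm(length(cur), 0, noise_sd), nrow(cur))
  noisy <- trace_set(stim$time, cur, voltage = stim$voltage,
                     sweep_labels = stim$sweep_labels, unit = "nA",
                     protocol_name = protocol$name)
  structure(list(traces = noisy, clean = clean,
                 N_c = if (is.null(N_c)) NA_real_ else N_c,
                 noise_sd = noise_sd, spike_amplitude = spike_amplitude,
                 R_seal = R_seal, R_series = R_series,
                 V_offset = V_offset, C_slow = C_slow, seed = seed),
            class = "synthetic_cell")
}

#' @export
print.synthetic_cell <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_cell> N_c = %s, noise = %g nA, ",
                     "R_seal = %g MOhm, seed = %d\n"),
              format(x$N_c), x$noise_sd, x$R_seal, x$seed))
  print(x$traces)
  invisible(x)
}

#' Population specification for synthetic cells
#'
#' Cell-to-cell variability: channel counts are drawn lognormally (the
#' macroscopic current magnitude varies considerably from cell to cell),
#' and QC metadata from simple parametric distributions.
#'
#' @param n_cells Number of cells (>= 1).
#' @param N_c_median Median channel count.
#' @param N_c_sigma Lognormal sigma of the channel count (0 = identical).
#' @param noise_sd Per-trace Gaussian noise s.d. (nA).
#' @param spike_amplitude Capacitive spike scale (nA per 100 mV).
#' @param R_seal_meanlog,R_seal_sdlog Lognormal seal resistance (MOhm).
#' @param seed Integer seed.
#' @return A `population_spec` list.
#' @export
population_spec <- function(n_cells = 10, N_c_median = 2588,
                            N_c_sigma = 0.3, noise_sd = 0.05,
                            spike_amplitude = 0.5,
                            R_seal_meanlog = log(600), R_seal_sdlog = 0.5,
                            seed = 1) {
  stopifnot(n_cells >= 1, N_c_median > 0, N_c_sigma >= 0)
  structure(list(n_cells = n_cells, N_c_median = N_c_median,
                 N_c_sigma = N_c_sigma, noise_sd = noise_sd,
                 spike_amplitude = spike_amplitude,
                 R_seal_meanlog = R_seal_meanlog,
                 R_seal_sdlog = R_seal_sdlog, seed = seed),
            class = "population_spec")
}

#' Generate a population of synthetic cells
#'
#' @param model A model accepted by [simulate_model()].
#' @param protocol A [voltage_protocol()].
#' @param spec A [population_spec()].
#' @param dt Sampling interval (ms).
#' @return List of [generate_cell()] results.
#' @export
generate_population <- function(model, protocol, spec = population_spec(),
                                dt = 0.05) {
  set.seed(spec$seed)
  n <- spec$n_cells
  N_c <- round(stats::rlnorm(n, log(spec$N_c_median), spec$N_c_sigma))
  N_c <- pmax(N_c, 1)
  R_seal <- stats::rlnorm(n, spec$R_seal_meanlog, spec$R_seal_sdlog)
  seeds <- sample.int(.Machine$integer.max / 2, n)
  lapply(seq_len(n), function(i)
    generate_cell(model, protocol, N_c = N_c[i],
                  noise_sd = spec$noise_sd,
                  spike_amplitude = spec$spike_amplitude,
                  R_seal = R_seal[i], dt = dt, seed = seeds[i]))
}

#' Quality-control filter for synthetic (or imported) cells
#'
#' Partition cells by the published exclusion rule (seal resistance below
#' threshold) and optionally by baseline noise level.
#'
#' @param cells List of `synthetic_cell`s.
#' @param min_R_seal Minimum seal resistance to keep (MOhm, default 300).
#' @param max_noise Optional maximum baseline standard deviation (nA),
#'   measured over the first 50 ms (holding segment) of each sweep.
#' @return List with `kept` and `excluded` (order preserved,
#'   `kept` + `excluded` = input).
#' @export
qc_filter <- function(cells, min_R_seal = 300, max_noise = NULL) {
  keep <- vapply(cells, function(cl) {
    ok <- cl$R_seal >= min_R_seal
    if (ok && !is.null(max_noise)) {
      idx <- cl$traces$time <= 50
      base_sd <- mean(apply(cl$traces$current[, idx, drop = FALSE], 1,
                            stats::sd))
      ok <- base_sd <= max_noise
    }
    ok
  }, logical(1))
  list(kept = cells[keep], excluded = cells[!keep])
}

#' Average the traces of several cells
#'
#' @param cells List of `synthetic_cell`s sharing one protocol/grid.
#' @return A [trace_set()] of the mean current.
#' @export
average_cells <- function(cells) {
  stopifnot(length(cells) >= 1)
  cur <- Reduce(`+`, lapply(cells, function(cl) cl$traces$current)) /
    length(cells)
  tmpl <- cells[[1]]$traces
  trace_set(tmpl$time, cur, voltage = tmpl$voltage,
            sweep_labels = tmpl$sweep_labels, unit = tmpl$unit,
            protocol_name = tmpl$protocol_name)
}
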