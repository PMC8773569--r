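#' Voltage-clamp segment
#'
#' A single piece of a voltage-clamp sweep: either a constant step or a
#' linear ramp. Voltages are in mV, durations in ms throughout the package.
#'
#' @param kind `"step"` or `"ramp"`.
#' @param v_start Voltage at segment start (mV).
#' @param v_end Voltage at segment end (mV). Must equal `v_start` for steps;
#'   defaults to `v_start`.
#' @param duration Segment duration (ms), strictly positive.
#' @return A one-row `data.frame` with columns `kind`, `v_start`, `v_end`,
#'   `duration`.
#' @export
segment <- function(kind = c("step", "ramp"), v_start, v_end = v_start,
                    duration) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(v_start), is.numeric(v_end), is.numeric(duration),
            length(v_start) == 1, length(v_end) == 1, length(duration) == 1,
            is.finite(v_start), is.finite(v_end), is.finite(duration))
  if (duration <= 0) stop("segment duration must be > 0")
  if (kind == "step" && v_start != v_end)
    stop("a step segment must have v_start == v_end")
  data.frame(kind = kind, v_start = v_start, v_end = v_end,
             duration = duration)
}

#' Voltage-clamp protocol
#'
#' A family of sweeps, each an ordered sequence of [segment()]s. All sweeps
#' must have the same total duration so they can share one time axis.
#'
#' @param name Protocol name.
#' @param sweeps List of sweeps; each sweep is a `data.frame` of segments
#'   (rows rbind-ed from [segment()]).
#' @param sweep_labels Numeric label per sweep, conventionally the varied
#'   voltage level (mV).
#' @return An object of class `voltage_protocol`.
#' @export
voltage_protocol <- function(name, sweeps, sweep_labels = NULL) {
  stopifnot(is.character(name), length(sweeps) >= 1)
  sweeps <- lapply(sweeps, function(sw) {
    sw <- as.data.frame(sw)
    stopifnot(all(c("kind", "v_start", "v_end", "duration") %in% names(sw)))
    if (any(sw$duration <= 0)) stop("all segment durations must be > 0")
    bad <- sw$kind == "step" & sw$v_start != sw$v_end
    if (any(bad)) stop("step segments must have v_start == v_end")
    sw
  })
  durs <- vapply(sweeps, function(sw) sum(sw$duration), numeric(1))
  if (diff(range(durs)) > 1e-9)
    stop("all sweeps must have equal total duration (got ",
         paste(unique(durs), collapse = ", "), " ms)")
  if (is.null(sweep_labels)) sweep_labels <- seq_along(sweeps)
  stopifnot(length(sweep_labels) == length(sweeps))
  structure(list(name = name, sweeps = sweeps,
                 sweep_labels = as.numeric(sweep_labels)),
            class = "voltage_protocol")
}

#' @export
print.voltage_protocol <- function(x, ...) {
  cat(sprintf("<voltage_protocol> %s: %d sweeps, %.6g ms each\n",
              x$name, length(x$sweeps), sum(x$sweeps[[1]]$duration)))
  cat("sweep labels (mV):", paste(x$sweep_labels, collapse = " "), "\n")
  cat("sweep 1 segments:\n")
  print(x$sweeps[[1]], row.names = FALSE)
  invisible(x)
}

n_sweeps <- function(protocol) length(protocol$sweeps)

#' Total duration of a protocol (ms)
#' @param protocol A [voltage_protocol()].
#' @return Scalar duration in ms.
#' @export
protocol_duration <- function(protocol) sum(protocol$sweeps[[1]]$duration)

#' Preset voltage protocols for Kv1.1 characterization
#'
#' The four standard whole-cell stimulation protocols used to characterize
#' Kv1.1 activation, deactivation, inactivation, and ramp responses:
#'
#' * `activation`: 100 ms at -80 mV, 500 ms test pulses from -90 to +80 mV
#'   in 10 mV increments (18 sweeps), 100 ms re-pulse at -80 mV.
#' * `deactivation`: 100 ms at -80 mV, 300 ms activating pulse at +70 mV,
#'   300 ms tail pulses from -80 to +30 mV in 10 mV steps (12 sweeps),
#'   100 ms re-pulse at -80 mV.
#' * `inactivation`: 100 ms at -80 mV, 1500 ms conditioning pulses from
#'   -40 to +70 mV in 10 mV increments (12 sweeps), 100 ms test pulse at
#'   +30 mV, 100 ms re-pulse at -80 mV.
#' * `ramp`: four symmetric triangular excursions (one sweep). The exact
#'   published ramp waveform is only shown graphically, so its geometry is
#'   configurable: each excursion runs `ramp_from` to `ramp_to` and back
#'   over 400/200/100/50 ms, separated by 400 ms holds at `ramp_from`,
#'   preceded and followed by 100 ms at -80 mV.
#'
#' @param name One of `"activation"`, `"deactivation"`, `"inactivation"`,
#'   `"ramp"`.
#' @param ramp_from,ramp_to Ramp excursion endpoints (mV), used only for the
#'   ramp preset.
#' @return A [voltage_protocol()].
#' @export
preset_protocol <- function(name, ramp_from = -90, ramp_to = 50) {
  presets <- c("activation", "deactivation", "inactivation", "ramp")
  if (!is.character(name) || length(name) != 1 || !(name %in% presets))
    stop("unknown protocol preset; valid presets are: ",
         paste(presets, collapse = ", "))
  step <- function(v, dur) segment("step", v, duration = dur)
  switch(name,
    activation = {
      vs <- seq(-90, 80, by = 10)
      voltage_protocol("activation",
        lapply(vs, function(v) rbind(step(-80, 100), step(v, 500),
                                     step(-80, 100))),
        sweep_labels = vs)
    },
    deactivation = {
      vs <- seq(-80, 30, by = 10)
      voltage_protocol("deactivation",
        lapply(vs, function(v) rbind(step(-80, 100), step(70, 300),
                                     step(v, 300), step(-80, 100))),
        sweep_labels = vs)
    },
    inactivation = {
      vs <- seq(-40, 70, by = 10)
      voltage_protocol("inactivation",
        lapply(vs, function(v) rbind(step(-80, 100), step(v, 1500),
                                     step(30, 100), step(-80, 100))),
        sweep_labels = vs)
    },
    ramp = {
      half <- function(dur) dur / 2
      segs <- list(step(-80, 100))
      for (dur in c(400, 200, 100, 50)) {
        segs <- c(segs, list(
          segment("ramp", ramp_from, ramp_to, half(dur)),
          segment("ramp", ramp_to, ramp_from, half(dur)),
          step(ramp_from, 400)))
      }
      segs <- c(segs, list(step(-80, 100)))
      voltage_protocol("ramp", list(do.call(rbind, segs)),
                       sweep_labels = ramp_to)
    })
}

#' Restrict a protocol to a subset of sweeps
#'
#' @param protocol A [voltage_protocol()].
#' @param labels Sweep labels (mV) to keep.
#' @return A [voltage_protocol()] with only the selected sweeps.
#' @export
subset_protocol <- function(protocol, labels) {
  keep <- protocol$sweep_labels %in% labels
  if (!any(keep)) stop("no sweeps match the requested labels")
  voltage_protocol(protocol$name, protocol$sweeps[keep],
                   protocol$sweep_labels[keep])
}

#' Sample a protocol onto a regular time grid
#'
#' Converts a protocol to a sampled stimulus: a shared time axis (ms) and a
#' sweep-by-sample voltage matrix. Steps are held at `v_start`; ramps are
#' linearly interpolated. Segment edges are half-open: the sample falling
#' exactly on a transition time takes the value of the new segment.
#'
#' @param protocol A [voltage_protocol()].
#' @param dt Sampling interval in ms. Must divide every segment duration
#'   (to within 1e-6 ms). Default 0.05 ms (20 kHz), which resolves the
#'   fastest Kv1.1 gating time constants (~0.1 ms) with at least two samples.
#' @return An object of class `sampled_stimulus`: list with `dt`, `time`
#'   (length n vector), `voltage` (sweeps x n matrix), `sweep_labels`,
#'   `protocol_name`.
#' @export
sample_protocol <- function(protocol, dt = 0.05) {
  stopifnot(inherits(protocol, "voltage_protocol"), dt > 0)
  for (sw in protocol$sweeps) {
    ratio <- sw$duration / dt
    if (any(abs(ratio - round(ratio)) > 1e-6))
      stop("dt = ", dt, " ms does not divide all segment durations")
  }
  total <- protocol_duration(protocol)
  n <- round(total / dt) + 1L
  time <- seq(0, by = dt, length.out = n)
  volt <- matrix(NA_real_, nrow = n_sweeps(protocol), ncol = n)
  for (i in seq_len(n_sweeps(protocol))) {
    sw <- protocol$sweeps[[i]]
    v <- numeric(n - 1L)
    pos <- 0L
    for (j in seq_len(nrow(sw))) {
      ns <- round(sw$duration[j] / dt)
      tt <- (seq_len(ns) - 1L) * dt
      v[pos + seq_len(ns)] <-
        if (sw$kind[j] == "step") sw$v_start[j]
        else sw$v_start[j] + (sw$v_end[j] - sw$v_start[j]) * tt /
               sw$duration[j]
      pos <- pos + ns
    }
    volt[i, ] <- c(v, sw$v_end[nrow(sw)])
  }
  structure(list(dt = dt, time = time, voltage = volt,
                 sweep_labels = protocol$sweep_labels,
                 protocol_name = protocol$name),
            class = "sampled_stimulus")
}

#' @export
print.sampled_stimulus <- function(x, ...) {
  cat(sprintf("<sampled_stimulus> %s: %d sweeps x %d samples, dt = %g ms\n",
              x$protocol_name, nrow(x$voltage), ncol(x$voltage), x$dt))
  invisible(x)
}

# segment boundaries of a sweep as sample indices (1-based, half-open)
segment_index <- function(sweep, dt, n) {
  ns <- round(sweep$duration / dt)
  ends <- cumsum(ns)
  starts <- c(0L, ends[-length(ends)]) + 1L
  # last segment also owns the final sample
  data.frame(start = starts, end = c(ends[-length(ends)], n))
}

#' Write / read a protocol as JSON
#'
#' @param protocol A [voltage_protocol()].
#' @param path File path.
#' @return `read_protocol` returns a [voltage_protocol()];
#'   `write_protocol` returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  obj <- list(name = protocol$name, sweep_labels = protocol$sweep_labels,
              sweeps = lapply(protocol$sweeps, as.list))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  voltage_protocol(obj$name, lapply(obj$sweeps, as.data.frame),
                   obj$sweep_labels)
}
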