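#' Trace set: sampled currents (and optionally voltages) per sweep
#'
#' The common container for simulated or recorded whole-cell data: a shared
#' time axis plus one current trace per sweep, with units metadata.
#'
#' @param time Time axis (ms), strictly increasing, constant spacing.
#' @param current Sweeps x samples matrix of currents.
#' @param voltage Optional sweeps x samples matrix of command voltages (mV).
#' @param sweep_labels Numeric label per sweep (mV).
#' @param unit Current unit, e.g. `"nA"` or `"norm"`.
#' @param protocol_name Name of the generating protocol.
#' @param extra Optional named list of extras (e.g. gate or state
#'   occupancy trajectories).
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(time, current, voltage = NULL, sweep_labels = NULL,
                      unit = "nA", protocol_name = "", extra = list()) {
  current <- rbind(current)
  stopifnot(length(time) == ncol(current))
  dts <- diff(time)
  if (any(dts <= 0) || diff(range(dts)) > 1e-6)
    stop("time must be strictly increasing with constant spacing")
  if (!is.null(voltage)) {
    voltage <- rbind(voltage)
    stopifnot(dim(voltage) == dim(current))
  }
  if (is.null(sweep_labels)) sweep_labels <- seq_len(nrow(current))
  stopifnot(length(sweep_labels) == nrow(current))
  structure(list(time = time, current = current, voltage = voltage,
                 sweep_labels = as.numeric(sweep_labels), unit = unit,
                 protocol_name = protocol_name, dt = dts[1], extra = extra),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %s: %d sweeps x %d samples, dt = %g ms, unit = %s\n",
              x$protocol_name, nrow(x$current), ncol(x$current), x$dt,
              x$unit))
  invisible(x)
}

#' Write a trace set to delimited text
#'
#' The file format is CSV with a commented YAML-style header carrying the
#' metadata (protocol name, dt, unit, sweep labels), then a `time` column
#' and one current column per sweep. Values are written with full precision
#' so that [read_traces()] round-trips exactly.
#'
#' @param traces A [trace_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# kv11sim_traces: 1",
    paste0("# protocol: ", traces$protocol_name),
    paste0("# dt_ms: ", sprintf("%.17g", traces$dt)),
    paste0("# unit: ", traces$unit),
    paste0("# sweep_labels_mV: ",
           paste(sprintf("%.17g", traces$sweep_labels), collapse = " "))),
    con)
  header <- c("time_ms", paste0("sweep_", seq_len(nrow(traces$current))))
  writeLines(paste(header, collapse = ","), con)
  body <- cbind(traces$time, t(traces$current))
  lines <- apply(body, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, con)
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#'
#' @param path File path.
#' @return A [trace_set()].
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trace file: ", path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0 || !grepl("^# kv11sim_traces", lines[1]))
    stop("not a kv11sim trace file (missing '# kv11sim_traces' header): ",
         path)
  meta <- list()
  for (ln in lines[hdr][-1]) {
    kv <- sub("^# *", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: *", "", kv)
    meta[[key]] <- val
  }
  for (k in c("protocol", "dt_ms", "unit", "sweep_labels_mV"))
    if (is.null(meta[[k]])) stop("missing header field '", k, "' in ", path)
  body <- lines[-hdr]
  if (length(body) < 2) stop("trace file has no data rows: ", path)
  cols <- strsplit(body[1], ",")[[1]]
  ncol_expect <- length(cols)
  rows <- strsplit(body[-1], ",")
  nfield <- lengths(rows)
  if (any(nfield != ncol_expect)) {
    bad <- which(nfield != ncol_expect)[1]
    stop("ragged row in ", path, " at line ",
         length(hdr) + 1 + bad, ": expected ", ncol_expect,
         " fields, found ", nfield[bad])
  }
  mat <- matrix(as.numeric(unlist(rows)), ncol = ncol_expect, byrow = TRUE)
  if (anyNA(mat)) stop("non-numeric value in trace file body: ", path)
  labels <- as.numeric(strsplit(meta$sweep_labels_mV, " +")[[1]])
  if (length(labels) != ncol_expect - 1)
    stop("column count (", ncol_expect - 1, " sweeps) does not match ",
         length(labels), " sweep labels in ", path)
  trace_set(time = mat[, 1], current = t(mat[, -1, drop = FALSE]),
            sweep_labels = labels, unit = meta$unit,
            protocol_name = meta$protocol)
}
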