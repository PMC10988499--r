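#' Construct a tension trace
#'
#' A uniformly sampled isometric-tension record from a fatigue-stimulation
#' protocol (e.g. 10 Hz indirect stimulation for 3 min), as a tibble-backed
#' object carrying the stimulation window.
#'
#' @param time Numeric vector of sample times (seconds), uniformly spaced.
#' @param tension Non-negative force samples (arbitrary units), same length.
#' @param stimulation_window Length-2 numeric `(start_s, end_s)`.
#' @return A `tension_trace` object (a tibble with columns `time_s`,
#'   `tension` and attributes).
#' @export
tension_trace <- function(time, tension, stimulation_window) {
  check_uniform_time(time)
  if (length(tension) != length(time)) abort("`time` and `tension` lengths differ")
  if (any(tension < 0)) abort("tension must be non-negative")
  check_window(stimulation_window, time)
  out <- tibble(time_s = as.numeric(time), tension = as.numeric(tension))
  structure(out, stimulation_window = as.numeric(stimulation_window),
            class = c("tension_trace", class(out)))
}

#' Construct a blood-flow trace
#'
#' Arterial blood-flow (and optionally arterial-pressure) samples bracketing
#' a stimulation bout, used for functional-hyperaemia analysis.
#'
#' @param time Numeric vector of sample times (seconds), uniformly spaced.
#' @param flow Flow in ml/min, non-negative.
#' @param pressure Optional arterial pressure (mmHg), strictly positive,
#'   sampled at the same times.
#' @param stimulation_window Length-2 numeric `(start_s, end_s)`.
#' @return A `flow_trace` object.
#' @export
flow_trace <- function(time, flow, pressure = NULL, stimulation_window) {
  check_uniform_time(time)
  if (length(flow) != length(time)) abort("`time` and `flow` lengths differ")
  if (any(flow < 0)) abort("flow must be non-negative")
  if (!is.null(pressure)) {
    if (length(pressure) != length(time)) abort("`pressure` length differs from `time`")
    if (any(pressure <= 0)) abort("pressure must be strictly positive throughout")
  }
  check_window(stimulation_window, time)
  out <- tibble(time_s = as.numeric(time), flow = as.numeric(flow))
  if (!is.null(pressure)) out$pressure <- as.numeric(pressure)
  structure(out, stimulation_window = as.numeric(stimulation_window),
            class = c("flow_trace", class(out)))
}

check_uniform_time <- function(time) {
  if (length(time) < 2) abort("trace must contain at least two samples")
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)) {
    abort("trace time base must be uniformly increasing")
  }
  invisible(time)
}

check_window <- function(w, time) {
  if (length(w) != 2 || w[2L] <= w[1L]) {
    abort("`stimulation_window` must be (start_s, end_s) with end > start")
  }
  if (w[1L] < time[1L] || w[2L] > time[length(time)]) {
    abort("stimulation window must lie inside the trace")
  }
  invisible(w)
}

#' Stimulation window of a trace
#' @param trace A `tension_trace` or `flow_trace`.
#' @return Length-2 numeric `(start_s, end_s)`.
#' @export
stimulation_window <- function(trace) attr(trace, "stimulation_window")

#' Read a sampled trace from CSV
#'
#' Expects columns `time_s,value` (tension or flow); an optional second CSV
#' supplies pressure for flow traces.
#'
#' @param path CSV with columns `time_s,value`.
#' @param type `"tension"` or `"flow"`.
#' @param stimulation_window Length-2 numeric (seconds).
#' @param pressure_path Optional CSV `time_s,value` with pressure (mmHg);
#'   must share the time base.
#' @return A `tension_trace` or `flow_trace`.
#' @export
read_trace <- function(path, type = c("tension", "flow"),
                       stimulation_window, pressure_path = NULL) {
  type <- match.arg(type)
  tb <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), value = readr::col_double()
  ), progress = FALSE)
  if (type == "tension") {
    tension_trace(tb$time_s, tb$value, stimulation_window)
  } else {
    pressure <- NULL
    if (!is.null(pressure_path)) {
      pb <- readr::read_csv(pressure_path, col_types = readr::cols(
        time_s = readr::col_double(), value = readr::col_double()
      ), progress = FALSE)
      if (!isTRUE(all.equal(pb$time_s, tb$time_s))) {
        abort("pressure trace time base must match the flow trace")
      }
      pressure <- pb$value
    }
    flow_trace(tb$time_s, tb$flow %||% tb$value, pressure, stimulation_window)
  }
}

#' Write a trace to CSV
#'
#' @param trace A `tension_trace` or `flow_trace`.
#' @param path Output CSV path (`time_s,value`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  value <- if (inherits(trace, "tension_trace")) trace$tension else trace$flow
  write_csv_full(tibble(time_s = trace$time_s, value = value), path)
  invisible(path)
}
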