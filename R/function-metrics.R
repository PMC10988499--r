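#' Detect twitch peaks in a tension trace
#'
#' Finds local maxima above 10% of the global maximum, separated by at
#' least `min_separation` seconds (default half the stimulation period, so
#' one peak per twitch at the protocol frequency). Candidates are scanned in
#' decreasing amplitude order and accepted greedily, so of two maxima closer
#' than the separation the taller wins.
#'
#' @param trace A [tension_trace()].
#' @param stim_freq_hz Stimulation frequency (Hz), used for the default
#'   separation `0.5 / stim_freq_hz`.
#' @param min_separation Minimum peak separation in seconds.
#' @param min_peaks Minimum acceptable number of peaks (default 10: the
#'   fatigue index needs five early plus five late twitches).
#' @return Integer vector of sample indices of the accepted peaks, in time
#'   order.
#' @export
detect_twitch_peaks <- function(trace, stim_freq_hz = 10,
                                min_separation = 0.5 / stim_freq_hz,
                                min_peaks = 10L) {
  stopifnot(inherits(trace, "tension_trace"))
  y <- trace$tension
  n <- length(y)
  gmax <- max(y)
  if (gmax <= 0) abort("flat or empty tension trace: no twitch peaks")
  thr <- 0.1 * gmax
  is_local_max <- c(FALSE, y[2:(n - 1L)] > y[1:(n - 2L)] &
                      y[2:(n - 1L)] >= y[3:n], FALSE)
  cand <- which(is_local_max & y > thr)
  if (length(cand)) {
    dt <- trace$time_s[2L] - trace$time_s[1L]
    sep <- max(1L, as.integer(round(min_separation / dt)))
    keep <- logical(length(cand))
    taken <- integer(0)
    for (k in order(y[cand], decreasing = TRUE)) {
      if (!length(taken) || all(abs(cand[k] - taken) >= sep)) {
        keep[k] <- TRUE
        taken <- c(taken, cand[k])
      }
    }
    cand <- sort(cand[keep])
  }
  if (length(cand) < min_peaks) {
    abort(sprintf(
      "only %d twitch peaks detected (need >= %d for fatigue analysis)",
      length(cand), min_peaks))
  }
  cand
}

#' Fatigue index of a tension trace
#'
#' FI = final tension / peak tension, each taken as the mean of five
#' consecutive twitch peak amplitudes: "final" the last five detected
#' twitches, "peak" the five consecutive twitches with the greatest mean
#' anywhere in the protocol (robust to delayed potentiation; for a
#' monotonically fatiguing trace this is the initial five). Reported both
#' as a ratio and in the x100 percentage form.
#'
#' @inheritParams detect_twitch_peaks
#' @return One-row tibble: `FI` (ratio), `FI_pct`, `peak_tension`,
#'   `final_tension`, plus list-columns `peak_indices_used` and
#'   `final_indices_used` (sample indices of the five twitches used).
#' @export
fatigue_index <- function(trace, stim_freq_hz = 10,
                          min_separation = 0.5 / stim_freq_hz) {
  peaks <- detect_twitch_peaks(trace, stim_freq_hz, min_separation)
  amps <- trace$tension[peaks]
  np <- length(amps)
  run_means <- vapply(seq_len(np - 4L), function(i) mean(amps[i:(i + 4L)]),
                      numeric(1))
  best <- which.max(run_means)
  peak_tension <- run_means[best]
  final_idx <- (np - 4L):np
  final_tension <- mean(amps[final_idx])
  fi <- final_tension / peak_tension
  tibble(
    FI = fi, FI_pct = 100 * fi,
    peak_tension = peak_tension, final_tension = final_tension,
    n_twitches = np,
    peak_indices_used = list(peaks[best:(best + 4L)]),
    final_indices_used = list(peaks[final_idx])
  )
}

#' Relative conductance and functional hyperaemia
#'
#' Expresses a blood-flow trace as vascular conductance (flow / pressure;
#' when pressure is absent the flow itself is used, with a message) relative
#' to its pre-stimulation baseline mean, and computes the functional
#' hyperaemia ratio: maximum smoothed flow in or after the stimulation
#' window divided by the baseline mean flow. Smoothing is a centred moving
#' average (default 1 s).
#'
#' @param flow A [flow_trace()].
#' @param smooth_s Smoothing window (seconds) for peak-flow detection.
#' @return A list with `series` (tibble: `time_s`, `relative_conductance`)
#'   and `summary` (one-row tibble: `hyperaemia_ratio`,
#'   `baseline_flow`, `peak_flow`, `used_pressure`).
#' @export
relative_conductance <- function(flow, smooth_s = 1) {
  stopifnot(inherits(flow, "flow_trace"))
  win <- stimulation_window(flow)
  pre <- flow$time_s < win[1L]
  if (!any(pre)) abort("no pre-stimulation baseline samples before the window")
  used_pressure <- "pressure" %in% names(flow)
  cond <- if (used_pressure) flow$flow / flow$pressure else flow$flow
  if (!used_pressure) {
    rlang::inform("no pressure trace: using flow as a conductance proxy")
  }
  base_cond <- mean(cond[pre])
  if (base_cond <= 0) abort("baseline conductance is zero; cannot normalise")
  series <- tibble(time_s = flow$time_s, relative_conductance = cond / base_cond)

  dt <- flow$time_s[2L] - flow$time_s[1L]
  k <- max(1L, as.integer(round(smooth_s / dt)))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- as.numeric(stats::filter(flow$flow, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- flow$flow[is.na(sm)]
  base_flow <- mean(flow$flow[pre])
  if (base_flow <= 0) abort("baseline flow is zero; cannot form hyperaemia ratio")
  during_after <- flow$time_s >= win[1L]
  peak_flow <- max(sm[during_after])
  list(
    series = series,
    summary = tibble(hyperaemia_ratio = peak_flow / base_flow,
                     baseline_flow = base_flow, peak_flow = peak_flow,
                     used_pressure = used_pressure)
  )
}
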