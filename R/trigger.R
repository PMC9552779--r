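#' Configuration of the closed-loop phase trigger
#'
#' Emulates the real-time system that locks test-cue presentation to
#' respiratory phase transitions: the airflow stream is causally low-pass
#' filtered, a trigger fires at every `every_n`-th baseline crossing in the
#' configured direction, and the cue appears `const_delay` plus a randomly
#' ordered lag (0/350/700 ms) after the trigger. The 0.27-s tube delay is
#' part of `const_delay` (0.27 tube + 0.4 mechanical = 0.67 s), matching the
#' apparatus bookkeeping rather than a shifted trace.
#'
#' @param mode `"EI"` (cue locked to inspiration onsets) or `"IE"`.
#' @param every_n fire once every `every_n` transitions (default 2).
#' @param lag_set candidate lags after the trigger, seconds.
#' @param const_delay constant trigger-to-cue delay, seconds (default 0.67).
#' @param stream_cutoff causal low-pass cutoff, Hz (default 2).
#' @param refractory minimum spacing between detected crossings, seconds;
#'   suppresses chatter of the causal filter around the baseline.
#' @return a `trigger_config` list.
#' @export
trigger_config <- function(mode = c("EI", "IE"), every_n = 2,
                           lag_set = c(0, 0.350, 0.700), const_delay = 0.67,
                           stream_cutoff = 2, refractory = 0.3) {
  mode <- match.arg(mode)
  if (every_n < 1) stop("'every_n' must be >= 1")
  if (const_delay < 0) stop("'const_delay' must be >= 0")
  structure(list(mode = mode, every_n = as.integer(every_n),
                 lag_set = lag_set, const_delay = const_delay,
                 stream_cutoff = stream_cutoff, refractory = refractory),
            class = "trigger_config")
}

#' Causal (streaming) detection of baseline crossings
#'
#' The real-time path: a 2nd-order Butterworth low-pass applied forward only
#' (no lookahead), with an event emitted at the first sample where the
#' filtered value crosses the baseline in the configured direction. The
#' causal filter's phase delay is part of the emulated phase-locking error,
#' as in the physical apparatus. A flat signal yields no events.
#'
#' @param trace a [resp_trace()] presented as an ordered stream.
#' @param config a [trigger_config()].
#' @return numeric vector of event times (seconds); may be empty.
#' @export
stream_detect <- function(trace, config = trigger_config()) {
  stopifnot(inherits(trace, "resp_trace"))
  nyq <- trace$sample_rate / 2
  bf <- signal::butter(2, config$stream_cutoff / nyq, type = "low")
  x <- as.numeric(signal::filter(bf, trace$samples - trace$baseline))
  n <- length(x)
  if (n < 2) return(numeric(0))
  idx <- if (config$mode == "EI") {
    which(x[-n] <= 0 & x[-1] > 0) + 1L
  } else {
    which(x[-n] >= 0 & x[-1] < 0) + 1L
  }
  tt <- trace_times(trace)[idx]
  if (length(tt) == 0) return(numeric(0))
  # refractory is relative to the last *kept* event
  out <- tt[1]
  for (t in tt[-1]) if (t - out[length(out)] >= config$refractory) out <- c(out, t)
  out
}

#' Schedule phase-locked cue times from crossing events
#'
#' Every `every_n`-th event (starting with the first) fires a trigger; the
#' cue time is the event time plus `const_delay` plus a lag drawn from
#' `lag_set`. Lags are drawn in shuffled complete sets ("random order"
#' without replacement per set), seedable.
#'
#' @param events numeric vector of crossing-event times (from
#'   [stream_detect()] or a ground-truth series).
#' @param config a [trigger_config()].
#' @param n_needed number of cue times required.
#' @param seed integer seed for the lag order.
#' @return a data.frame with `trigger_time`, `lag`, `cue_time`.
#' @export
schedule_triggers <- function(events, config = trigger_config(), n_needed,
                              seed = 1L) {
  events <- sort(as.numeric(events))
  anchors <- events[seq(1, length(events), by = config$every_n)]
  if (length(anchors) < n_needed) {
    stop(sprintf("event stream exhausted: %d triggers available, %d cues needed",
                 length(anchors), n_needed))
  }
  anchors <- anchors[seq_len(n_needed)]
  set.seed(seed)
  k <- length(config$lag_set)
  lags <- unlist(lapply(seq_len(ceiling(n_needed / k)),
                        function(i) sample(config$lag_set, k)))[seq_len(n_needed)]
  data.frame(trigger_time = anchors, lag = lags,
             cue_time = anchors + config$const_delay + lags)
}
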