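#' Parameters for respiratory transition detection
#'
#' Onsets of inspiration (EI transition) and expiration (IE transition) are
#' defined as the time at which flow first crosses the baseline level and
#' subsequently deviates from it by more than `sd_multiplier` times the noise
#' standard deviation, so that sub-threshold wiggles around the baseline are
#' not counted as phase transitions.
#'
#' @param sd_multiplier excursion gate in noise SDs (default 2).
#' @param lowpass_cutoff low-pass cutoff for detection, Hz (default 2).
#' @param min_phase_dur minimum credible phase duration, seconds; crossings
#'   closer than this to the previous accepted transition are merged.
#' @param baseline_window leading window (seconds) used to estimate the
#'   baseline when the trace does not declare one.
#' @return a `detection_params` list.
#' @export
detection_params <- function(sd_multiplier = 2, lowpass_cutoff = 2,
                             min_phase_dur = 0.2, baseline_window = 5) {
  if (sd_multiplier <= 0) stop("'sd_multiplier' must be positive")
  structure(list(sd_multiplier = sd_multiplier,
                 lowpass_cutoff = lowpass_cutoff,
                 min_phase_dur = min_phase_dur,
                 baseline_window = baseline_window),
            class = "detection_params")
}

#' Respiratory phase-transition series
#'
#' Ordered, strictly alternating EI (inspiration onset) and IE (expiration
#' onset) event times.
#'
#' @param time numeric vector of transition times (seconds), strictly
#'   increasing.
#' @param kind character vector, `"EI"` or `"IE"`, strictly alternating.
#' @return an object of class `resp_phase_series` (a data.frame).
#' @export
resp_phase_series <- function(time, kind) {
  kind <- as.character(kind)
  if (length(time) != length(kind)) stop("'time' and 'kind' lengths differ")
  if (length(time) && any(diff(time) <= 0)) {
    stop("transition times must be strictly increasing")
  }
  if (!all(kind %in% c("EI", "IE"))) stop("kinds must be 'EI' or 'IE'")
  if (length(kind) > 1 && any(kind[-1] == kind[-length(kind)])) {
    stop("transition kinds must strictly alternate")
  }
  structure(data.frame(time = time, kind = kind, stringsAsFactors = FALSE),
            class = c("resp_phase_series", "data.frame"))
}

#' @export
print.resp_phase_series <- function(x, ...) {
  cat(sprintf("<resp_phase_series> %d transitions (%d EI, %d IE)\n",
              nrow(x), sum(x$kind == "EI"), sum(x$kind == "IE")))
  if (nrow(x)) cat(sprintf("  span: %.3f - %.3f s\n", x$time[1], x$time[nrow(x)]))
  invisible(x)
}

#' Detect respiratory phase transitions offline
#'
#' The trace is low-pass filtered (zero-phase), then each baseline crossing
#' is accepted as a transition only if the following excursion exceeds the
#' baseline by more than `sd_multiplier` noise SDs: upward crossings are EI
#' transitions (inspiration onsets), downward crossings IE transitions.
#' Crossing time is the first sample past the baseline. The output strictly
#' alternates; same-direction repeats and crossings closer than
#' `min_phase_dur` to the previous accepted one are discarded.
#'
#' The noise SD is estimated as the SD of the high-frequency residual
#' (raw minus filtered trace), which is available even when the recording
#' starts mid-breath and contains no quiet calibration segment.
#'
#' @param trace a [resp_trace()].
#' @param params a [detection_params()].
#' @return a [resp_phase_series()].
#' @export
detect_transitions <- function(trace, params = detection_params()) {
  stopifnot(inherits(trace, "resp_trace"))
  filt <- lowpass(trace, cutoff = params$lowpass_cutoff)
  noise_sd <- sd(trace$samples - filt$samples)
  x <- filt$samples - trace$baseline
  if (all(abs(x) < .Machine$double.eps^.5)) {
    stop("flat signal: no baseline crossings found")
  }
  thr <- params$sd_multiplier * noise_sd

  n <- length(x)
  up   <- which(x[-n] <= 0 & x[-1] > 0) + 1L
  down <- which(x[-n] >= 0 & x[-1] < 0) + 1L
  if (length(up) == 0 && length(down) == 0) stop("no baseline crossings found")
  idx  <- c(up, down)
  kind <- rep(c("EI", "IE"), c(length(up), length(down)))
  o <- order(idx)
  idx <- idx[o]; kind <- kind[o]

  # excursion between this crossing and the next (or end): must beat the gate
  seg_end <- c(idx[-1] - 1L, n)
  ok <- vapply(seq_along(idx), function(i) {
    seg <- x[idx[i]:seg_end[i]]
    if (kind[i] == "EI") max(seg) > thr else min(seg) < -thr
  }, logical(1))
  idx <- idx[ok]; kind <- kind[ok]
  if (length(idx) < 2) stop("fewer than two valid transitions detected")

  tt <- trace_times(trace)[idx]
  keep <- logical(length(idx))
  keep[1] <- TRUE
  last <- 1L
  for (i in seq_along(idx)[-1]) {
    if (kind[i] != kind[last] && tt[i] - tt[last] >= params$min_phase_dur) {
      keep[i] <- TRUE
      last <- i
    }
  }
  resp_phase_series(tt[keep], kind[keep])
}

#' Per-breath metrics and respiratory frequency
#'
#' A breath (cycle) runs from one EI transition to the next; its inspiratory
#' duration is the time to the intervening IE transition, its tidal amplitude
#' the maximum absolute excursion of the raw trace from baseline within the
#' cycle. Respiratory frequency is complete breaths per minute of elapsed
#' cycle time.
#'
#' @param series a [resp_phase_series()].
#' @param trace the raw [resp_trace()] (amplitudes are measured on the raw
#'   waveform); may be `NULL`, in which case amplitudes are `NA`.
#' @return a list with `breaths` (data.frame: onset, insp_dur, exp_dur,
#'   duration, amplitude) and `frequency` (breaths/min).
#' @export
breath_metrics <- function(series, trace = NULL) {
  stopifnot(inherits(series, "resp_phase_series"))
  if (nrow(series) < 3) stop("need at least one complete cycle (>= 3 transitions)")
  ei <- which(series$kind == "EI")
  # complete cycles: EI ... IE ... EI
  ei <- ei[ei + 2 <= nrow(series)]
  if (length(ei) == 0) stop("no complete EI-to-EI cycle in series")
  onset <- series$time[ei]
  t_ie  <- series$time[ei + 1]
  t_end <- series$time[ei + 2]
  insp <- t_ie - onset
  expd <- t_end - t_ie
  amp <- rep(NA_real_, length(ei))
  if (!is.null(trace)) {
    tt <- trace_times(trace)
    # cycles are contiguous (each ends where the next begins)
    breaks <- c(onset, t_end[length(t_end)])
    ci <- findInterval(tt, breaks)
    sel <- ci >= 1 & ci <= length(onset) & tt < breaks[length(breaks)]
    mx <- tapply(abs(trace$samples[sel] - trace$baseline), ci[sel], max)
    amp[as.integer(names(mx))] <- mx
  }
  breaths <- data.frame(onset = onset, insp_dur = insp, exp_dur = expd,
                        duration = insp + expd, amplitude = amp)
  freq <- nrow(breaths) / (sum(breaths$duration) / 60)
  list(breaths = breaths, frequency = freq)
}

#' Flag sighs in a breath table
#'
#' A sigh is a breath whose tidal amplitude is at least twice the mean tidal
#' amplitude of its period (the mean includes the breath itself). Flags are
#' therefore scale-invariant.
#'
#' @param breaths a breath table from [breath_metrics()] (needs `amplitude`).
#' @param period optional grouping vector (one label per breath, e.g. task
#'   epoch); `NULL` treats all breaths as one period.
#' @return logical vector of sigh flags.
#' @export
detect_sighs <- function(breaths, period = NULL) {
  stopifnot(is.data.frame(breaths), "amplitude" %in% names(breaths))
  if (nrow(breaths) == 0) stop("empty breath table")
  if (is.null(period)) period <- rep(1L, nrow(breaths))
  if (length(period) != nrow(breaths)) stop("'period' length mismatch")
  flags <- logical(nrow(breaths))
  for (p in unique(period)) {
    sel <- period == p
    m <- mean(breaths$amplitude[sel])
    flags[sel] <- breaths$amplitude[sel] >= 2 * m
  }
  flags
}

#' Lag-1 autocorrelation of breath durations
#'
#' Pearson correlation between consecutive total breath durations; an index
#' of breath-to-breath regularity (respiratory correlated variability).
#'
#' @param durations numeric vector of total breath durations (seconds).
#' @return correlation in \[-1, 1\].
#' @export
lag1_autocorr <- function(durations) {
  n <- length(durations)
  if (n < 3) stop("need at least 3 breaths")
  x <- durations[-n]; y <- durations[-1]
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in durations")
  cor(x, y)
}

#' Respiration volume per time (RVT) on the scan grid
#'
#' Instantaneous RVT is the breath's peak-to-trough envelope difference
#' divided by its period (Birn-style), evaluated at breath midpoints and
#' linearly interpolated onto the trace grid. The scan-grid value for scan k
#' is the mean of this signal over the window
#' `[scan_start + k*tr - delay, scan_start + (k+1)*tr - delay)`, i.e. each
#' scan reflects respiration `delay` seconds earlier.
#'
#' @param trace a [resp_trace()].
#' @param series a [resp_phase_series()] for the trace.
#' @param tr scan repetition time, seconds (default 0.8).
#' @param delay hemodynamic delay of the respiratory effect, seconds
#'   (default 5.6).
#' @param n_scans number of scan windows.
#' @param scan_start time of the first scan window start, seconds.
#' @return an `rvt_series` list with `values`, `tr`, `delay`.
#' @export
compute_rvt <- function(trace, series, tr = 0.8, delay = 5.6, n_scans,
                        scan_start = 0) {
  stopifnot(inherits(trace, "resp_trace"), inherits(series, "resp_phase_series"))
  bm <- breath_metrics(series, trace)
  br <- bm$breaths
  tt <- trace_times(trace)
  # envelope difference: peak minus trough of the raw waveform within each cycle
  breaks <- c(br$onset, br$onset[nrow(br)] + br$duration[nrow(br)])
  ci <- findInterval(tt, breaks)
  sel <- ci >= 1 & ci <= nrow(br) & tt < breaks[length(breaks)]
  mx <- tapply(trace$samples[sel], ci[sel], max)
  mn <- tapply(trace$samples[sel], ci[sel], min)
  pk <- rep(NA_real_, nrow(br))
  pk[as.integer(names(mx))] <- mx - mn
  inst <- pk / br$duration
  mid <- br$onset + br$duration / 2
  rvt_t <- approx(mid, inst, xout = tt, rule = 2)$y

  w0 <- scan_start + (seq_len(n_scans) - 1) * tr - delay
  if (min(w0) < tt[1] || max(w0) + tr > tt[length(tt)]) {
    stop("scan grid (shifted by 'delay') extends beyond the trace")
  }
  fs <- trace$sample_rate
  wlen <- max(1L, round(tr * fs))
  i0 <- pmax(1L, round((w0 - trace$start_time) * fs) + 1L)
  vals <- vapply(seq_along(w0), function(k) {
    mean(rvt_t[i0[k]:min(i0[k] + wlen - 1L, length(rvt_t))])
  }, numeric(1))
  structure(list(values = vals, tr = tr, delay = delay,
                 method = "envelope-difference over period"),
            class = "rvt_series")
}
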