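#' Respiratory trace container
#'
#' A uniformly sampled airflow/pressure recording. The baseline is the
#' room-pressure level measured before the task; flow values are relative to
#' arbitrary sensor units.
#'
#' @param samples numeric vector of flow/pressure values.
#' @param sample_rate sampling frequency in Hz.
#' @param start_time time of the first sample, in seconds.
#' @param baseline baseline (zero-flow) level in the units of `samples`.
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(samples, sample_rate, start_time = 0, baseline = 0) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("'samples' must be non-empty")
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("'sample_rate' must be a positive number")
  }
  if (!is.finite(baseline)) stop("'baseline' must be finite")
  structure(
    list(samples = samples, sample_rate = sample_rate,
         start_time = start_time, baseline = baseline),
    class = "resp_trace"
  )
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %d samples @ %g Hz, t = [%.3f, %.3f] s, baseline %g\n",
              length(x$samples), x$sample_rate, x$start_time,
              x$start_time + (length(x$samples) - 1) / x$sample_rate,
              x$baseline))
  invisible(x)
}

#' Sample times of a respiratory trace
#' @param trace a [resp_trace()].
#' @return numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  trace$start_time + (seq_along(trace$samples) - 1) / trace$sample_rate
}

trace_duration <- function(trace) length(trace$samples) / trace$sample_rate

#' Compensate the acquisition lag of the airflow signal
#'
#' Nasal-cannula recordings arrive with a constant delay (tubing plus sensor
#' mechanics); this shifts all timestamps earlier by `lag` so that the trace
#' is aligned with the stimulus/response clock. Sample values are unchanged.
#'
#' @param trace a [resp_trace()].
#' @param lag constant delay to remove, seconds (default 0.27, the delay of a
#'   6-m cannula extension tube).
#' @return the lag-compensated `resp_trace`.
#' @export
compensate_lag <- function(trace, lag = 0.27) {
  stopifnot(inherits(trace, "resp_trace"))
  if (!is.finite(lag) || lag < 0) stop("'lag' must be a non-negative number")
  if (lag > trace_duration(trace)) {
    stop("'lag' exceeds the trace duration")
  }
  trace$start_time <- trace$start_time - lag
  trace
}

#' Zero-phase low-pass filter of a respiratory trace
#'
#' Offline filtering to isolate the respiratory cycle from sensor noise,
#' realized as a 4th-order Butterworth applied forward and backward
#' (zero-phase), so detected onset times are not biased by filter delay.
#'
#' @param trace a [resp_trace()].
#' @param cutoff cutoff frequency in Hz (default 2).
#' @param order filter order (default 4).
#' @return a `resp_trace` with the same grid and filtered samples.
#' @export
lowpass <- function(trace, cutoff = 2, order = 4) {
  stopifnot(inherits(trace, "resp_trace"))
  nyq <- trace$sample_rate / 2
  if (cutoff >= nyq) stop("'cutoff' must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  # filtfilt needs the signal demeaned around baseline to limit edge transients
  x <- trace$samples - trace$baseline
  y <- signal::filtfilt(bf, x)
  trace$samples <- y + trace$baseline
  trace
}

# ---- BIDS-style physiological recording IO ---------------------------------

#' Write a respiratory trace as BIDS-style physio files
#'
#' Writes `<prefix>_physio.tsv.gz` (columns `time`, `flow`) and a JSON
#' sidecar `<prefix>_physio.json` with `SamplingFrequency`, `StartTime`,
#' `Columns`, and the baseline level.
#'
#' @param trace a [resp_trace()].
#' @param prefix file path prefix (directory must exist).
#' @return invisibly, the two paths written.
#' @export
write_physio <- function(trace, prefix) {
  stopifnot(inherits(trace, "resp_trace"))
  tsv <- paste0(prefix, "_physio.tsv.gz")
  js  <- paste0(prefix, "_physio.json")
  con <- gzfile(tsv, "w")
  on.exit(close(con), add = TRUE)
  df <- data.frame(time = trace_times(trace), flow = trace$samples)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(SamplingFrequency = trace$sample_rate,
               StartTime = trace$start_time,
               Columns = c("time", "flow"),
               Baseline = trace$baseline)
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}

#' Read a respiratory trace from BIDS-style physio files or plain CSV
#'
#' For `<prefix>_physio.tsv.gz` + sidecar use the prefix; a path ending in
#' `.csv` is read as a two-column (time, value) table with the sampling rate
#' inferred from the time column.
#'
#' @param path file prefix (BIDS) or a `.csv` path.
#' @param baseline baseline override; if `NULL`, taken from the sidecar (or 0).
#' @return a [resp_trace()].
#' @export
read_physio <- function(path, baseline = NULL) {
  if (grepl("\\.csv$", path)) {
    df <- read.table(path, header = TRUE, sep = ",")
    dt <- diff(df[[1]])
    if (any(dt <= 0)) stop("time column must be strictly increasing")
    fs <- 1 / median(dt)
    return(resp_trace(df[[2]], sample_rate = fs, start_time = df[[1]][1],
                      baseline = if (is.null(baseline)) 0 else baseline))
  }
  tsv <- paste0(path, "_physio.tsv.gz")
  js  <- paste0(path, "_physio.json")
  if (!file.exists(tsv)) stop("physio file not found: ", tsv)
  side <- if (file.exists(js)) jsonlite::read_json(js) else list()
  con <- gzfile(tsv, "r")
  on.exit(close(con), add = TRUE)
  df <- read.table(con, header = TRUE, sep = "\t")
  fs <- side$SamplingFrequency
  if (is.null(fs)) fs <- 1 / median(diff(df$time))
  t0 <- if (!is.null(side$StartTime)) side$StartTime else df$time[1]
  bl <- if (!is.null(baseline)) baseline
        else if (!is.null(side$Baseline)) side$Baseline else 0
  resp_trace(df$flow, sample_rate = as.numeric(fs), start_time = as.numeric(t0),
             baseline = as.numeric(bl))
}

#' Write a task event table as a BIDS-style events TSV
#' @param events a data.frame with at least `onset` and `duration` columns.
#' @param path output path (`*_events.tsv`).
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events), all(c("onset", "duration") %in% names(events)))
  write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a task event table
#' @param path an events TSV/CSV path.
#' @return a data.frame.
#' @export
read_events <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}
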