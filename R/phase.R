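#' Project an event time onto the circular respiratory phase
#'
#' Phase angle in degrees: 0-180 spans the inspiration containing the event
#' (piecewise-linear from its EI onset to the IE transition), 180-360 spans
#' the expiration (IE to the next EI). Continuous at 180 and wraps to 0 at
#' each detected EI onset. Angles therefore stretch/compress with the actual
#' phase durations of the breath the event falls in.
#'
#' @param t numeric vector of event times, seconds; each must lie within a
#'   complete detected cycle.
#' @param series a [resp_phase_series()].
#' @return numeric vector of angles in `[0, 360)`.
#' @export
project_phase <- function(t, series) {
  stopifnot(inherits(series, "resp_phase_series"))
  tt <- series$time
  kk <- series$kind
  idx <- findInterval(t, tt)
  bad <- idx < 1 | idx >= length(tt)
  if (any(bad)) {
    stop(sprintf("%d event time(s) outside the detected cycles", sum(bad)))
  }
  frac <- (t - tt[idx]) / (tt[idx + 1] - tt[idx])
  ifelse(kk[idx] == "EI", 180 * frac, 180 + 180 * frac) %% 360
}

#' Circular summary: mean resultant vector
#'
#' The mean resultant vector is the average of unit vectors at the event
#' phase angles; its direction is the preferred phase and its length R (in
#' \[0, 1\]) quantifies concentration — shorter means greater dispersion.
#' The circular SD is `sqrt(-2 log R)`, reported in degrees.
#'
#' @param angles numeric vector of phase angles in degrees.
#' @return a `circ_summary` list: `mean_direction` (degrees in \[0, 360)),
#'   `resultant_length`, `circular_sd` (degrees), `n`.
#' @export
circ_summary <- function(angles) {
  if (length(angles) == 0) stop("empty angle set")
  th <- angles * pi / 180
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  dir <- (atan2(S, C) * 180 / pi) %% 360
  csd <- if (R > 0) sqrt(-2 * log(R)) * 180 / pi else Inf
  structure(list(mean_direction = dir, resultant_length = R,
                 circular_sd = csd, n = length(angles)),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("<circ_summary> n=%d  direction=%.1f deg  R=%.3f  SD=%.1f deg\n",
              x$n, x$mean_direction, x$resultant_length, x$circular_sd))
  invisible(x)
}

#' Classify a cue phase angle into one of six sextiles
#'
#' Half-open 60-degree bins: three over inspiration (INS 0-60, INS 60-120,
#' INS 120-180) and three over expiration (EXP 180-240, EXP 240-300,
#' EXP 300-360).
#'
#' @param angle numeric vector of angles in `[0, 360)`.
#' @return factor with the six sextile labels.
#' @export
classify_cue_sextile <- function(angle) {
  labs <- c("INS 0-60", "INS 60-120", "INS 120-180",
            "EXP 180-240", "EXP 240-300", "EXP 300-360")
  i <- pmin(floor((angle %% 360) / 60) + 1, 6)
  factor(labs[i], levels = labs)
}

# transitions strictly inside the open interval (a, b)
transitions_inside <- function(a, b, series) {
  sel <- series$time > a & series$time < b
  series$kind[sel]
}

#' Classify a test block by the transitions it spans
#'
#' A test block runs from the test-cue presentation to the motor response.
#' Blocks containing no phase transition are INS or EXP according to the
#' phase at the cue; blocks spanning only IE transition(s) are IE, only EI
#' transition(s) EI, and blocks spanning both kinds are "Both" (excluded
#' from condition analyses downstream). Transitions exactly at the cue or
#' response instant are not counted as inside the block (open interval).
#'
#' @param cue_time,response_time numeric vectors (seconds), paired.
#' @param series a [resp_phase_series()].
#' @return factor with levels INS, IE, EXP, EI, Both.
#' @export
classify_block <- function(cue_time, response_time, series) {
  stopifnot(length(cue_time) == length(response_time))
  if (any(response_time <= cue_time)) stop("response before (or at) cue time")
  ang <- project_phase(cue_time, series)
  out <- character(length(cue_time))
  for (i in seq_along(cue_time)) {
    k <- transitions_inside(cue_time[i], response_time[i], series)
    out[i] <- if (length(k) == 0) {
      if (ang[i] < 180) "INS" else "EXP"
    } else if (all(k == "IE")) "IE"
      else if (all(k == "EI")) "EI"
      else "Both"
  }
  factor(out, levels = c("INS", "IE", "EXP", "EI", "Both"))
}

#' Seconds of expiration contained in a time interval
#'
#' Sums the overlap of `[a, b]` with the expiratory half-cycles (IE to next
#' EI) of the series. Used for the per-condition expiration-duration measure.
#'
#' @param a,b interval bounds, seconds (vectors, paired).
#' @param series a [resp_phase_series()].
#' @return numeric vector of expiration seconds.
#' @export
expiration_in_interval <- function(a, b, series) {
  stopifnot(length(a) == length(b))
  ie <- which(series$kind == "IE")
  ie <- ie[ie < nrow(series)]
  s <- series$time[ie]          # expiration starts
  e <- series$time[ie + 1]      # expiration ends (next EI)
  vapply(seq_along(a), function(i) {
    sum(pmax(0, pmin(b[i], e) - pmax(a[i], s)))
  }, numeric(1))
}

#' Per-subject condition summaries of test blocks
#'
#' Averages RT, accuracy, and expiration-duration-in-block per subject for
#' each respiratory condition, and appends a pooled INS+EXP summary (the
#' transition-free conditions combined). Subjects with zero blocks in a
#' condition appear with `n_blocks = 0` and `NA` means (flagged missing, not
#' zero). Blocks labeled "Both" and blocks without a response must be
#' excluded before calling.
#'
#' @param blocks data.frame with columns `subject`, `condition` (INS/IE/
#'   EXP/EI), `rt`, `correct` (logical), and optionally `exp_dur_in_block`.
#' @return a data.frame: subject, condition, n_blocks, mean_rt, accuracy,
#'   mean_exp_dur.
#' @export
summarize_conditions <- function(blocks) {
  stopifnot(all(c("subject", "condition", "rt", "correct") %in% names(blocks)))
  if (any(blocks$condition == "Both")) {
    stop("'Both' blocks must be excluded before summarizing")
  }
  has_exp <- "exp_dur_in_block" %in% names(blocks)
  conds <- c("INS", "IE", "EXP", "EI", "INS+EXP")
  subs <- unique(blocks$subject)
  grid <- expand.grid(subject = subs, condition = conds,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  one <- function(su, co) {
    sel <- blocks$subject == su &
      (if (co == "INS+EXP") blocks$condition %in% c("INS", "EXP")
       else blocks$condition == co)
    n <- sum(sel)
    data.frame(subject = su, condition = co, n_blocks = n,
               mean_rt = if (n) mean(blocks$rt[sel]) else NA_real_,
               accuracy = if (n) mean(blocks$correct[sel]) else NA_real_,
               mean_exp_dur = if (n && has_exp)
                 mean(blocks$exp_dur_in_block[sel]) else NA_real_)
  }
  out <- do.call(rbind, Map(one, grid$subject, grid$condition))
  rownames(out) <- NULL
  out
}

#' Cue-to-response phase shift and dispersion change
#'
#' For paired cue/response phase angles, the shift is the circular mean of
#' the per-event angular differences (response minus cue), and the
#' dispersion change is the circular SD of responses minus that of cues
#' (negative = responses more phase-concentrated than cues).
#'
#' @param cue_angles,response_angles paired numeric vectors, degrees.
#' @return a list: `shift` (degrees, in \[-180, 180)), `delta_sd` (degrees).
#' @export
cue_response_phase_shift <- function(cue_angles, response_angles) {
  if (length(cue_angles) != length(response_angles)) {
    stop("cue and response angles must be paired")
  }
  d <- (response_angles - cue_angles) %% 360
  cs <- circ_summary(d)
  shift <- cs$mean_direction
  if (shift >= 180) shift <- shift - 360
  list(shift = shift,
       delta_sd = circ_summary(response_angles)$circular_sd -
         circ_summary(cue_angles)$circular_sd)
}
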