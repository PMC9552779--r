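#' Parameters for the synthetic respiration generator
#'
#' Defaults emulate quiet nasal breathing during the task: mean inspiratory
#' duration 1.46 s and expiratory duration 2.09 s (the group means measured
#' in the study this pipeline reproduces), lognormal breath-to-breath jitter
#' with a common coefficient of variation, and occasional sighs realized as
#' single breaths with amplitude multiplier 2.5.
#'
#' @param mean_insp_dur mean inspiratory duration, seconds.
#' @param mean_exp_dur mean expiratory duration, seconds.
#' @param dur_cv coefficient of variation of phase durations (lognormal
#'   jitter; 0 gives perfectly periodic breathing).
#' @param amplitude tidal flow amplitude, arbitrary pressure units.
#' @param noise_sd white sensor noise SD, same units as `amplitude`.
#' @param sigh_prob per-breath probability of a sigh.
#' @param sigh_mult amplitude multiplier of a sigh breath (>= 2 so that sighs
#'   satisfy the twice-the-mean detection definition with margin).
#' @param sample_rate sampling rate, Hz (default 1000, the study's rate).
#' @param seed integer seed.
#' @return a `resp_gen_params` list.
#' @export
resp_gen_params <- function(mean_insp_dur = 1.46, mean_exp_dur = 2.09,
                            dur_cv = 0.1, amplitude = 1, noise_sd = 0,
                            sigh_prob = 0.01, sigh_mult = 2.5,
                            sample_rate = 1000, seed = 1L) {
  if (mean_insp_dur <= 0 || mean_exp_dur <= 0) stop("phase durations must be > 0")
  if (sigh_prob < 0 || sigh_prob >= 1) stop("'sigh_prob' must be in [0, 1)")
  if (sample_rate <= 0) stop("'sample_rate' must be > 0")
  if (dur_cv < 0) stop("'dur_cv' must be >= 0")
  structure(list(mean_insp_dur = mean_insp_dur, mean_exp_dur = mean_exp_dur,
                 dur_cv = dur_cv, amplitude = amplitude, noise_sd = noise_sd,
                 sigh_prob = sigh_prob, sigh_mult = sigh_mult,
                 sample_rate = sample_rate, seed = as.integer(seed)),
            class = "resp_gen_params")
}

# lognormal draw with given mean and CV; degenerate at the mean when cv = 0
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a ground-truth breath sequence
#'
#' Draws alternating inspiration/expiration durations (lognormal jitter) and
#' sigh flags covering at least `duration` seconds, starting with an EI
#' transition at `start_time`.
#'
#' @param params a [resp_gen_params()].
#' @param duration time span to cover, seconds.
#' @param start_time time of the first inspiration onset.
#' @return a list with `breaths` (data.frame: onset, insp_dur, exp_dur,
#'   duration, amp_mult, is_sigh) and `series` (the ground-truth
#'   [resp_phase_series()]).
#' @export
gen_breath_series <- function(params, duration, start_time = 0) {
  stopifnot(inherits(params, "resp_gen_params"))
  if (duration < 2 * (params$mean_insp_dur + params$mean_exp_dur)) {
    stop("'duration' must cover at least two full breaths")
  }
  set.seed(params$seed)
  # over-generate then trim: expected cycle length plus safety margin
  n_guess <- ceiling(duration / (params$mean_insp_dur + params$mean_exp_dur) * 1.5) + 4
  repeat {
    insp <- rlnorm_cv(n_guess, params$mean_insp_dur, params$dur_cv)
    expd <- rlnorm_cv(n_guess, params$mean_exp_dur, params$dur_cv)
    if (sum(insp + expd) >= duration) break
    n_guess <- n_guess * 2
  }
  cyc <- insp + expd
  onset <- start_time + c(0, cumsum(cyc))[seq_len(n_guess)]
  keep <- onset < start_time + duration
  insp <- insp[keep]; expd <- expd[keep]; onset <- onset[keep]
  is_sigh <- runif(length(onset)) < params$sigh_prob
  amp_mult <- ifelse(is_sigh, params$sigh_mult, 1)
  breaths <- data.frame(onset = onset, insp_dur = insp, exp_dur = expd,
                        duration = insp + expd, amp_mult = amp_mult,
                        is_sigh = is_sigh)
  tr_time <- as.vector(rbind(onset, onset + insp))
  tr_kind <- rep(c("EI", "IE"), length(onset))
  list(breaths = breaths, series = resp_phase_series(tr_time, tr_kind))
}

#' Generate a synthetic respiratory trace with ground truth
#'
#' Flow is a half-sinusoid per phase: positive during inspiration, negative
#' during expiration, scaled by the breath's amplitude multiplier, plus white
#' sensor noise. With `noise_sd = 0` the trace crosses the baseline exactly
#' at the ground-truth transitions.
#'
#' @param params a [resp_gen_params()].
#' @param duration trace length, seconds.
#' @param baseline baseline level added to the flow signal.
#' @return a list with `trace` (a [resp_trace()]), `truth` (the ground-truth
#'   [resp_phase_series()]), and `breaths` (the ground-truth breath table).
#' @export
gen_resp_trace <- function(params, duration, baseline = 0) {
  stopifnot(inherits(params, "resp_gen_params"))
  if (duration <= 0) stop("'duration' must be positive")
  min_phase <- min(params$mean_insp_dur, params$mean_exp_dur)
  if (params$sample_rate * min_phase < 4) {
    stop("'sample_rate' too low to resolve a respiratory phase (< 4 samples/phase)")
  }
  gb <- gen_breath_series(params, duration)
  br <- gb$breaths
  tt <- seq(0, duration - 1 / params$sample_rate, by = 1 / params$sample_rate)

  # per-sample phase bookkeeping via the interleaved transition times
  trans <- gb$series$time
  idx <- findInterval(tt, trans)          # 0 before first EI (empty here)
  idx[idx < 1] <- 1L
  idx[idx > length(trans)] <- length(trans)
  ph_start <- trans[idx]
  is_insp <- gb$series$kind[idx] == "EI"
  breath_i <- (idx + 1L) %/% 2L
  ph_dur <- ifelse(is_insp, br$insp_dur[breath_i], br$exp_dur[breath_i])
  frac <- pmin((tt - ph_start) / ph_dur, 1)
  flow <- params$amplitude * br$amp_mult[breath_i] *
    sin(pi * frac) * ifelse(is_insp, 1, -1)
  if (params$noise_sd > 0) flow <- flow + rnorm(length(flow), 0, params$noise_sd)

  list(trace = resp_trace(flow + baseline, params$sample_rate,
                          start_time = 0, baseline = baseline),
       truth = gb$series, breaths = br)
}
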