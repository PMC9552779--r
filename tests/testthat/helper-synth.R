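# shared fixtures, all built in code

# periodic noiseless generator settings (1.46 s inspiration, 2.09 s expiration)
periodic_params <- function(fs = 200, seed = 1) {
  resp_gen_params(dur_cv = 0, noise_sd = 0, sigh_prob = 0,
                  sample_rate = fs, seed = seed)
}

# strictly periodic hand-built transition series: EI at 0, 3.55, 7.10, ...
periodic_series <- function(n_breaths = 10, insp = 1.46, expd = 2.09) {
  onset <- (seq_len(n_breaths) - 1) * (insp + expd)
  resp_phase_series(as.vector(rbind(onset, onset + insp)),
                    rep(c("EI", "IE"), n_breaths))
}

# balanced long table with per-subject intercepts and optional condition means
balanced_table <- function(n = 25, k = 4, effect = rep(0, k), seed = 1,
                           noise_sd = 1, subject_sd = 1) {
  set.seed(seed)
  b0 <- rnorm(n, 0, subject_sd)
  data.frame(subject = rep(seq_len(n), k),
             condition = rep(paste0("c", seq_len(k)), each = n),
             value = rep(effect, each = n) + rep(b0, k) +
               rnorm(n * k, 0, noise_sd))
}

# candidate phase-locked cue times from a ground-truth series
truth_triggers <- function(series, seed = 1) {
  cfgEI <- trigger_config("EI"); cfgIE <- trigger_config("IE")
  ei <- series$time[series$kind == "EI"]
  ie <- series$time[series$kind == "IE"]
  list(EI = schedule_triggers(ei, cfgEI, ceiling(length(ei) / 2),
                              seed = seed)$cue_time,
       IE = schedule_triggers(ie, cfgIE, ceiling(length(ie) / 2),
                              seed = seed + 1)$cue_time)
}
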