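#' Configuration for a full synthetic study
#'
#' Defaults mirror the study conditions: 25 subjects, 16 epochs (8 fixed-ISI
#' + 8 phase-triggered), 1 kHz airflow sampling, 2-Hz detection low-pass
#' with a 2-SD excursion gate, trigger delay 0.67 s with 0/350/700-ms lags,
#' and planted retrieval deficits in the EI condition (+150 ms RT, -10
#' accuracy points, -0.4 d-prime). Between-subject variability: phase
#' duration means drawn around 1.46 s (inspiration) and 2.09 s (expiration).
#'
#' @param n_subjects number of synthetic subjects.
#' @param seed master seed; per-subject and per-stage seeds are derived from
#'   it deterministically.
#' @param mode `"full"` (generate and process 1-kHz airflow traces through
#'   the streaming and offline detectors) or `"fast"` (work from the
#'   ground-truth transition series; identical downstream analysis).
#' @param run_glm build and fit the toy single-run GLM (default TRUE).
#' @param spec a [session_spec()].
#' @param sample_rate airflow sampling rate, Hz (full mode).
#' @param session_duration respiration coverage per subject, seconds.
#' @param behavior a [behavior_effect_params()]; default plants the EI
#'   deficits via the signal-detection observer.
#' @param subject_sd between-subject SDs: list(rt, accuracy, dprime,
#'   insp_dur, exp_dur).
#' @param activation planted within-subject coupling between d-prime and a
#'   synthetic region "activation" covariate: list(slope, noise_sd,
#'   intercept_sd).
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return a `study_config` list.
#' @export
study_config <- function(n_subjects = 25, seed = 1L,
                         mode = c("full", "fast"), run_glm = TRUE,
                         spec = session_spec(), sample_rate = 1000,
                         session_duration = 2200,
                         behavior = study_behavior_defaults(),
                         subject_sd = list(rt = 0.1, accuracy = 0.02,
                                           dprime = 0.15, insp_dur = 0.25,
                                           exp_dur = 0.40),
                         activation = list(slope = 0.6, noise_sd = 0.35,
                                           intercept_sd = 1),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 mode = mode, run_glm = run_glm, spec = spec,
                 sample_rate = sample_rate,
                 session_duration = session_duration, behavior = behavior,
                 subject_sd = subject_sd, activation = activation,
                 out_dir = out_dir),
            class = "study_config")
}

#' Default planted behavioral effects of the synthetic study
#'
#' SDT observer with a baseline d-prime of 2.4 and condition shifts giving
#' the orderings under test: highest RT, lowest accuracy, and lowest
#' d-prime in the EI condition (blocks spanning the inspiration onset),
#' intermediate deficits in the IE condition.
#'
#' @param seed integer seed.
#' @return a [behavior_effect_params()].
#' @export
study_behavior_defaults <- function(seed = 1L) {
  behavior_effect_params(
    base_rt = 1.0,
    rt_shift_by_condition = c(INS = 0, EXP = 0.03, IE = 0.07, EI = 0.15),
    base_accuracy = 0.85,
    acc_shift_by_condition = c(INS = 0, EXP = 0, IE = -0.04, EI = -0.10),
    rt_noise_sd = 0.35,
    base_dprime = 2.4,
    dprime_shift_by_condition = c(INS = 0, EXP = 0, IE = -0.15, EI = -0.4),
    seed = seed)
}

# deterministic per-subject seed stream; stays far below .Machine$integer.max
derive_seed <- function(seed, subject, stage) {
  as.integer((as.numeric(seed) * 7919 + subject * 131 + stage) %% 2147480000)
}

#' Simulate the behavioral arm of a multi-subject study
#'
#' For each subject: draw subject-level respiratory and behavioral
#' parameters, generate the breath sequence (and in full mode the airflow
#' trace processed by the causal streaming detector and the offline
#' transition detector), schedule the phase-locked Epoch-B cues, lay out
#' the session, and simulate test blocks with the planted effects.
#'
#' @param config a [study_config()].
#' @return a list: `blocks` (all subjects), `resp` (per-subject respiratory
#'   summary), `subject1` (series/trace/events of the first subject, kept
#'   for the GLM stage).
#' @export
simulate_behavior_study <- function(config = study_config()) {
  set.seed(config$seed)
  ns <- config$n_subjects
  insp_mu <- pmax(0.7, rnorm(ns, 1.46, config$subject_sd$insp_dur))
  exp_mu <- pmax(0.9, rnorm(ns, 2.09, config$subject_sd$exp_dur))
  rt_off <- rnorm(ns, 0, config$subject_sd$rt)
  dp_off <- rnorm(ns, 0, config$subject_sd$dprime)
  acc_off <- if (is.null(config$behavior$base_dprime)) {
    rnorm(ns, 0, config$subject_sd$accuracy)
  } else {
    # SDT observer: subject ability shifts d-prime, with accuracy moved
    # coherently along the unbiased-observer curve acc = Phi(d'/2) so that
    # the (accuracy, d-prime) pair stays attainable for every subject
    dp_off * stats::dnorm(qnorm(config$behavior$base_accuracy)) / 2
  }

  blocks <- vector("list", ns)
  resp <- vector("list", ns)
  subject1 <- NULL
  for (s in seq_len(ns)) {
    rp <- resp_gen_params(mean_insp_dur = insp_mu[s], mean_exp_dur = exp_mu[s],
                          dur_cv = 0.1, sigh_prob = 0.01,
                          noise_sd = if (config$mode == "full") 0.05 else 0,
                          sample_rate = config$sample_rate,
                          seed = derive_seed(config$seed, s, 1))
    if (config$mode == "full") {
      gt <- gen_resp_trace(rp, config$session_duration)
      series <- detect_transitions(gt$trace)
      ei_ev <- stream_detect(gt$trace, trigger_config("EI"))
      ie_ev <- stream_detect(gt$trace, trigger_config("IE"))
      trace <- gt$trace
      truth_breaths <- gt$breaths
    } else {
      gb <- gen_breath_series(rp, config$session_duration)
      series <- gb$series
      ei_ev <- series$time[series$kind == "EI"]
      ie_ev <- series$time[series$kind == "IE"]
      trace <- NULL
      truth_breaths <- gb$breaths
    }
    cfgEI <- trigger_config("EI"); cfgIE <- trigger_config("IE")
    schEI <- schedule_triggers(ei_ev, cfgEI,
                               n_needed = ceiling(length(ei_ev) / cfgEI$every_n),
                               seed = derive_seed(config$seed, s, 2))
    schIE <- schedule_triggers(ie_ev, cfgIE,
                               n_needed = ceiling(length(ie_ev) / cfgIE$every_n),
                               seed = derive_seed(config$seed, s, 3))
    ev <- gen_session(config$spec,
                      triggers = list(EI = schEI$cue_time, IE = schIE$cue_time),
                      seed = derive_seed(config$seed, s, 4))
    tests <- ev[ev$trial_type == "test", ]
    bp <- config$behavior
    bp$base_rt <- bp$base_rt + rt_off[s]
    bp$base_accuracy <- bp$base_accuracy + acc_off[s]
    if (!is.null(bp$base_dprime)) bp$base_dprime <- bp$base_dprime + dp_off[s]
    bl <- simulate_test_blocks(series, tests, bp, subject = s,
                               seed = derive_seed(config$seed, s, 5))
    bl$epoch <- tests$epoch
    bl$epoch_type <- tests$epoch_type
    blocks[[s]] <- bl

    bm <- breath_metrics(series, trace)
    n_sighs <- if (all(is.na(bm$breaths$amplitude))) {
      # no trace: fall back to ground-truth amplitude multipliers
      sum(detect_sighs(data.frame(amplitude = truth_breaths$amp_mult)))
    } else {
      sum(detect_sighs(bm$breaths))
    }
    resp[[s]] <- data.frame(
      subject = s, n_breaths = nrow(bm$breaths),
      mean_insp_dur = mean(bm$breaths$insp_dur),
      mean_exp_dur = mean(bm$breaths$exp_dur),
      resp_freq = bm$frequency,
      lag1_autocorr = lag1_autocorr(bm$breaths$duration),
      n_sighs = n_sighs)
    if (s == 1) {
      subject1 <- list(series = series, trace = trace, events = ev, blocks = bl)
    }
  }
  list(blocks = do.call(rbind, blocks), resp = do.call(rbind, resp),
       subject1 = subject1)
}

#' Analyze the behavioral arm of a study
#'
#' Drops "Both" blocks, summarizes RT/accuracy/expiration duration per
#' subject x condition, runs the routed omnibus battery on each measure,
#' computes the per-subject signal-detection table over the pooled INS+EXP,
#' IE, and EI conditions with its own battery, and the repeated-measures
#' correlation between d-prime and the planted activation covariate.
#'
#' @param blocks a blocks data.frame from [simulate_behavior_study()] (or
#'   assembled from real event/physio files).
#' @param activation list(slope, noise_sd, intercept_sd) for the synthetic
#'   activation covariate; `NULL` skips the rmcorr stage.
#' @param seed seed for the activation covariate noise.
#' @return a list of condition summaries, batteries, SDT tables, and rmcorr.
#' @export
analyze_study <- function(blocks, activation = list(slope = 0.6,
                                                    noise_sd = 0.35,
                                                    intercept_sd = 1),
                          seed = 1L) {
  usable <- blocks[blocks$condition != "Both", ]
  usable$condition <- droplevels(factor(usable$condition,
                                        levels = c("INS", "IE", "EXP", "EI")))
  cond_sum <- summarize_conditions(usable)
  four <- cond_sum[cond_sum$condition %in% c("INS", "IE", "EXP", "EI"), ]
  if (any(four$n_blocks == 0)) {
    warning("subject(s) with empty condition cells; dropping affected subjects")
    bad <- unique(four$subject[four$n_blocks == 0])
    four <- four[!four$subject %in% bad, ]
  }
  tab <- function(df, col) data.frame(subject = df$subject,
                                      condition = as.character(df$condition),
                                      value = df[[col]])
  rt_bat <- run_omnibus(tab(four, "mean_rt"))
  acc_bat <- run_omnibus(tab(four, "accuracy"))
  exp_bat <- run_omnibus(tab(four, "mean_exp_dur"))

  # familiarity metrics over pooled transition-free conditions
  u3 <- usable
  u3$condition <- ifelse(as.character(u3$condition) %in% c("INS", "EXP"),
                         "INS+EXP", as.character(u3$condition))
  sdt <- sdt_table(u3)
  dp_bat <- run_omnibus(data.frame(subject = sdt$subject,
                                   condition = sdt$condition,
                                   value = sdt$dprime))
  c_bat <- run_omnibus(data.frame(subject = sdt$subject,
                                  condition = sdt$condition,
                                  value = sdt$criterion))

  rmc <- NULL
  act <- NULL
  if (!is.null(activation)) {
    set.seed(seed + 7L)
    subs <- unique(sdt$subject)
    b0 <- stats::setNames(rnorm(length(subs), 5, activation$intercept_sd),
                          as.character(subs))
    act <- sdt[c("subject", "condition", "dprime")]
    act$activation <- b0[as.character(act$subject)] +
      activation$slope * act$dprime +
      rnorm(nrow(act), 0, activation$noise_sd)
    rmc <- rmcorr(act$activation, act$dprime, act$subject)
  }

  group_means <- function(df, col) {
    m <- tapply(df[[col]], df$condition, mean, na.rm = TRUE)
    m[order(names(m))]
  }
  list(condition_summary = cond_sum,
       group_rt = group_means(four, "mean_rt"),
       group_accuracy = group_means(four, "accuracy"),
       rt = rt_bat, accuracy = acc_bat, exp_dur = exp_bat,
       sdt = sdt, dprime = dp_bat, criterion = c_bat,
       rmcorr = rmc, activation_table = act)
}

#' Build the single-run design matrix from a simulated session
#'
#' Takes the epochs of one fMRI run (four epochs, 825 scans at TR 0.8 s by
#' default), assembles the design events (sample/delay/test blocks, extra
#' button presses during the post-task attention period), and builds the
#' design with phase-transition and (when a trace is available) RVT
#' regressors.
#'
#' @param events session event table (from [gen_session()]).
#' @param blocks matching blocks table (for test response times).
#' @param series a [resp_phase_series()].
#' @param trace optional [resp_trace()] for the RVT regressor.
#' @param run_epochs epoch indices of the run.
#' @param tr,n_scans,drop_initial scan grid parameters.
#' @return a `design_matrix`.
#' @export
run_design_from_session <- function(events, blocks, series, trace = NULL,
                                    run_epochs = 1:4, tr = 0.8, n_scans = 825,
                                    drop_initial = 10) {
  ev <- events[events$epoch %in% run_epochs, ]
  bl <- blocks[blocks$epoch %in% run_epochs, ]
  tests <- ev[ev$trial_type == "test", ]
  stopifnot(nrow(tests) == nrow(bl))
  dev <- data.frame(onset = ev$onset, duration = ev$duration,
                    trial_type = ev$trial_type, epoch = ev$epoch,
                    response_time = NA_real_)
  dev$response_time[dev$trial_type == "test"] <- bl$response_time
  last <- max(bl$response_time)
  press <- seq(last + 10, n_scans * tr - 20, by = 3)
  if (length(press)) {
    dev <- rbind(dev, data.frame(onset = press, duration = 0,
                                 trial_type = "extra_response",
                                 epoch = NA, response_time = NA_real_))
  }
  rvt <- NULL
  if (!is.null(trace)) {
    rvt <- compute_rvt(trace, series, tr = tr, delay = 5.6,
                       n_scans = n_scans - drop_initial,
                       scan_start = drop_initial * tr)
  }
  build_design(dev, series, rvt, tr = tr, n_scans = n_scans,
               drop_initial = drop_initial)
}

#' Run the full synthetic study
#'
#' Generates (or streams) respiration and task data for all subjects, runs
#' the behavioral analysis battery, and (optionally) the toy GLM stage:
#' single-run design matrix, simulated BOLD with an EI-attenuated test-block
#' response, OLS fit, and the IE > EI and INS+EXP > EI condition contrasts.
#' Writes TSV/JSON outputs when `config$out_dir` is set. Bit-reproducible
#' under `config$seed`.
#'
#' @param config a [study_config()].
#' @return a `study_report` list.
#' @export
run_full_study <- function(config = study_config()) {
  sim <- simulate_behavior_study(config)
  ana <- analyze_study(sim$blocks, activation = config$activation,
                       seed = config$seed)
  glm_part <- NULL
  if (config$run_glm) {
    s1 <- sim$subject1
    design <- run_design_from_session(s1$events, s1$blocks, s1$series,
                                      trace = s1$trace)
    ci <- design$col_info
    betas <- stats::setNames(numeric(ncol(design$X)), colnames(design$X))
    betas[ci$name[ci$type == "test_block"]] <- 1
    betas[ci$name[ci$type == "test_block" & ci$condition %in% "EI"]] <- 0.5
    betas["sample_block"] <- 0.8
    betas["delay_block"] <- 0.3
    Y <- gen_bold(design, betas, noise_sd = 1, n_voxels = 1,
                  seed = derive_seed(config$seed, 0, 9))
    fit <- fit_glm(Y, design)
    contrasts <- list(
      ie_gt_ei = contrast_estimate(fit, condition_contrast(design, "IE", "EI")),
      insexp_gt_ei = contrast_estimate(fit, condition_contrast(design,
                                                               c("INS", "EXP"),
                                                               "EI")))
    glm_part <- list(design = design, betas = betas, contrasts = contrasts)
  }
  report <- structure(list(config = config, resp = sim$resp,
                           blocks = sim$blocks, analysis = ana,
                           glm = glm_part),
                      class = "study_report")
  if (!is.null(config$out_dir)) write_study_outputs(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects, %d test blocks (%s mode, seed %d)\n",
              x$config$n_subjects, nrow(x$blocks), x$config$mode,
              x$config$seed))
  cat(sprintf("  respiration: insp %.2f s, exp %.2f s, %.1f breaths/min\n",
              mean(x$resp$mean_insp_dur), mean(x$resp$mean_exp_dur),
              mean(x$resp$resp_freq)))
  cat("  group mean RT by condition (s):\n")
  print(round(x$analysis$group_rt, 3))
  cat("  RT omnibus: "); print(x$analysis$rt$omnibus)
  cat("  d-prime omnibus: "); print(x$analysis$dprime$omnibus)
  if (!is.null(x$analysis$rmcorr)) {
    cat("  d-prime ~ activation: "); print(x$analysis$rmcorr)
  }
  invisible(x)
}

# tidy row for the stats TSV
stat_row <- function(label, sr) {
  data.frame(test = label, name = sr$test_name, statistic = sr$statistic,
             df1 = sr$df[1], df2 = if (length(sr$df) > 1) sr$df[2] else NA,
             epsilon = sr$epsilon_gg, p = sr$p,
             ci_low = sr$ci[1], ci_high = sr$ci[2], correction = sr$correction)
}

#' Write study outputs as TSV files with a JSON provenance block
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_study_outputs <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  a <- report$analysis
  write.table(report$blocks, file.path(dir, "blocks.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(a$condition_summary, file.path(dir, "condition_summary.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(a$sdt, file.path(dir, "sdt.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(report$resp, file.path(dir, "respiration.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  stats_tab <- rbind(stat_row("rt_omnibus", a$rt$omnibus),
                     stat_row("accuracy_omnibus", a$accuracy$omnibus),
                     stat_row("exp_dur_omnibus", a$exp_dur$omnibus),
                     stat_row("dprime_omnibus", a$dprime$omnibus),
                     stat_row("criterion_omnibus", a$criterion$omnibus))
  if (!is.null(a$rmcorr)) {
    stats_tab <- rbind(stats_tab, stat_row("dprime_activation_rmcorr", a$rmcorr))
  }
  write.table(stats_tab, file.path(dir, "stats.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cfg <- report$config
  prov <- list(seed = cfg$seed, n_subjects = cfg$n_subjects, mode = cfg$mode,
               sample_rate = cfg$sample_rate,
               generated = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Effect-recovery rate over seeded study replicates
#'
#' Repeats the fast-mode synthetic study and scores each replicate for
#' reproducing the planted retrieval pattern: highest condition-mean RT,
#' lowest accuracy, and lowest d-prime all in the EI condition, with the
#' EI-involving post hoc comparison significant after Bonferroni correction
#' in each battery (RT: EI vs INS; accuracy: EI vs INS; d-prime: EI vs
#' INS+EXP).
#'
#' @param n_replicates number of replicates.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param n_subjects subjects per replicate.
#' @return a list: `rate` (proportion of successful replicates), `detail`
#'   (per-replicate logical matrix).
#' @export
run_recovery_replicates <- function(n_replicates = 100, seed = 1L,
                                    n_subjects = 25) {
  ph_p <- function(bat, c1, c2) {
    ph <- bat$posthoc
    sel <- (ph$cond1 == c1 & ph$cond2 == c2) | (ph$cond1 == c2 & ph$cond2 == c1)
    ph$p_adjusted[sel]
  }
  detail <- matrix(NA, n_replicates, 6,
                   dimnames = list(NULL, c("rt_order", "acc_order", "dp_order",
                                           "rt_sig", "acc_sig", "dp_sig")))
  for (r in seq_len(n_replicates)) {
    cfg <- study_config(n_subjects = n_subjects, seed = seed + r,
                        mode = "fast", run_glm = FALSE)
    sim <- simulate_behavior_study(cfg)
    ana <- analyze_study(sim$blocks, activation = NULL)
    dp_means <- tapply(ana$sdt$dprime, ana$sdt$condition, mean)
    detail[r, ] <- c(
      names(which.max(ana$group_rt)) == "EI",
      names(which.min(ana$group_accuracy)) == "EI",
      names(which.min(dp_means)) == "EI",
      ph_p(ana$rt, "EI", "INS") < 0.05,
      ph_p(ana$accuracy, "EI", "INS") < 0.05,
      ph_p(ana$dprime, "EI", "INS+EXP") < 0.05)
  }
  list(rate = mean(apply(detail, 1, all)), detail = detail)
}

#' Type-I error of the routed battery under the null
#'
#' Simulates exchangeable (no condition effect) normal repeated-measures
#' tables, runs the full assumption-routed omnibus, and reports the
#' empirical rejection rate at `alpha`.
#'
#' @param n_replicates number of simulated tables.
#' @param n_subjects,k table dimensions.
#' @param alpha nominal level.
#' @param seed master seed.
#' @param subject_sd SD of the (exchangeable) subject intercepts.
#' @return a list: `rate`, `n_nonparametric` (replicates routed to Friedman).
#' @export
calibrate_type1 <- function(n_replicates = 2000, n_subjects = 25, k = 4,
                            alpha = 0.05, seed = 1L, subject_sd = 1) {
  rej <- logical(n_replicates)
  nonpar <- 0L
  conds <- paste0("c", seq_len(k))
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    b0 <- rnorm(n_subjects, 0, subject_sd)
    tab <- data.frame(subject = rep(seq_len(n_subjects), k),
                      condition = rep(conds, each = n_subjects),
                      value = rep(b0, k) + rnorm(n_subjects * k))
    bat <- run_omnibus(tab, alpha = alpha)
    rej[r] <- bat$omnibus$p < alpha
    if (bat$route$route == "nonparametric") nonpar <- nonpar + 1L
  }
  list(rate = mean(rej), n_nonparametric = nonpar)
}

#' Bias check of the IE > EI contrast on a planted single-run design
#'
#' Builds one 825-scan run design from a simulated four-epoch session
#' (2 Epoch A + 2 Epoch B), plants an attenuation `delta` on the
#' EI-condition test-block betas, simulates white-noise BOLD repeatedly,
#' and compares the mean IE > EI contrast estimate with `delta`.
#'
#' @param n_sims number of noise realizations.
#' @param delta planted beta attenuation in the EI condition.
#' @param noise_sd BOLD noise SD.
#' @param seed master seed.
#' @param sample_rate airflow sampling rate for the run trace.
#' @return a list: `mean_estimate`, `se_mean`, `delta`, `n_sims`,
#'   `n_ie_blocks`, `n_ei_blocks`.
#' @export
glm_recovery <- function(n_sims = 200, delta = 0.5, noise_sd = 1, seed = 1L,
                         sample_rate = 1000) {
  rp <- resp_gen_params(sample_rate = sample_rate, seed = seed)
  gt <- gen_resp_trace(rp, 680)
  series <- gt$truth
  cfgEI <- trigger_config("EI"); cfgIE <- trigger_config("IE")
  ei_ev <- series$time[series$kind == "EI"]
  ie_ev <- series$time[series$kind == "IE"]
  schEI <- schedule_triggers(ei_ev, cfgEI, ceiling(length(ei_ev) / 2),
                             seed = seed + 1)
  schIE <- schedule_triggers(ie_ev, cfgIE, ceiling(length(ie_ev) / 2),
                             seed = seed + 2)
  spec1 <- session_spec(n_epochs_A = 2, n_epochs_B = 2)
  ev <- gen_session(spec1, triggers = list(EI = schEI$cue_time,
                                           IE = schIE$cue_time),
                    seed = seed + 3)
  tests <- ev[ev$trial_type == "test", ]
  bl <- simulate_test_blocks(series, tests, behavior_effect_params(seed = seed),
                             seed = seed + 4)
  bl$epoch <- tests$epoch
  design <- run_design_from_session(ev, bl, series, trace = gt$trace,
                                    run_epochs = sort(unique(ev$epoch)))
  ci <- design$col_info
  betas <- stats::setNames(numeric(ncol(design$X)), colnames(design$X))
  betas[ci$name[ci$type == "test_block"]] <- 1
  betas[ci$name[ci$type == "test_block" & ci$condition %in% "EI"]] <- 1 - delta
  w <- condition_contrast(design, "IE", "EI")
  est <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    Y <- gen_bold(design, betas, noise_sd = noise_sd, seed = seed + 100 + i)
    est[i] <- contrast_estimate(fit_glm(Y, design), w)$estimate
  }
  list(mean_estimate = mean(est), se_mean = sd(est) / sqrt(n_sims),
       delta = delta, n_sims = n_sims,
       n_ie_blocks = sum(ci$condition %in% "IE"),
       n_ei_blocks = sum(ci$condition %in% "EI"))
}
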