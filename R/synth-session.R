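#' The visual cue attribute space
#'
#' Cues combine a symbol, a color, a count, and a screen position, six
#' levels each: 6 x 6 x 6 x 6 = 1,296 possible cues. An "old" (match) test
#' cue equals a sample cue in all four attributes; a "new" (nonmatch) cue
#' differs in at least one.
#'
#' @return a data.frame with one row per possible cue.
#' @export
cue_space <- function() {
  expand.grid(
    symbol = c("circle", "triangle", "rectangle", "cross", "crescent", "heart"),
    color = c("red", "blue", "green", "yellow", "pink", "skyblue"),
    number = 1:6,
    position = c("center", "right", "left", "top", "bottom_right", "bottom_left"),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Session specification for the delayed matching-to-sample task
#'
#' Defaults mirror the study paradigm: 8 fixed-ISI epochs (Epoch A) and 8
#' phase-triggered epochs (Epoch B), each with 4 sample cues, a 10-13 s
#' delay, and 10 test cues (5 old / 5 new); Epoch-A test cues at a 6-s ISI
#' plus a 0/350/700-ms lag in random order.
#'
#' @param n_epochs_A,n_epochs_B epoch counts.
#' @param samples_per_epoch sample cues per epoch.
#' @param tests_per_epoch test cues per epoch.
#' @param delay_range sample-to-test delay interval, seconds.
#' @param isi_A Epoch-A inter-stimulus interval, seconds.
#' @param lag_set cue lags, seconds.
#' @param sample_isi spacing of sample cues, seconds.
#' @param cue_duration on-screen cue duration, seconds.
#' @param epoch_gap rest after each epoch, seconds.
#' @return a `session_spec` list.
#' @export
session_spec <- function(n_epochs_A = 8, n_epochs_B = 8, samples_per_epoch = 4,
                         tests_per_epoch = 10, delay_range = c(10, 13),
                         isi_A = 6, lag_set = c(0, 0.350, 0.700),
                         sample_isi = 3, cue_duration = 0.5, epoch_gap = 6) {
  stopifnot(n_epochs_A >= 0, n_epochs_B >= 0, tests_per_epoch >= 2,
            delay_range[1] <= delay_range[2], isi_A > 0)
  structure(list(n_epochs_A = n_epochs_A, n_epochs_B = n_epochs_B,
                 samples_per_epoch = samples_per_epoch,
                 tests_per_epoch = tests_per_epoch,
                 delay_range = delay_range, isi_A = isi_A, lag_set = lag_set,
                 sample_isi = sample_isi, cue_duration = cue_duration,
                 epoch_gap = epoch_gap),
            class = "session_spec")
}

# lags drawn in shuffled complete sets ("random order" without replacement)
draw_lags <- function(lag_set, n) {
  k <- length(lag_set)
  unlist(lapply(seq_len(ceiling(n / k)),
                function(i) sample(lag_set, k)))[seq_len(n)]
}

#' Generate a full task session event table
#'
#' Lays out epochs sequentially: per epoch, sample cues, a random delay,
#' then the test section. Epoch-A test cues follow the fixed ISI plus lag;
#' Epoch-B test cues are taken from the supplied phase-locked candidate cue
#' times (from [schedule_triggers()]). Cue attributes are drawn from the
#' 1,296-cue space with exactly 5 old and 5 new test cues per epoch in
#' random order.
#'
#' @param spec a [session_spec()].
#' @param triggers a list with elements `EI` and `IE`: candidate cue times
#'   for the two Epoch-B modes (required if `n_epochs_B > 0`).
#' @param epoch_order character vector of `"A"`/`"B"`; default shuffles A/B
#'   in balanced groups of four (two of each), as in a four-epoch fMRI run.
#' @param b_modes phase-lock mode per B epoch; default alternates EI/IE.
#' @param start_time session start, seconds.
#' @param seed integer seed.
#' @return a data.frame of events: onset, duration, trial_type, epoch,
#'   epoch_type, mode, trial, symbol, color, number, position, is_old.
#' @export
gen_session <- function(spec, triggers = NULL, epoch_order = NULL,
                        b_modes = NULL, start_time = 0, seed = 1L) {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(seed)
  nA <- spec$n_epochs_A; nB <- spec$n_epochs_B
  if (is.null(epoch_order)) {
    if (nA == nB && (nA + nB) %% 4 == 0) {
      epoch_order <- unlist(lapply(seq_len((nA + nB) / 4),
                                   function(i) sample(c("A", "A", "B", "B"))))
    } else {
      epoch_order <- sample(rep(c("A", "B"), c(nA, nB)))
    }
  }
  stopifnot(sum(epoch_order == "A") == nA, sum(epoch_order == "B") == nB)
  if (is.null(b_modes)) b_modes <- rep(c("EI", "IE"), length.out = nB)
  if (nB > 0 && is.null(triggers)) {
    stop("Epoch-B epochs require 'triggers' (candidate cue times per mode)")
  }

  space <- cue_space()
  events <- list()
  t_cur <- start_time
  b_i <- 0L
  for (ep in seq_along(epoch_order)) {
    typ <- epoch_order[ep]
    mode <- NA_character_
    s_on <- t_cur + (seq_len(spec$samples_per_epoch) - 1) * spec$sample_isi
    s_end <- max(s_on) + spec$cue_duration
    delay <- runif(1, spec$delay_range[1], spec$delay_range[2])
    sec_start <- s_end + delay
    if (typ == "A") {
      lags <- draw_lags(spec$lag_set, spec$tests_per_epoch)
      t_on <- sec_start + (seq_len(spec$tests_per_epoch) - 1) * spec$isi_A + lags
    } else {
      b_i <- b_i + 1L
      mode <- b_modes[b_i]
      cand <- triggers[[mode]]
      cand <- cand[cand >= sec_start]
      if (length(cand) < spec$tests_per_epoch) {
        stop(sprintf("epoch %d: only %d phase-locked cue times available, %d needed",
                     ep, length(cand), spec$tests_per_epoch))
      }
      t_on <- cand[seq_len(spec$tests_per_epoch)]
    }
    # cue attributes: 4 distinct samples; 5 old repeats of them, 5 new others
    s_idx <- sample(nrow(space), spec$samples_per_epoch)
    n_old <- floor(spec$tests_per_epoch / 2)
    n_new <- spec$tests_per_epoch - n_old
    old_idx <- sample(s_idx, n_old, replace = TRUE)
    new_idx <- sample(setdiff(seq_len(nrow(space)), s_idx), n_new)
    is_old <- sample(rep(c(TRUE, FALSE), c(n_old, n_new)))
    t_idx <- integer(spec$tests_per_epoch)
    t_idx[is_old] <- old_idx
    t_idx[!is_old] <- new_idx

    events[[length(events) + 1]] <- data.frame(
      onset = s_on, duration = spec$cue_duration, trial_type = "sample",
      epoch = ep, epoch_type = typ, mode = mode,
      trial = seq_along(s_on), space[s_idx, ], is_old = NA,
      row.names = NULL)
    events[[length(events) + 1]] <- data.frame(
      onset = t_on, duration = spec$cue_duration, trial_type = "test",
      epoch = ep, epoch_type = typ, mode = mode,
      trial = seq_along(t_on), space[t_idx, ], is_old = is_old,
      row.names = NULL)
    t_cur <- max(t_on) + 3 + spec$epoch_gap   # 3-s response window
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

#' Behavioral effect parameters for the synthetic observer
#'
#' Reaction times are `base_rt + condition shift + truncated-normal noise`.
#' Choices come from one of two observers: a Bernoulli-accuracy observer
#' (correct with condition-adjusted probability, the default) or, when
#' `base_dprime` is given, an equal-variance signal-detection observer whose
#' per-condition hit/false-alarm rates are solved to jointly match the
#' condition's target accuracy and target d-prime.
#'
#' @param base_rt baseline reaction time, seconds.
#' @param rt_shift_by_condition named numeric: additive RT shift per
#'   respiratory condition (seconds).
#' @param base_accuracy baseline probability correct.
#' @param acc_shift_by_condition named numeric: additive accuracy shift.
#' @param rt_noise_sd trial-to-trial RT noise SD (truncated at 0).
#' @param base_dprime optional baseline d-prime (enables the SDT observer).
#' @param dprime_shift_by_condition named numeric: additive d-prime shift.
#' @param seed integer seed.
#' @return a `behavior_effect_params` list.
#' @export
behavior_effect_params <- function(base_rt = 1.0,
                                   rt_shift_by_condition = c(INS = 0, EXP = 0.03,
                                                             IE = 0.07, EI = 0.15),
                                   base_accuracy = 0.85,
                                   acc_shift_by_condition = c(INS = 0, EXP = 0,
                                                              IE = -0.04, EI = -0.10),
                                   rt_noise_sd = 0.35,
                                   base_dprime = NULL,
                                   dprime_shift_by_condition = NULL,
                                   seed = 1L) {
  if (base_rt <= 0) stop("'base_rt' must be positive")
  structure(list(base_rt = base_rt,
                 rt_shift_by_condition = rt_shift_by_condition,
                 base_accuracy = base_accuracy,
                 acc_shift_by_condition = acc_shift_by_condition,
                 rt_noise_sd = rt_noise_sd,
                 base_dprime = base_dprime,
                 dprime_shift_by_condition = dprime_shift_by_condition,
                 seed = as.integer(seed)),
            class = "behavior_effect_params")
}

clamp01 <- function(p, eps = 1e-4) pmin(pmax(p, eps), 1 - eps)

shift_for <- function(shifts, cond) {
  out <- numeric(length(cond))
  if (is.null(shifts)) return(out)
  named <- cond %in% names(shifts)
  unknown <- !named & !(cond %in% c("Both"))
  if (any(unknown)) {
    stop("unknown condition label(s): ",
         paste(unique(cond[unknown]), collapse = ", "))
  }
  out[named] <- shifts[cond[named]]
  out   # "Both" (and any unshifted label) gets 0
}

# Solve (hit, fa) jointly matching accuracy = (hit + 1 - fa)/2 and
# d' = z(hit) - z(fa) for the equal-variance observer. For a given accuracy
# the attainable minimum is d' = 2 z(accuracy) (unbiased criterion); larger
# d' targets are met on the conservative branch (fa below 1 - accuracy).
solve_sdt_rates <- function(accuracy, dp) {
  accuracy <- clamp01(accuracy, 1e-3)
  dp_min <- 2 * qnorm(accuracy)
  if (dp < dp_min - 1e-9) {
    stop(sprintf("d-prime %.3f unattainable at accuracy %.3f (minimum %.3f)",
                 dp, accuracy, dp_min))
  }
  fa_sym <- 1 - accuracy
  lo <- max(1e-9, 1 - 2 * accuracy + 1e-9)
  g <- function(fa) qnorm(2 * accuracy - 1 + fa) - qnorm(fa) - dp
  if (g(fa_sym) > 0) {     # dp == dp_min up to tolerance
    fa <- fa_sym
  } else {
    fa <- uniroot(g, c(lo + (fa_sym - lo) * 1e-9, fa_sym), tol = 1e-12)$root
  }
  c(hit = 2 * accuracy - 1 + fa, fa = fa)
}

rtrunc_norm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep_len(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= 0]
  }
  x
}

#' Generate behavioral responses for labeled test blocks
#'
#' Applies the planted condition effects of a [behavior_effect_params()] to
#' blocks that already carry a respiratory condition label: RT shifts plus
#' truncated-normal noise, and choices from the Bernoulli-accuracy or SDT
#' observer. Deterministic under the params seed. Blocks labeled "Both"
#' receive the baseline (no planted shift).
#'
#' @param blocks data.frame with a `condition` column and, for choice
#'   generation, an `is_old` column.
#' @param params a [behavior_effect_params()].
#' @return `blocks` with added columns `rt`, `choice_old`, `correct`.
#' @export
gen_behavior <- function(blocks, params = behavior_effect_params()) {
  stopifnot(is.data.frame(blocks), "condition" %in% names(blocks))
  set.seed(params$seed)
  cond <- as.character(blocks$condition)
  n <- nrow(blocks)
  rt <- rtrunc_norm_pos(n, params$base_rt + shift_for(params$rt_shift_by_condition, cond),
                        params$rt_noise_sd)
  blocks$rt <- rt
  if ("is_old" %in% names(blocks)) {
    acc <- clamp01(params$base_accuracy +
                     shift_for(params$acc_shift_by_condition, cond))
    if (!is.null(params$base_dprime)) {
      dp <- params$base_dprime +
        shift_for(params$dprime_shift_by_condition, cond)
      u <- runif(n)
      choice <- logical(n)
      for (cc in unique(cond)) {
        sel <- cond == cc
        r <- solve_sdt_rates(acc[sel][1], dp[sel][1])
        p_old <- ifelse(blocks$is_old[sel], r["hit"], r["fa"])
        choice[sel] <- u[sel] < p_old
      }
      blocks$choice_old <- choice
      blocks$correct <- blocks$choice_old == blocks$is_old
    } else {
      correct <- runif(n) < acc
      blocks$correct <- correct
      blocks$choice_old <- ifelse(correct, blocks$is_old, !blocks$is_old)
    }
  }
  blocks
}

#' Simulate labeled test blocks from cue times and a phase series
#'
#' Two-stage generative scheme keeping the planted effects consistent with
#' the analysis-time classification: a provisional RT (baseline + noise)
#' determines a provisional block condition; the condition's RT shift is
#' then added, the final response time set, and the block re-classified on
#' the final interval. Choices are generated from the final condition.
#'
#' @param series a [resp_phase_series()] covering all cue/response times.
#' @param tests data.frame of test events with `onset` and `is_old`.
#' @param params a [behavior_effect_params()].
#' @param subject subject identifier attached to the output.
#' @param seed integer seed.
#' @return a blocks data.frame: subject, cue_time, response_time, rt,
#'   condition, cue_angle, cue_sextile, is_old, choice_old, correct,
#'   exp_dur_in_block.
#' @export
simulate_test_blocks <- function(series, tests, params = behavior_effect_params(),
                                 subject = 1L, seed = 1L) {
  stopifnot(inherits(series, "resp_phase_series"),
            all(c("onset", "is_old") %in% names(tests)))
  set.seed(seed)
  n <- nrow(tests)
  cue <- tests$onset
  rt0 <- rtrunc_norm_pos(n, params$base_rt, params$rt_noise_sd)
  cond0 <- as.character(classify_block(cue, cue + rt0, series))
  rt <- rt0 + shift_for(params$rt_shift_by_condition, cond0)
  resp <- cue + rt
  cond <- classify_block(cue, resp, series)
  blocks <- data.frame(subject = subject, cue_time = cue, response_time = resp,
                       rt = rt, condition = cond, is_old = tests$is_old)
  # choices keyed to the final (analysis-visible) condition
  pb <- params; pb$seed <- seed + 1L
  choice_part <- gen_behavior(blocks[c("condition", "is_old")], pb)
  blocks$choice_old <- choice_part$choice_old
  blocks$correct <- choice_part$correct
  blocks$cue_angle <- project_phase(cue, series)
  blocks$cue_sextile <- classify_cue_sextile(blocks$cue_angle)
  blocks$exp_dur_in_block <- expiration_in_interval(cue, resp, series)
  blocks
}
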