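#' Canonical double-gamma HRF specification
#'
#' Peak delay 6 s, undershoot delay 16 s, unit dispersions,
#' peak:undershoot ratio 6, 32-s kernel: the canonical hemodynamic response
#' used by SPM-style first-level models.
#'
#' @param peak_delay,undershoot_delay gamma delays, seconds.
#' @param peak_disp,undershoot_disp gamma dispersions.
#' @param ratio peak-to-undershoot amplitude ratio.
#' @param length kernel length, seconds.
#' @return an `hrf_spec` list.
#' @export
hrf_spec <- function(peak_delay = 6, undershoot_delay = 16, peak_disp = 1,
                     undershoot_disp = 1, ratio = 6, length = 32) {
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length = length),
            class = "hrf_spec")
}

#' Sample the HRF kernel
#' @param hrf an [hrf_spec()].
#' @param dt sampling step, seconds.
#' @return numeric kernel (sum-normalized to unit area).
#' @export
hrf_kernel <- function(hrf = hrf_spec(), dt = 0.8) {
  t <- seq(0, hrf$length, by = dt)
  h <- stats::dgamma(t, shape = hrf$peak_delay / hrf$peak_disp,
                     scale = hrf$peak_disp) -
    stats::dgamma(t, shape = hrf$undershoot_delay / hrf$undershoot_disp,
                  scale = hrf$undershoot_disp) / hrf$ratio
  h / sum(h)
}

#' Boxcar regressor on the scan grid (pre-convolution)
#'
#' Each scan bin is the half-open interval `[k*tr, (k+1)*tr)`; the regressor
#' value is the fraction of the bin occupied by the event. A zero-duration
#' event is an impulse: unit mass in its containing bin.
#'
#' @param onset,duration event timing, seconds (vectors, paired); onsets are
#'   relative to the run start.
#' @param tr scan repetition time.
#' @param n_scans number of scans in the run.
#' @return numeric regressor of length `n_scans`.
#' @export
boxcar <- function(onset, duration, tr, n_scans) {
  stopifnot(length(onset) == length(duration))
  if (any(onset < 0)) stop("'onset' must be >= 0")
  if (any(onset >= n_scans * tr)) stop("event beyond the scan window")
  reg <- numeric(n_scans)
  for (i in seq_along(onset)) {
    if (duration[i] == 0) {
      k <- floor(onset[i] / tr) + 1
      reg[k] <- reg[k] + 1
    } else {
      lo <- (seq_len(n_scans) - 1) * tr
      ov <- pmax(0, pmin(lo + tr, onset[i] + duration[i]) - pmax(lo, onset[i]))
      reg <- reg + ov / tr
    }
  }
  reg
}

#' Convolve a regressor with the canonical HRF
#'
#' Causal linear convolution, truncated to the regressor length.
#'
#' @param reg numeric regressor on the scan grid.
#' @param tr scan repetition time.
#' @param hrf an [hrf_spec()].
#' @return convolved regressor, same length.
#' @export
convolve_hrf <- function(reg, tr = 0.8, hrf = hrf_spec()) {
  h <- hrf_kernel(hrf, dt = tr)
  full <- convolve(reg, rev(h), type = "open")
  full[seq_along(reg)]
}

#' Signed phase-transition regressor
#'
#' The IE and EI transition trains are integrated as a single regressor at
#' scan resolution: +1 mass per IE transition and -1 per EI transition in
#' the containing bin (coincident transitions sum), optionally HRF-convolved.
#'
#' @param series a [resp_phase_series()] with times relative to the run start.
#' @param tr scan repetition time.
#' @param n_scans number of scans.
#' @param convolve HRF-convolve the impulse train (default TRUE).
#' @param hrf an [hrf_spec()].
#' @return numeric regressor of length `n_scans`.
#' @export
phase_transition_regressor <- function(series, tr = 0.8, n_scans,
                                       convolve = TRUE, hrf = hrf_spec()) {
  stopifnot(inherits(series, "resp_phase_series"))
  reg <- numeric(n_scans)
  sel <- series$time >= 0 & series$time < n_scans * tr
  k <- floor(series$time[sel] / tr) + 1
  s <- ifelse(series$kind[sel] == "IE", 1, -1)
  for (i in seq_along(k)) reg[k[i]] <- reg[k[i]] + s[i]
  if (convolve) convolve_hrf(reg, tr, hrf) else reg
}

#' Discrete-cosine drift basis (high-pass filter)
#'
#' The standard realization of a high-pass threshold in a first-level GLM:
#' cosine regressors up to the cutoff frequency are included in the design
#' (and thereby projected out of both the data and the task regressors).
#'
#' @param n_scans number of retained scans.
#' @param tr scan repetition time.
#' @param cutoff high-pass threshold in Hz (default 1/128).
#' @return matrix with one column per drift regressor (possibly 0 columns).
#' @export
dct_basis <- function(n_scans, tr = 0.8, cutoff = 1 / 128) {
  R <- floor(2 * n_scans * tr * cutoff)
  if (R < 1) return(matrix(numeric(0), n_scans, 0))
  t <- seq_len(n_scans) - 1
  X <- sapply(seq_len(R), function(r) {
    sqrt(2 / n_scans) * cos(pi * (2 * t + 1) * r / (2 * n_scans))
  })
  colnames(X) <- paste0("drift_", seq_len(R))
  X
}

#' Build a single-run first-level design matrix
#'
#' Columns per run: one sample-block regressor (one boxcar per epoch, from
#' the first to the last sample cue), one delay-block regressor, one column
#' per test block (cue onset to motor response), one extra-response
#' regressor (impulses at button presses outside test blocks), the signed
#' phase-transition regressor, the RVT regressor, drift (DCT) regressors at
#' the high-pass cutoff, and an intercept. The first `drop_initial` volumes
#' are discarded before modeling; all regressors are built on the full grid
#' and then truncated, so HRF convolution is unaffected by the discard.
#'
#' @param events data.frame with columns `onset`, `duration`, `trial_type`
#'   (`"sample"`, `"test"`, `"extra_response"`), `epoch`, and for test rows
#'   `response_time` (absolute, seconds). Times are relative to run start.
#' @param series a [resp_phase_series()] on the run clock (for the phase
#'   regressor and test-block condition labels); may be `NULL` to omit.
#' @param rvt an `rvt_series` from [compute_rvt()] with one value per
#'   retained scan; may be `NULL` to omit.
#' @param tr scan repetition time (default 0.8).
#' @param n_scans scans acquired in the run (default 825).
#' @param drop_initial initial volumes discarded (default 10).
#' @param highpass_cutoff Hz (default 1/128).
#' @param hrf an [hrf_spec()].
#' @param convolve_phase HRF-convolve the phase-transition regressor.
#' @return a `design_matrix` list: `X` (retained scans x columns), `tr`,
#'   `n_scans`, `drop_initial`, `col_info` (data.frame: name, type,
#'   condition), `frame_times`.
#' @export
build_design <- function(events, series = NULL, rvt = NULL, tr = 0.8,
                         n_scans = 825, drop_initial = 10,
                         highpass_cutoff = 1 / 128, hrf = hrf_spec(),
                         convolve_phase = TRUE) {
  stopifnot(is.data.frame(events),
            all(c("onset", "duration", "trial_type", "epoch") %in% names(events)))
  run_len <- n_scans * tr
  if (any(events$onset < 0 | events$onset >= run_len)) {
    stop("events outside the run window")
  }
  cols <- list(); info <- list()
  add <- function(name, x, type, condition = NA_character_) {
    cols[[length(cols) + 1]] <<- x
    info[[length(info) + 1]] <<- data.frame(name = name, type = type,
                                            condition = condition)
    names(cols)[length(cols)] <<- name
  }

  samp <- events[events$trial_type == "sample", ]
  tests <- events[events$trial_type == "test", ]
  # sample block: first to last sample cue per epoch; delay: sample end to
  # first test cue of the epoch
  s_on <- s_dur <- d_on <- d_dur <- numeric(0)
  for (ep in sort(unique(samp$epoch))) {
    se <- samp[samp$epoch == ep, ]
    a <- min(se$onset)
    b <- max(se$onset + se$duration)
    s_on <- c(s_on, a); s_dur <- c(s_dur, b - a)
    te <- tests[tests$epoch == ep, ]
    if (nrow(te)) {
      d_on <- c(d_on, b); d_dur <- c(d_dur, min(te$onset) - b)
    }
  }
  add("sample_block", convolve_hrf(boxcar(s_on, s_dur, tr, n_scans), tr, hrf),
      "task")
  add("delay_block", convolve_hrf(boxcar(d_on, d_dur, tr, n_scans), tr, hrf),
      "task")

  if (nrow(tests)) {
    if (!"response_time" %in% names(tests) || any(is.na(tests$response_time))) {
      stop("test events need a 'response_time' column")
    }
    if (any(tests$response_time <= tests$onset)) {
      stop("test response before cue onset")
    }
    conds <- if (!is.null(series)) {
      as.character(classify_block(tests$onset, tests$response_time, series))
    } else rep(NA_character_, nrow(tests))
    for (i in seq_len(nrow(tests))) {
      add(sprintf("test_%02d", i),
          convolve_hrf(boxcar(tests$onset[i],
                              tests$response_time[i] - tests$onset[i],
                              tr, n_scans), tr, hrf),
          "test_block", conds[i])
    }
  }

  extra <- events[events$trial_type == "extra_response", ]
  xr <- if (nrow(extra)) boxcar(extra$onset, rep(0, nrow(extra)), tr, n_scans)
        else numeric(n_scans)
  add("extra_response", convolve_hrf(xr, tr, hrf), "task")

  if (!is.null(series)) {
    add("phase_transition",
        phase_transition_regressor(series, tr, n_scans,
                                   convolve = convolve_phase, hrf = hrf),
        "physio")
  }

  keep <- seq.int(drop_initial + 1, n_scans)
  X <- do.call(cbind, cols)[keep, , drop = FALSE]

  if (!is.null(rvt)) {
    v <- rvt$values
    if (length(v) != length(keep)) {
      stop("RVT series must have one value per retained scan")
    }
    X <- cbind(X, rvt = v)
    info[[length(info) + 1]] <- data.frame(name = "rvt", type = "physio",
                                           condition = NA_character_)
  }

  D <- dct_basis(length(keep), tr, highpass_cutoff)
  if (ncol(D)) {
    X <- cbind(X, D)
    for (nm in colnames(D)) {
      info[[length(info) + 1]] <- data.frame(name = nm, type = "drift",
                                             condition = NA_character_)
    }
  }
  X <- cbind(X, intercept = 1)
  info[[length(info) + 1]] <- data.frame(name = "intercept", type = "intercept",
                                         condition = NA_character_)
  structure(list(X = X, tr = tr, n_scans = n_scans,
                 drop_initial = drop_initial,
                 col_info = do.call(rbind, info),
                 frame_times = (keep - 1) * tr),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d scans x %d columns (tr = %g s, %d dropped)\n",
              nrow(x$X), ncol(x$X), x$tr, x$drop_initial))
  cat("  column types:",
      paste(sprintf("%s=%d", names(table(x$col_info$type)),
                    as.integer(table(x$col_info$type))), collapse = ", "), "\n")
  invisible(x)
}

#' Fit an ordinary-least-squares GLM
#'
#' OLS fit of one or more voxel series on the design; rank deficiency is an
#' error naming the dependent columns. Temporal autocorrelation modeling is
#' out of scope here: simulation-based recovery checks use white noise.
#'
#' @param Y numeric vector or matrix (scans x voxels).
#' @param design a `design_matrix` from [build_design()], or a plain matrix.
#' @return a `glm_fit` list: `betas`, `sigma2`, `df_residual`, `xtx_inv`,
#'   `colnames`.
#' @export
fit_glm <- function(Y, design) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("Y and design have different numbers of scans")
  if (nrow(X) <= ncol(X)) stop("need more scans than design columns")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    stop("rank-deficient design; dependent columns: ",
         paste(dep, collapse = ", "))
  }
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfres
  structure(list(betas = betas, sigma2 = sigma2, df_residual = dfres,
                 xtx_inv = chol2inv(chol(crossprod(X))),
                 colnames = colnames(X), design = design),
            class = "glm_fit")
}

#' Contrast estimate and t-statistic
#'
#' `estimate = c'beta`, `t = c'beta / sqrt(c' (X'X)^-1 c * sigma2)`.
#'
#' @param fit a `glm_fit`.
#' @param weights named numeric vector of contrast weights over design
#'   columns (unnamed columns get weight 0).
#' @return a data.frame (one row per voxel): estimate, se, t, df.
#' @export
contrast_estimate <- function(fit, weights) {
  stopifnot(inherits(fit, "glm_fit"))
  if (is.null(names(weights))) stop("'weights' must be a named vector")
  unknown <- setdiff(names(weights), fit$colnames)
  if (length(unknown)) {
    stop("unknown design columns: ", paste(unknown, collapse = ", "))
  }
  cvec <- numeric(length(fit$colnames))
  names(cvec) <- fit$colnames
  cvec[names(weights)] <- weights
  est <- drop(t(cvec) %*% fit$betas)
  cvar <- drop(t(cvec) %*% fit$xtx_inv %*% cvec)
  se <- sqrt(cvar * fit$sigma2)
  data.frame(estimate = est, se = se, t = est / se, df = fit$df_residual)
}

#' Condition contrast weights over test-block columns
#'
#' Builds weights for contrasts between respiratory conditions of the test
#' blocks, e.g. IE > EI: `+1/n_IE` on every IE-condition test column and
#' `-1/n_EI` on every EI column, so the contrast estimates the per-block
#' mean difference. Conditions may be pooled by passing several labels
#' (e.g. `c("INS", "EXP")`). "Both" blocks keep weight 0 throughout.
#'
#' @param design a `design_matrix` whose test columns carry condition labels.
#' @param positive,negative character vectors of condition labels; `negative`
#'   may be `NULL` for a condition-vs-baseline contrast.
#' @return named weight vector usable with [contrast_estimate()].
#' @export
condition_contrast <- function(design, positive, negative = NULL) {
  stopifnot(inherits(design, "design_matrix"))
  ci <- design$col_info
  tb <- ci[ci$type == "test_block", ]
  pos <- tb$name[tb$condition %in% positive]
  if (length(pos) == 0) stop("no test blocks in the positive condition(s)")
  w <- stats::setNames(rep(1 / length(pos), length(pos)), pos)
  if (!is.null(negative)) {
    neg <- tb$name[tb$condition %in% negative]
    if (length(neg) == 0) stop("no test blocks in the negative condition(s)")
    w <- c(w, stats::setNames(rep(-1 / length(neg), length(neg)), neg))
  }
  w
}

#' Simulate voxel time series from a design
#'
#' `Y = X beta + white noise`; the standard parameter-recovery surface for
#' the design-matrix code.
#'
#' @param design a `design_matrix` (or plain matrix).
#' @param betas numeric vector, one per design column.
#' @param noise_sd white-noise SD.
#' @param n_voxels number of independent voxel series.
#' @param seed integer seed.
#' @return numeric matrix (scans x voxels).
#' @export
gen_bold <- function(design, betas, noise_sd = 1, n_voxels = 1, seed = 1L) {
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  if (length(betas) != ncol(X)) {
    stop(sprintf("'betas' length %d != %d design columns",
                 length(betas), ncol(X)))
  }
  set.seed(seed)
  mu <- drop(X %*% betas)
  matrix(mu, nrow(X), n_voxels) +
    matrix(rnorm(nrow(X) * n_voxels, 0, noise_sd), nrow(X), n_voxels)
}
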