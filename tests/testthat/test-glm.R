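test_that("boxcar occupancies follow interval-overlap arithmetic", {
  # one full bin
  expect_equal(boxcar(0.8, 0.8, tr = 0.8, n_scans = 5),
               c(0, 1, 0, 0, 0))
  # 1.2-s event starting mid-bin: half of bin 1, all of bin 2
  expect_equal(boxcar(0.4, 1.2, tr = 0.8, n_scans = 4),
               c(0.5, 1, 0, 0), tolerance = 1e-12)
  # zero-duration event: unit impulse in its containing bin
  expect_equal(boxcar(1.7, 0, tr = 0.8, n_scans = 4),
               c(0, 0, 1, 0))
  expect_error(boxcar(100, 1, tr = 0.8, n_scans = 5), "beyond")
})

test_that("HRF convolution is linear, causal, and plateaus at the integral", {
  n <- 100
  imp <- c(1, numeric(n - 1))
  h <- hrf_kernel(hrf_spec(), dt = 0.8)
  out <- convolve_hrf(imp, tr = 0.8)
  expect_equal(out[seq_along(h)], h, tolerance = 1e-10)
  expect_equal(out[(length(h) + 1):n], numeric(n - length(h)),
               tolerance = 1e-12)
  # kernel peaks near 5-6 s
  expect_lt(abs((which.max(h) - 1) * 0.8 - 5.2), 1.3)

  a <- boxcar(2, 3, 0.8, n); b <- boxcar(40, 1, 0.8, n)
  expect_equal(convolve_hrf(a + b, 0.8),
               convolve_hrf(a, 0.8) + convolve_hrf(b, 0.8), tolerance = 1e-10)

  const <- rep(2, 200)
  plateau <- convolve_hrf(const, 0.8)[150:200]
  expect_equal(plateau, rep(2 * sum(h), 51), tolerance = 1e-9)
})

test_that("phase-transition regressor is a signed impulse train", {
  s1 <- resp_phase_series(2.0, "EI")
  r1 <- phase_transition_regressor(s1, tr = 0.8, n_scans = 10,
                                   convolve = FALSE)
  expect_equal(r1, c(0, 0, -1, numeric(7)))

  s2 <- periodic_series(10)
  r2 <- phase_transition_regressor(s2, tr = 0.8, n_scans = 45,
                                   convolve = FALSE)
  expect_equal(sum(r2), 0)  # equal EI and IE counts cancel

  # strictly periodic breathing gives a periodic regressor; compare over a
  # common multiple of the 3.55-s cycle and the 0.8-s bin (71 bins = 16
  # cycles), with the series nudged off the bin edges to dodge float ties
  s3 <- periodic_series(120)
  s3$time <- s3$time + 0.013
  r3 <- phase_transition_regressor(s3, tr = 0.8, n_scans = 355,
                                   convolve = FALSE)
  expect_equal(r3[1:71], r3[72:142])
  expect_equal(r3[1:71], r3[143:213])
})

test_that("drift basis size follows the high-pass threshold", {
  D <- dct_basis(815, tr = 0.8, cutoff = 1 / 128)
  expect_equal(ncol(D), floor(2 * 815 * 0.8 / 128))   # 10 regressors
  expect_equal(crossprod(D), diag(ncol(D)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(ncol(dct_basis(50, 0.8, 1 / 128)), 0)
})

test_that("design assembly has the full per-run column bookkeeping", {
  ser <- gen_breath_series(resp_gen_params(seed = 23), 700)$series
  trg <- truth_triggers(ser, seed = 23)
  spec1 <- session_spec(n_epochs_A = 2, n_epochs_B = 2)
  ev <- gen_session(spec1, triggers = trg, seed = 23)
  tests <- ev[ev$trial_type == "test", ]
  bl <- simulate_test_blocks(ser, tests, behavior_effect_params(seed = 23),
                             seed = 23)
  bl$epoch <- tests$epoch
  des <- run_design_from_session(ev, bl, ser, run_epochs = 1:4)

  expect_equal(nrow(des$X), 815)            # 825 scans minus 10 discarded
  types <- table(des$col_info$type)
  expect_equal(unname(types["test_block"]), 40)  # 4 epochs x 10 test blocks
  expect_equal(unname(types["task"]), 3)    # sample, delay, extra response
  expect_equal(unname(types["physio"]), 1)  # phase transitions (no trace/RVT)
  expect_equal(unname(types["intercept"]), 1)
  expect_equal(unname(types["drift"]), 10)
  expect_false(any(!is.finite(des$X)))
})

test_that("noiseless data give exact beta recovery and clean contrasts", {
  set.seed(31)
  X <- cbind(a = rnorm(60), b = rnorm(60), c = rnorm(60), intercept = 1)
  beta <- c(1.5, -2, 0.5, 10)
  fit <- fit_glm(X %*% beta, X)
  expect_equal(drop(fit$betas), beta, tolerance = 1e-9,
               ignore_attr = TRUE)
  ce <- contrast_estimate(fit, c(a = 1))
  expect_equal(ce$estimate, 1.5, tolerance = 1e-9)

  # duplicated column: rank-deficiency error naming the offender
  X2 <- cbind(X, a2 = X[, "a"])
  expect_error(fit_glm(rnorm(60), X2), "a2")
  expect_error(contrast_estimate(fit, c(zz = 1)), "unknown")
  expect_error(contrast_estimate(fit, 1), "named")
})

test_that("OLS contrast estimates are unbiased over repeated noise", {
  set.seed(32)
  X <- cbind(a = convolve_hrf(boxcar(c(5, 40, 70), rep(4, 3), 0.8, 120), 0.8),
             b = convolve_hrf(boxcar(c(20, 55, 85), rep(4, 3), 0.8, 120), 0.8),
             intercept = 1)
  beta <- c(1, 0, 0)
  est <- vapply(1:100, function(i) {
    Y <- gen_bold(X, beta, noise_sd = 1, seed = 320 + i)
    contrast_estimate(fit_glm(Y, X), c(a = 1, b = -1))$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 3 * sd(est) / sqrt(100))

  # null betas: t statistics center on zero
  est0 <- vapply(1:100, function(i) {
    Y <- gen_bold(X, c(0, 0, 0), noise_sd = 1, seed = 640 + i)
    contrast_estimate(fit_glm(Y, X), c(a = 1))$t
  }, numeric(1))
  expect_lt(abs(mean(est0)), 3 / sqrt(100) + 0.05)
})

test_that("condition contrasts are antisymmetric and drift-protected", {
  ser <- gen_breath_series(resp_gen_params(seed = 24), 700)$series
  trg <- truth_triggers(ser, seed = 24)
  ev <- gen_session(session_spec(n_epochs_A = 2, n_epochs_B = 2),
                    triggers = trg, seed = 24)
  tests <- ev[ev$trial_type == "test", ]
  bl <- simulate_test_blocks(ser, tests, behavior_effect_params(seed = 24),
                             seed = 24)
  bl$epoch <- tests$epoch
  des <- run_design_from_session(ev, bl, ser, run_epochs = 1:4)
  betas <- stats::setNames(numeric(ncol(des$X)), colnames(des$X))
  Y <- gen_bold(des, betas, noise_sd = 1, seed = 25)
  fit <- fit_glm(Y, des)
  fwd <- contrast_estimate(fit, condition_contrast(des, "IE", "EI"))$estimate
  rev <- contrast_estimate(fit, condition_contrast(des, "EI", "IE"))$estimate
  expect_equal(fwd + rev, 0, tolerance = 1e-10)

  # injected linear drift leaks only marginally into task betas once the
  # cosine drift basis is in the design
  drift <- seq(0, 5, length.out = nrow(des$X))
  b1 <- fit_glm(Y, des)$betas["sample_block", 1]
  b2 <- fit_glm(Y + drift, des)$betas["sample_block", 1]
  expect_lt(abs(b2 - b1), 0.15)
})

test_that("gen_bold is seeded and dimension-checked", {
  X <- cbind(a = rnorm(30), intercept = 1)
  expect_identical(gen_bold(X, c(1, 0), seed = 5), gen_bold(X, c(1, 0), seed = 5))
  expect_error(gen_bold(X, c(1, 0, 2)), "design columns")
})
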