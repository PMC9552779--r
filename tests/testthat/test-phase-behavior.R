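test_that("phase projection is piecewise linear with the stated anchors", {
  ser <- periodic_series(5)
  expect_equal(project_phase(0, ser), 0)
  expect_equal(project_phase(1.46 / 2, ser), 90, tolerance = 1e-12)
  expect_equal(project_phase(1.46, ser), 180, tolerance = 1e-12)
  # midpoint of the 2.09-s expiration sits at 270 degrees
  expect_equal(project_phase(1.46 + 2.09 / 2, ser), 270, tolerance = 1e-12)
  expect_equal(project_phase(3.55, ser), 0, tolerance = 1e-12)  # wraps at EI
  expect_error(project_phase(1e6, ser), "outside")
})

test_that("phase is strictly increasing within each breath", {
  set.seed(2)
  p <- resp_gen_params(dur_cv = 0.25, sample_rate = 60, seed = 2)
  ser <- gen_breath_series(p, 200)$series
  for (b in c(1, 10, 20)) {
    t0 <- ser$time[ser$kind == "EI"][b]
    t1 <- ser$time[ser$kind == "EI"][b + 1]
    tt <- seq(t0, t1 - 1e-6, length.out = 100)
    expect_true(all(diff(project_phase(tt, ser)) > 0))
  }
})

test_that("circular summaries follow vector arithmetic", {
  s <- circ_summary(rep(90, 8))
  expect_equal(s$mean_direction, 90, tolerance = 1e-9)
  expect_equal(s$resultant_length, 1, tolerance = 1e-9)
  expect_equal(s$circular_sd, 0, tolerance = 1e-4)

  expect_lt(circ_summary(c(0, 90, 180, 270))$resultant_length, 1e-12)

  s2 <- circ_summary(c(0, 90))
  expect_equal(s2$mean_direction, 45, tolerance = 1e-9)
  expect_equal(s2$resultant_length, sqrt(2) / 2, tolerance = 1e-9)

  # resultant length is bounded by 1 for arbitrary angle sets
  set.seed(3)
  for (i in 1:20) {
    expect_lte(circ_summary(runif(50, 0, 360))$resultant_length, 1)
  }
  expect_error(circ_summary(numeric(0)), "empty")
})

test_that("sextile bins are half-open 60-degree intervals", {
  expect_equal(as.character(classify_cue_sextile(0)), "INS 0-60")
  expect_equal(as.character(classify_cue_sextile(59.999)), "INS 0-60")
  expect_equal(as.character(classify_cue_sextile(60)), "INS 60-120")
  expect_equal(as.character(classify_cue_sextile(179.9)), "INS 120-180")
  expect_equal(as.character(classify_cue_sextile(300)), "EXP 300-360")
  expect_equal(as.character(classify_cue_sextile(359.999)), "EXP 300-360")
})

test_that("block classification counts strictly interior transitions", {
  ser <- periodic_series(5)
  # cue at 100 deg, response at 150 deg of the same inspiration: INS
  expect_equal(as.character(classify_block(1.46 * 100 / 180,
                                           1.46 * 150 / 180, ser)), "INS")
  # cue late inspiration, response in the following expiration: IE
  expect_equal(as.character(classify_block(1.3, 2.0, ser)), "IE")
  # cue in expiration, response in the next inspiration: EI
  expect_equal(as.character(classify_block(2.0, 3.8, ser)), "EI")
  # cue in expiration, response after the next EI and IE: Both
  expect_equal(as.character(classify_block(2.0, 5.2, ser)), "Both")
  # entirely within one expiration: EXP
  expect_equal(as.character(classify_block(1.6, 3.0, ser)), "EXP")
  # a transition exactly at the response instant is NOT inside the block
  expect_equal(as.character(classify_block(0.5, 1.46, ser)), "INS")
  expect_equal(as.character(classify_block(1.0, 1.47, ser)), "IE")
  expect_error(classify_block(2, 1, ser), "response before")
})

test_that("the five block labels partition all blocks", {
  set.seed(4)
  ser <- gen_breath_series(resp_gen_params(dur_cv = 0.15, seed = 4), 600)$series
  cue <- runif(500, 5, 560)
  resp <- cue + runif(500, 0.3, 2.5)
  cond <- classify_block(cue, resp, ser)
  expect_false(any(is.na(cond)))
  expect_equal(sum(table(cond)), 500)
})

test_that("sextile occupancy tracks phase-bin durations for uniform times", {
  ser <- periodic_series(300)
  set.seed(9)
  # stay inside complete cycles: the last EI onset is at 299 * 3.55
  t <- runif(100000, 1, 299 * 3.55 - 1)
  tab <- table(classify_cue_sextile(project_phase(t, ser)))
  shares <- as.numeric(tab) / sum(tab)
  expected <- c(rep(1.46 / 3, 3), rep(2.09 / 3, 3)) / 3.55
  expect_true(all(abs(shares - expected) < 0.01))
})

test_that("expiration-in-interval integrates the expiratory overlap", {
  ser <- periodic_series(5)
  expect_equal(expiration_in_interval(0.2, 1.0, ser), 0)          # all insp
  expect_equal(expiration_in_interval(1.46, 3.55, ser), 2.09,
               tolerance = 1e-12)                                  # one full exp
  # half of the first expiration plus 0.3 s of inspiration
  expect_equal(expiration_in_interval(1.46 + 1.045, 3.55 + 0.3, ser), 1.045,
               tolerance = 1e-12)
})

test_that("condition summaries average per subject and flag missing cells", {
  blocks <- data.frame(
    subject = c(1, 1, 1, 2),
    condition = c("INS", "INS", "EI", "EXP"),
    rt = c(1, 2, 3, 1.5),
    correct = c(TRUE, FALSE, TRUE, TRUE),
    exp_dur_in_block = c(0, 0, 1.2, 0.8))
  s <- summarize_conditions(blocks)
  g <- function(su, co) s[s$subject == su & s$condition == co, ]
  expect_equal(g(1, "INS")$mean_rt, 1.5)
  expect_equal(g(1, "INS")$accuracy, 0.5)
  expect_equal(g(1, "EI")$accuracy, 1)
  expect_equal(g(2, "EXP")$mean_rt, 1.5)
  # subject 2 has no EI blocks: flagged missing, not zero
  expect_equal(g(2, "EI")$n_blocks, 0)
  expect_true(is.na(g(2, "EI")$mean_rt))
  # pooled INS+EXP row exists and combines the transition-free blocks
  expect_equal(g(1, "INS+EXP")$n_blocks, 2)
  expect_equal(g(1, "INS+EXP")$mean_rt, 1.5)
  # counts conserved within each subject
  tot1 <- sum(s$n_blocks[s$subject == 1 & s$condition %in%
                           c("INS", "IE", "EXP", "EI")])
  expect_equal(tot1, 3)
  expect_error(summarize_conditions(transform(blocks, condition = "Both")),
               "Both")
})

test_that("cue-to-response phase shifts follow rigid rotations", {
  set.seed(12)
  cues <- runif(200, 0, 360)
  out0 <- cue_response_phase_shift(cues, cues)
  expect_equal(out0$shift, 0, tolerance = 1e-9)
  expect_equal(out0$delta_sd, 0, tolerance = 1e-9)

  out30 <- cue_response_phase_shift(cues, (cues + 30) %% 360)
  expect_equal(out30$shift, 30, tolerance = 1e-9)
  expect_equal(out30$delta_sd, 0, tolerance = 1e-6)

  # uniform cues, concentrated responses: dispersion tightens by about the
  # circular SD of the uniform sample
  resp <- rnorm(200, 300, 5) %% 360
  outc <- cue_response_phase_shift(cues, resp)
  expect_lt(outc$delta_sd, 0)
  expect_lt(abs(-outc$delta_sd - circ_summary(cues)$circular_sd) /
              circ_summary(cues)$circular_sd, 0.25)
  expect_error(cue_response_phase_shift(1:3, 1:4), "paired")
})
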