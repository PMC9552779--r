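test_that("assumption routing matches Shapiro-Wilk's nominal behavior", {
  # normal data: the parametric-route frequency should match the chance that
  # all k Shapiro tests pass, (1 - alpha)^k
  k <- 3; reps <- 200
  routes <- vapply(seq_len(reps), function(r) {
    route_assumptions(balanced_table(n = 25, k = k, seed = 1000 + r))$route
  }, character(1))
  p_expect <- 0.95^k
  se <- sqrt(p_expect * (1 - p_expect) / reps)
  expect_lt(abs(mean(routes == "parametric") - p_expect), 3 * se + 0.02)

  # heavily skewed data is routed nonparametric essentially always
  routes2 <- vapply(seq_len(100), function(r) {
    set.seed(2000 + r)
    tab <- balanced_table(n = 25, k = k, seed = 2000 + r)
    tab$value <- rexp(nrow(tab))
    route_assumptions(tab)$route
  }, character(1))
  expect_gte(mean(routes2 == "nonparametric"), 0.95)
})

test_that("sphericity is trivially satisfied at k = 2 and GG flags only k >= 3", {
  rt <- route_assumptions(balanced_table(n = 20, k = 2, seed = 5))
  expect_true(is.na(rt$mauchly_p))
  expect_false(rt$use_gg)
  # a zero-variance condition is a normality failure, not an error
  tab <- balanced_table(n = 10, k = 3, seed = 6)
  tab$value[tab$condition == "c1"] <- 0
  expect_equal(route_assumptions(tab)$route, "nonparametric")
})

test_that("repeated-measures ANOVA carries the textbook df and limits", {
  a <- rm_anova_gg(balanced_table(n = 25, k = 4, seed = 1))
  expect_equal(a$df, c(3, 72))
  a2 <- rm_anova_gg(balanced_table(n = 25, k = 3, seed = 2))
  expect_equal(a2$df, c(2, 48))
  expect_lte(a$epsilon_gg, 1)

  # identical conditions per subject: F = 0
  tab <- balanced_table(n = 8, k = 4, seed = 3)
  w <- tab$value[tab$condition == "c1"]
  tab$value <- rep(w, 4)
  expect_equal(rm_anova_gg(tab)$statistic, 0, tolerance = 1e-12)

  # with epsilon forced to 1 the GG p equals the uncorrected p
  a3 <- rm_anova_gg(balanced_table(n = 12, k = 3, seed = 4), gg = FALSE)
  expect_equal(a3$p, a3$p_uncorrected)
})

test_that("RM-ANOVA matches a brute-force sums-of-squares oracle", {
  # 4 subjects x 3 conditions, computed from first principles
  w <- matrix(c(1.0, 2.0, 1.5,
                2.2, 2.9, 2.4,
                0.7, 1.4, 1.1,
                1.9, 2.6, 2.0), 4, 3, byrow = TRUE)
  tab <- data.frame(subject = rep(1:4, 3),
                    condition = rep(c("a", "b", "c"), each = 4),
                    value = as.vector(w))
  n <- 4; k <- 3
  grand <- mean(w)
  ss_cond <- n * sum((colMeans(w) - grand)^2)
  ss_subj <- k * sum((rowMeans(w) - grand)^2)
  ss_err <- sum((w - outer(rowMeans(w), colMeans(w), "+") + grand)^2)
  F_oracle <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  S <- cov(w); C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  eps_oracle <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  a <- rm_anova_gg(tab)
  expect_equal(a$statistic, F_oracle, tolerance = 1e-10)
  expect_equal(a$epsilon_gg, min(eps_oracle, 1), tolerance = 1e-10)
  expect_equal(a$p_uncorrected, pf(F_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against base aov on the same layout
  av <- summary(stats::aov(value ~ factor(condition) +
                             Error(factor(subject)), data = tab))
  F_aov <- av[["Error: Within"]][[1]]["factor(condition)", "F value"]
  expect_equal(a$statistic, F_aov, tolerance = 1e-8)
})

test_that("Friedman test carries df k-1 and matches the rank formula", {
  f <- friedman(balanced_table(n = 25, k = 4, seed = 7))
  expect_equal(f$df, 3)

  # tie-free 3 x 3 toy table against the direct rank-sum formula
  w <- matrix(c(1, 2, 3,
                2, 3, 1,
                1, 3, 2), 3, 3, byrow = TRUE)
  tab <- data.frame(subject = rep(1:3, 3),
                    condition = rep(c("a", "b", "c"), each = 3),
                    value = as.vector(w))
  R <- rowSums(apply(w, 1, rank))  # rank sums per condition
  n <- 3; k <- 3
  chi_oracle <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  expect_equal(friedman(tab)$statistic, chi_oracle, tolerance = 1e-10)

  # identical columns: no information, statistic 0
  tab0 <- data.frame(subject = rep(1:5, 3),
                     condition = rep(c("a", "b", "c"), each = 5),
                     value = rep(rnorm(5), 3))
  expect_error(friedman(tab0), "constant")
})

test_that("Friedman is invariant to monotone transforms", {
  tab <- balanced_table(n = 10, k = 4, seed = 8)
  f1 <- friedman(tab)$statistic
  tab$value <- exp(tab$value)
  expect_equal(friedman(tab)$statistic, f1, tolerance = 1e-10)
})

test_that("post hocs enumerate all pairs with a Bonferroni factor", {
  tab <- balanced_table(n = 12, k = 4, seed = 9)
  ph <- posthoc_pairwise(tab, "parametric")
  expect_equal(nrow(ph), 6)
  expect_equal(ph$p_adjusted, pmin(ph$p_raw * 6, 1))
  expect_true(all(ph$df == 11))

  # identical pair: corrected p = 1 on both routes
  tab2 <- balanced_table(n = 10, k = 2, seed = 10)
  tab2$value <- rep(tab2$value[tab2$condition == "c1"], 2)
  expect_equal(posthoc_pairwise(tab2, "nonparametric")$p_adjusted, 1)
  expect_equal(posthoc_pairwise(tab2, "parametric")$p_adjusted, 1)
})

test_that("one-sample t matches hand arithmetic", {
  r <- one_sample_t(rnorm(25))
  expect_equal(r$df, 24)
  expect_equal(one_sample_t(c(-2, -1, 1, 2))$statistic, 0, tolerance = 1e-12)
  # {1,2,3}: mean 2, sd 1, t = 2 sqrt(3)
  r3 <- one_sample_t(c(1, 2, 3))
  expect_equal(r3$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r3$df, 2)
  expect_error(one_sample_t(rep(1, 5)), "zero variance")
})

test_that("rmcorr carries df N(k-1)-1 and nails exact linear structure", {
  set.seed(11)
  sub <- rep(1:25, each = 3)
  x <- rnorm(75)
  y <- x + rep(rnorm(25, 0, 5), each = 3)   # exact slope 1 within subject
  r <- suppressWarnings(rmcorr(x, y, sub))  # perfect fit trips lm warnings
  expect_equal(r$df, 49)
  expect_equal(r$statistic, 1, tolerance = 1e-7)

  expect_error(rmcorr(1:3, 1:3, c(1, 1, 2)), "at least 2 observations")
})

test_that("rmcorr equals a brute-force blocked ANCOVA oracle", {
  x <- c(1.0, 2.0, 3.0, 0.5, 1.5, 2.5, 2.0, 3.0, 4.0)
  y <- c(1.1, 1.9, 3.2, 2.6, 3.4, 4.1, 0.9, 2.2, 2.8)
  sub <- rep(1:3, each = 3)
  # oracle: center x and y within subject, then correlate the residuals;
  # equivalently sequential SS from the blocked linear model
  xc <- x - ave(x, sub)
  yc <- y - ave(y, sub)
  slope <- sum(xc * yc) / sum(xc^2)
  ss_x <- slope^2 * sum(xc^2)
  ss_e <- sum((yc - slope * xc)^2)
  r_oracle <- sign(slope) * sqrt(ss_x / (ss_x + ss_e))
  r <- rmcorr(x, y, sub)
  expect_equal(r$statistic, r_oracle, tolerance = 1e-10)
  expect_equal(r$df, length(x) - 3 - 1)
  # Fisher-z CI with SE 1/sqrt(df - 3)
  z <- atanh(r_oracle)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) / sqrt(r$df - 3))
  expect_equal(r$ci, ci, tolerance = 1e-10)
})

test_that("rmcorr is invariant to per-subject shifts of either variable", {
  set.seed(13)
  sub <- rep(1:10, each = 4)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  r0 <- rmcorr(x, y, sub)$statistic
  x2 <- x + rep(rnorm(10, 0, 100), each = 4)
  y2 <- y + rep(rnorm(10, 0, 100), each = 4)
  expect_equal(rmcorr(x2, y2, sub)$statistic, r0, tolerance = 1e-8)
})

test_that("the routed omnibus returns a coherent bundle", {
  tab <- balanced_table(n = 20, k = 3, effect = c(0, 0, 2), seed = 14)
  out <- run_omnibus(tab)
  expect_true(out$route$route %in% c("parametric", "nonparametric"))
  expect_s3_class(out$omnibus, "stat_result")
  expect_equal(nrow(out$posthoc), 3)
  expect_lt(out$omnibus$p, 0.01)  # a 2-SD planted effect at n = 20 is obvious
})
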