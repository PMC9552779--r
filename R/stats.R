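#' @name stats_battery
#' @title Repeated-measures statistical battery with assumption routing
#' @description
#' The battery mirrors the decision logic used for within-subject condition
#' comparisons in respiration-locked task studies: condition-wise
#' Shapiro-Wilk normality checks and a Mauchly sphericity check route the
#' omnibus test to a one-way repeated-measures ANOVA (with Greenhouse-Geisser
#' correction when sphericity is violated) or to the nonparametric Friedman
#' test, followed by Bonferroni-corrected pairwise post hocs (paired t or
#' Wilcoxon signed-rank, matching the route).
#'
#' All functions take a balanced long table: a data.frame with columns
#' `subject`, `condition`, `value`.
NULL

stat_result <- function(test_name, statistic, df, p, epsilon_gg = NA_real_,
                        ci = c(NA_real_, NA_real_), correction = "none",
                        extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic, df = df,
                   p = p, epsilon_gg = epsilon_gg, ci = ci,
                   correction = correction), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g", x$test_name,
              x$statistic, dfs, x$p))
  if (!is.na(x$epsilon_gg)) cat(sprintf(", GG epsilon = %.3f", x$epsilon_gg))
  if (!all(is.na(x$ci))) cat(sprintf(", 95%% CI [%.3f, %.3f]", x$ci[1], x$ci[2]))
  if (x$correction != "none") cat(sprintf(" (%s)", x$correction))
  cat("\n")
  invisible(x)
}

# long (subject, condition, value) -> subjects x conditions matrix; errors on
# unbalanced designs
long_to_wide <- function(table) {
  stopifnot(all(c("subject", "condition", "value") %in% names(table)))
  subs <- unique(table$subject)
  conds <- unique(table$condition)
  tab <- base::table(table$subject, table$condition)
  if (any(tab != 1)) stop("unbalanced table: each subject needs exactly one value per condition")
  w <- matrix(NA_real_, length(subs), length(conds),
              dimnames = list(as.character(subs), as.character(conds)))
  w[cbind(match(table$subject, subs), match(table$condition, conds))] <- table$value
  w
}

#' Route a condition table to a parametric or nonparametric analysis
#'
#' Shapiro-Wilk is applied per condition; if any condition departs from
#' normality at `alpha`, the whole family is routed to the nonparametric
#' branch (Friedman + Wilcoxon post hocs). Sphericity (Mauchly, for k >= 3)
#' violated alone does not change the route: the parametric branch then uses
#' the Greenhouse-Geisser correction. With k = 2 sphericity holds trivially.
#'
#' @param table long data.frame (`subject`, `condition`, `value`).
#' @param alpha significance level for the assumption checks (default 0.05).
#' @return a list: `route` ("parametric"/"nonparametric"), `use_gg` (logical),
#'   `shapiro` (per-condition p-values), `mauchly_p`.
#' @export
route_assumptions <- function(table, alpha = 0.05) {
  w <- long_to_wide(table)
  if (nrow(w) < 3) stop("need at least 3 subjects")
  k <- ncol(w)
  # a zero-variance condition is degenerate: treat as a normality failure
  shapiro <- apply(w, 2, function(v) {
    if (length(unique(v)) == 1) 0 else shapiro.test(v)$p.value
  })
  mauchly_p <- NA_real_
  if (k >= 3) {
    mauchly_p <- tryCatch(
      mauchly.test(lm(w ~ 1), X = ~1)$p.value,
      error = function(e) NA_real_)
  }
  normal_ok <- all(shapiro >= alpha)
  spherical <- is.na(mauchly_p) || mauchly_p >= alpha
  list(route = if (normal_ok) "parametric" else "nonparametric",
       use_gg = normal_ok && !spherical,
       shapiro = shapiro, mauchly_p = mauchly_p)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject sums-of-squares decomposition: F with df
#' (k-1, (k-1)(n-1)). The Greenhouse-Geisser epsilon is computed from the
#' double-centered condition covariance matrix; `p` is evaluated at
#' epsilon-scaled df when `gg = TRUE`, and the uncorrected p-value is also
#' returned.
#'
#' @param table long data.frame (`subject`, `condition`, `value`).
#' @param gg apply the Greenhouse-Geisser correction to the reported p
#'   (default TRUE).
#' @return a `stat_result` (extra fields: `p_uncorrected`).
#' @export
rm_anova_gg <- function(table, gg = TRUE) {
  w <- long_to_wide(table)
  n <- nrow(w); k <- ncol(w)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  grand <- mean(w)
  cm <- colMeans(w); rm_ <- rowMeans(w)
  ss_cond <- n * sum((cm - grand)^2)
  ss_subj <- k * sum((rm_ - grand)^2)
  ss_tot <- sum((w - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  if (ss_tot <= .Machine$double.eps * max(1, abs(grand))) {
    stop("zero variance across all cells")
  }
  Fv <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  # GG epsilon from the double-centered covariance of conditions; a
  # degenerate (zero) within-subject covariance is spherical by convention
  S <- stats::cov(w)
  C <- diag(k) - matrix(1 / k, k, k)
  Sc <- C %*% S %*% C
  eps <- if (sum(Sc^2) <= .Machine$double.eps) 1 else
    min(sum(diag(Sc))^2 / (df1 * sum(Sc^2)), 1)
  p_unc <- pf(Fv, df1, df2, lower.tail = FALSE)
  p_gg <- pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
  stat_result("repeated-measures ANOVA", Fv, c(df1, df2),
              p = if (gg) p_gg else p_unc, epsilon_gg = eps,
              correction = if (gg) "Greenhouse-Geisser" else "none",
              extra = list(p_uncorrected = p_unc,
                           ss = c(condition = ss_cond, subject = ss_subj,
                                  error = ss_err)))
}

#' Friedman rank-sum test
#'
#' Nonparametric omnibus for k repeated conditions; chi-squared statistic
#' with df k-1, average ranks on ties (via [stats::friedman.test()]).
#'
#' @param table long data.frame (`subject`, `condition`, `value`).
#' @return a `stat_result`.
#' @export
friedman <- function(table) {
  w <- long_to_wide(table)
  if (all(apply(w, 1, function(r) length(unique(r)) == 1))) {
    stop("all rows constant: Friedman statistic undefined")
  }
  ft <- friedman.test(w)
  stat_result("Friedman rank sum test", unname(ft$statistic),
              unname(ft$parameter), ft$p.value)
}

#' Bonferroni-corrected pairwise post hoc comparisons
#'
#' All k(k-1)/2 condition pairs, each tested with a paired t test
#' (parametric route) or Wilcoxon signed-rank test (nonparametric route;
#' zero differences dropped, average ranks). Raw p-values are multiplied by
#' the number of pairs and clipped at 1.
#'
#' @param table long data.frame (`subject`, `condition`, `value`).
#' @param route `"parametric"` or `"nonparametric"`.
#' @return a data.frame: cond1, cond2, statistic, df, p_raw, p_adjusted.
#' @export
posthoc_pairwise <- function(table, route = c("parametric", "nonparametric")) {
  route <- match.arg(route)
  w <- long_to_wide(table)
  k <- ncol(w)
  if (k < 2) stop("need at least 2 conditions")
  pairs <- utils::combn(colnames(w), 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- w[, pairs[1, j]]; b <- w[, pairs[2, j]]
    if (all(a == b)) {
      # identical conditions carry no paired evidence
      return(data.frame(cond1 = pairs[1, j], cond2 = pairs[2, j],
                        statistic = 0, df = NA_real_, p_raw = 1))
    }
    if (route == "parametric") {
      tt <- t.test(a, b, paired = TRUE)
      data.frame(cond1 = pairs[1, j], cond2 = pairs[2, j],
                 statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value)
    } else {
      wt <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                         correct = TRUE))
      data.frame(cond1 = pairs[1, j], cond2 = pairs[2, j],
                 statistic = unname(wt$statistic), df = NA_real_,
                 p_raw = wt$p.value)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(out$p_raw * m, 1)
  out
}

#' Omnibus test with assumption routing
#'
#' Convenience wrapper running [route_assumptions()] and then either
#' [rm_anova_gg()] (Greenhouse-Geisser only when Mauchly rejects) or
#' [friedman()], plus the matching post hocs.
#'
#' @param table long data.frame (`subject`, `condition`, `value`).
#' @param alpha assumption-check level.
#' @return a list: `route`, `omnibus` (stat_result), `posthoc` (data.frame).
#' @export
run_omnibus <- function(table, alpha = 0.05) {
  rt <- route_assumptions(table, alpha)
  if (rt$route == "parametric") {
    om <- rm_anova_gg(table, gg = rt$use_gg)
    ph <- posthoc_pairwise(table, "parametric")
  } else {
    om <- friedman(table)
    ph <- posthoc_pairwise(table, "nonparametric")
  }
  list(route = rt, omnibus = om, posthoc = ph)
}

#' Two-sided one-sample t test against a constant
#'
#' @param values numeric vector (n >= 2).
#' @param mu null value (default 0).
#' @return a `stat_result` with the 95% CI of the mean.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2) stop("need at least 2 values")
  if (sd(values) == 0) stop("zero variance")
  tt <- t.test(values, mu = mu)
  stat_result("one-sample t test", unname(tt$statistic),
              unname(tt$parameter), tt$p.value,
              ci = as.numeric(tt$conf.int))
}

#' Repeated-measures correlation
#'
#' Common within-subject linear association between two measures, estimated
#' by analysis of covariance with subject as a blocking factor:
#' `r_rm = sign(slope) * sqrt(SS_measure / (SS_measure + SS_error))` with
#' `df = N_obs - n_subjects - 1`. The 95% CI uses the Fisher z transform
#' with standard error `1/sqrt(df - 3)`.
#'
#' @param x,y paired numeric vectors.
#' @param subject subject identifier vector (>= 2 observations each).
#' @return a `stat_result` (statistic is r_rm; extra field `slope`).
#' @export
rmcorr <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  if (any(base::table(subject) < 2)) {
    stop("every subject needs at least 2 observations")
  }
  subject <- factor(subject)
  fit <- lm(y ~ subject + x)
  a <- anova(fit)
  ss_x <- a["x", "Sum Sq"]
  ss_e <- a["Residuals", "Sum Sq"]
  dfe <- a["Residuals", "Df"]
  slope <- unname(coef(fit)["x"])
  r <- sign(slope) * sqrt(ss_x / (ss_x + ss_e))
  tv <- r * sqrt(dfe / (1 - r^2))
  p <- 2 * pt(-abs(tv), dfe)
  z <- atanh(r); se <- 1 / sqrt(dfe - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  stat_result("repeated-measures correlation", r, dfe, p, ci = ci,
              extra = list(slope = slope, t = tv))
}
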