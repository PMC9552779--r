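#' Hit and false-alarm rates with extreme-rate correction
#'
#' Hit rate is P(choice "old" | truth old) and false-alarm rate
#' P(choice "old" | truth new). Because z-scores diverge at 0 and 1, rates
#' are corrected before use: the default log-linear correction adds 0.5 to
#' every cell count and 1 to every denominator, applied to all cells for
#' comparability; `"clamp"` instead replaces 0 with 1/(2N) and 1 with
#' 1 - 1/(2N).
#'
#' @param is_old logical vector: truth labels of the test cues.
#' @param choice_old logical vector: whether the subject answered "old".
#' @param correction `"loglinear"` (default) or `"clamp"`.
#' @return a list: `hit`, `fa`, `n_old`, `n_new`, `correction`.
#' @export
sdt_rates <- function(is_old, choice_old, correction = c("loglinear", "clamp")) {
  correction <- match.arg(correction)
  stopifnot(length(is_old) == length(choice_old))
  n_old <- sum(is_old); n_new <- sum(!is_old)
  if (n_old == 0 || n_new == 0) stop("need at least one old and one new trial")
  h <- sum(is_old & choice_old)
  f <- sum(!is_old & choice_old)
  if (correction == "loglinear") {
    hit <- (h + 0.5) / (n_old + 1)
    fa  <- (f + 0.5) / (n_new + 1)
  } else {
    hit <- h / n_old; fa <- f / n_new
    hit <- min(max(hit, 1 / (2 * n_old)), 1 - 1 / (2 * n_old))
    fa  <- min(max(fa,  1 / (2 * n_new)), 1 - 1 / (2 * n_new))
  }
  list(hit = hit, fa = fa, n_old = n_old, n_new = n_new,
       correction = correction)
}

#' Discriminability d-prime
#'
#' `d' = z(hit) - z(false alarm)`, the separation of the old/new evidence
#' distributions in equal-variance signal detection theory.
#'
#' @param hit,fa rates strictly inside (0, 1) (pre-corrected).
#' @return numeric d-prime.
#' @export
dprime <- function(hit, fa) {
  if (any(hit <= 0 | hit >= 1 | fa <= 0 | fa >= 1)) {
    stop("rates must lie strictly in (0, 1); apply sdt_rates() correction first")
  }
  qnorm(hit) - qnorm(fa)
}

#' Decision criterion c
#'
#' `c = -(z(hit) + z(false alarm)) / 2`; positive values indicate a
#' conservative bias toward answering "new".
#'
#' @inheritParams dprime
#' @return numeric criterion.
#' @export
criterion_c <- function(hit, fa) {
  if (any(hit <= 0 | hit >= 1 | fa <= 0 | fa >= 1)) {
    stop("rates must lie strictly in (0, 1); apply sdt_rates() correction first")
  }
  -(qnorm(hit) + qnorm(fa)) / 2
}

#' Signal-detection table per subject and condition
#'
#' Computes corrected rates, d-prime, and criterion c per subject x
#' condition cell (per-subject estimates, to be averaged or compared across
#' subjects downstream — never pooled counts).
#'
#' @param blocks data.frame with columns `subject`, `condition`, `is_old`,
#'   `choice_old`.
#' @param correction passed to [sdt_rates()].
#' @return a data.frame: subject, condition, n_old, n_new, hit, fa, dprime,
#'   criterion, correction.
#' @export
sdt_table <- function(blocks, correction = "loglinear") {
  stopifnot(all(c("subject", "condition", "is_old", "choice_old") %in%
                  names(blocks)))
  cells <- unique(blocks[c("subject", "condition")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- blocks$subject == cells$subject[i] &
      blocks$condition == cells$condition[i]
    r <- sdt_rates(blocks$is_old[sel], blocks$choice_old[sel], correction)
    data.frame(subject = cells$subject[i],
               condition = cells$condition[i],
               n_old = r$n_old, n_new = r$n_new, hit = r$hit, fa = r$fa,
               dprime = dprime(r$hit, r$fa),
               criterion = criterion_c(r$hit, r$fa),
               correction = r$correction)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
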