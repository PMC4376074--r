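# Independent oracles used across the suite. These deliberately take the
# slow, enumerate-everything route so they share no code with the package
# implementations they check.

# Exhaustive gap-tolerant run search: enumerate every window [i, j] of a
# positivity vector, keep windows whose boundaries are positive, whose
# interior holds at most `max_gaps` non-positives, and which contain at
# least `min_positive` positives; then decompose left to right, always
# taking the leftmost-starting (ties: longest) valid window after the
# previous one. Returns a list of c(start_idx, end_idx, n_positive).
oracle_gap_runs <- function(p, min_positive = 4, max_gaps = 1) {
  n <- length(p)
  if (n == 0) return(list())
  cum <- cumsum(p)
  npos <- function(i, j) cum[j] - if (i > 1) cum[i - 1] else 0
  valid <- list()
  for (i in seq_len(n)) {
    if (!p[i]) next
    for (j in i:n) {
      if (!p[j]) next
      tot <- npos(i, j)
      interior_nonpos <- (j - i + 1) - tot
      if (interior_nonpos <= max_gaps && tot >= min_positive) {
        valid[[length(valid) + 1]] <- c(i, j, tot)
      }
    }
  }
  if (!length(valid)) return(list())
  vm <- do.call(rbind, valid)
  out <- list()
  pos <- 1
  repeat {
    cand <- vm[vm[, 1] >= pos, , drop = FALSE]
    if (nrow(cand) == 0) break
    cand <- cand[cand[, 1] == min(cand[, 1]), , drop = FALSE]
    pick <- cand[which.max(cand[, 2]), ]
    out[[length(out) + 1]] <- pick
    pos <- pick[2] + 1
  }
  out
}

# Two-sided Fisher's exact P for a 2x2 table by direct hypergeometric
# summation over all tables with the observed margins.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pooled-variance two-sample t-test P value from the textbook formula.
oracle_student_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(tstat), df = na + nb - 2)
}

# Fraction-scale odds skew, written on the odds scale (independent of the
# generator's ratio formula).
oracle_apply_skew <- function(f, s) {
  if (f == 0) return(0)
  if (f == 1) return(1)
  odds <- s * f / (1 - f)
  odds / (1 + odds)
}
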