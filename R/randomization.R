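# Randomization-based interval: the group sequential analysis is re-run over
# re-randomized treatment allocations with the observed patient outcomes held
# fixed.  The adjusted p-value at a hypothesized effect theta0 is the
# proportion of allocations whose (stopping stage, statistic) pair is as
# extreme or more extreme -- in the stagewise ordering -- than the observed
# one after the hypothesized effect has been removed from the treated
# outcomes; the interval inverts this p-value over theta0 with a common set
# of allocations across evaluations.  The per-stage statistic is studentized
# by the allocation-invariant dispersion of the effect-removed outcomes, so
# that permuting labels within identical group compositions leaves it
# unchanged.

randomization_row <- function(outcome, level, resamples, seed = NULL,
                              truncate = FALSE) {
  design <- outcome$design
  al <- 1 - level
  pats <- patient_level(outcome)
  n1t <- design$n1_treatment; n1c <- design$n1_control
  d2t <- design$n2_treatment - n1t; d2c <- design$n2_control - n1c
  has2 <- outcome$stop_stage == 2L
  A2 <- NULL
  A1 <- with_seed(seed, {
    a1 <- t(vapply(seq_len(resamples), function(i) {
      g <- numeric(n1c + n1t); g[sample.int(n1c + n1t, n1t)] <- 1; g
    }, numeric(n1c + n1t)))
    if (has2) {
      A2 <- t(vapply(seq_len(resamples), function(i) {
        g <- numeric(d2c + d2t); g[sample.int(d2c + d2t, d2t)] <- 1; g
      }, numeric(d2c + d2t)))
    }
    a1
  })
  sf1 <- sqrt(1 / n1c + 1 / n1t)
  sf2 <- sqrt(1 / design$n2_control + 1 / design$n2_treatment)

  # adjusted p-value function: proportion of allocations as extreme or more
  # extreme than the observed result, increasing in theta0
  p_adj <- function(theta0) {
    ys1 <- pats$y1 - theta0 * pats$g1
    sd1 <- sd(ys1)
    z1_of <- function(st) ((st / n1t) - ((sum(ys1) - st) / n1c) + theta0) /
      (sd1 * sf1)
    z1r <- z1_of(as.vector(A1 %*% ys1))
    z1o <- z1_of(sum(ys1[pats$g1 == 1]))
    t1r <- z1r >= design$e1
    t1o <- z1o >= design$e1
    if (has2) {
      ys2 <- pats$y2 - theta0 * pats$g2
      sdA <- sd(c(ys1, ys2))
      tot <- sum(ys1) + sum(ys2)
      z2_of <- function(st) {
        ((st / design$n2_treatment) -
           ((tot - st) / design$n2_control) + theta0) / (sdA * sf2)
      }
      z2r <- z2_of(as.vector(A1 %*% ys1) + as.vector(A2 %*% ys2))
      z2o <- z2_of(sum(ys1[pats$g1 == 1]) + sum(ys2[pats$g2 == 1]))
    }
    if (t1o || !has2) {
      # observed result stopped at stage 1: only stage-1 stoppers with a
      # larger statistic are more extreme
      mean(t1r & z1r >= z1o)
    } else {
      mean(t1r | (!t1r & z2r >= z2o))
    }
  }
  zero_p <- p_adj(0) == 0
  f <- function(th, idx) vapply(th, p_adj, numeric(1))
  lo <- vroot_increasing(f, al / 2, iters = 40L)
  up <- vroot_increasing(f, 1 - al / 2, iters = 40L)
  pt <- vroot_increasing(f, 0.5, iters = 40L)
  tibble(
    rep = 1L, method = "randomization",
    point = pt$root,
    lower = if (truncate) max(lo$root, -1) else lo$root,
    upper = if (truncate) min(up$root, 1) else up$root,
    empty = FALSE,
    failed = lo$failed || up$failed,
    trunc_lower = truncate && !is.na(lo$root) && lo$root < -1,
    trunc_upper = truncate && !is.na(up$root) && up$root > 1,
    zero_p = zero_p
  )
}

# reconstruct a patient-level outcome/allocation table from the cumulative
# counts (outcome order within arm and stage is exchangeable)
patient_level <- function(outcome) {
  counts <- outcome$counts
  w1 <- counts_wide(counts, 1)
  y1 <- c(rep(1, w1$s_control), rep(0, w1$n_control - w1$s_control),
          rep(1, w1$s_treatment), rep(0, w1$n_treatment - w1$s_treatment))
  g1 <- c(rep(0, w1$n_control), rep(1, w1$n_treatment))
  out <- list(y1 = y1, g1 = g1)
  if (outcome$stop_stage == 2L) {
    w2 <- counts_wide(counts, 2)
    ic <- w2$s_control - w1$s_control
    it <- w2$s_treatment - w1$s_treatment
    nc <- w2$n_control - w1$n_control
    nt <- w2$n_treatment - w1$n_treatment
    out$y2 <- c(rep(1, ic), rep(0, nc - ic), rep(1, it), rep(0, nt - it))
    out$g2 <- c(rep(0, nc), rep(1, nt))
  }
  out
}
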