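# Vectorized interval computations over a replicate frame (see
# trials_frame()).  Each iv_* function returns a tibble aligned with the
# input rows: lower, upper, empty, failed (and where natural a point
# estimate).  Intervals are reported untruncated; truncation to the
# parameter space [-1, 1] is applied by the caller on request.

q2 <- function(level) qnorm(1 - (1 - level) / 2)

iv_blank <- function(n) {
  tibble(lower = rep(NA_real_, n), upper = rep(NA_real_, n),
         point = rep(NA_real_, n),
         empty = rep(FALSE, n), failed = rep(FALSE, n))
}

iv_wald <- function(reps, design, level) {
  out <- iv_blank(nrow(reps))
  q <- q2(level)
  out$lower <- reps$theta_hat - q * reps$se_w
  out$upper <- reps$theta_hat + q * reps$se_w
  out$point <- reps$theta_hat
  out$failed <- !reps$valid
  out$lower[out$failed] <- NA_real_
  out$upper[out$failed] <- NA_real_
  out
}

iv_repeated <- function(reps, design, level) {
  out <- iv_blank(nrow(reps))
  half <- ifelse(reps$stage == 1L,
                 design$e1 / sqrt(reps$info1),
                 design$e2 / sqrt(reps$info2_obs))
  out$lower <- reps$theta_hat - half
  out$upper <- reps$theta_hat + half
  out$failed <- !reps$valid
  out$lower[out$failed] <- NA_real_
  out$upper[out$failed] <- NA_real_
  out
}

iv_final_unconditional <- function(reps, design, level) {
  al <- 1 - level
  out <- iv_blank(nrow(reps))
  out$failed <- !reps$valid |
    (reps$stage == 2L & reps$info2_obs <= reps$info1)
  t1 <- which(reps$stage == 1L & !out$failed)
  if (length(t1)) {
    s1 <- sqrt(reps$info1[t1])
    out$lower[t1] <- (qnorm(al / 2) + reps$z1[t1]) / s1
    out$upper[t1] <- (qnorm(1 - al / 2) + reps$z1[t1]) / s1
    out$point[t1] <- reps$z1[t1] / s1   # MUE closed form: 0.5 root
  }
  t2 <- which(reps$stage == 2L & !out$failed)
  if (length(t2)) {
    s1 <- sqrt(reps$info1[t2]); s2 <- sqrt(reps$info2_obs[t2])
    rho <- s1 / s2
    z2 <- reps$z2[t2]
    e1 <- design$e1
    f <- function(th, idx) {
      a <- e1 - th * s1[idx]
      pnorm(a, lower.tail = FALSE) +
        pbvn_cont(a, z2[idx] - th * s2[idx], rho[idx])
    }
    m <- length(t2)
    lo <- vroot_increasing(f, rep(al / 2, m))
    up <- vroot_increasing(f, rep(1 - al / 2, m))
    out$lower[t2] <- lo$root
    out$upper[t2] <- up$root
    out$failed[t2] <- lo$failed | up$failed
  }
  out
}

# exact first two moments of the stopped MLE under the canonical model;
# all terms are available in closed form because the stopping region is a
# half-line in the stage-1 statistic
stopped_mle_moments <- function(theta, info1, info2, e1) {
  s1 <- sqrt(info1)
  c1 <- e1 - theta * s1
  phi <- dnorm(c1)
  Phi <- pnorm(c1)
  bias <- phi * (1 / s1 - s1 / info2)
  m2 <- theta^2 + 2 * theta * bias +
    (1 - Phi + c1 * phi) / info1 +
    (Phi - (info1 / info2) * c1 * phi) / info2
  list(mean_bias = bias, var = m2 - (theta + bias)^2)
}

iv_adjusted_asymptotic <- function(reps, design, level) {
  out <- iv_blank(nrow(reps))
  q <- q2(level)
  out$failed <- !reps$valid |
    (reps$stage == 2L & reps$info2_obs < reps$info1)
  ok <- which(!out$failed)
  mom <- stopped_mle_moments(reps$theta_hat[ok], reps$info1[ok],
                             reps$info2[ok], design$e1)
  centre <- reps$theta_hat[ok] - mom$mean_bias
  hw <- q * sqrt(pmax(mom$var, 0))
  out$lower[ok] <- centre - hw
  out$upper[ok] <- centre + hw
  out$point[ok] <- centre
  out
}

iv_final_conditional <- function(reps, design, level) {
  al <- 1 - level
  out <- iv_blank(nrow(reps))
  out$failed <- !reps$valid |
    (reps$stage == 2L & reps$info2_obs <= reps$info1)
  e1 <- design$e1
  t1 <- which(reps$stage == 1L & !out$failed)
  if (length(t1)) {
    s1 <- sqrt(reps$info1[t1])
    z1 <- pmax(reps$z1[t1], e1)
    f <- function(th, idx) {
      exp(pnorm(z1[idx] - th * s1[idx], lower.tail = FALSE, log.p = TRUE) -
            pnorm(e1 - th * s1[idx], lower.tail = FALSE, log.p = TRUE))
    }
    m <- length(t1)
    lo <- vroot_increasing(f, rep(al / 2, m), max_double = 14L, iters = 80L)
    up <- vroot_increasing(f, rep(1 - al / 2, m), max_double = 14L,
                           iters = 80L)
    out$lower[t1] <- lo$root
    out$upper[t1] <- up$root
    out$failed[t1] <- lo$failed | up$failed
  }
  t2 <- which(reps$stage == 2L & !out$failed)
  if (length(t2)) {
    s1 <- sqrt(reps$info1[t2]); s2 <- sqrt(reps$info2_obs[t2])
    rho <- s1 / s2
    th_obs <- reps$theta_hat[t2]
    f <- function(th, idx) {
      pcond_exceed(e1 - th * s1[idx],
                   (th_obs[idx] - th) * s2[idx], rho[idx])
    }
    m <- length(t2)
    lo <- vroot_increasing(f, rep(al / 2, m))
    up <- vroot_increasing(f, rep(1 - al / 2, m))
    out$lower[t2] <- lo$root
    out$upper[t2] <- up$root
    out$failed[t2] <- lo$failed | up$failed
  }
  out
}

# restriction of the conditional interval to the effect sizes under which
# the observed stopping stage is not too improbable; closed-form caps
iv_restricted <- function(cond, reps, design, level) {
  al <- 1 - level
  out <- cond
  s1 <- sqrt(reps$info1)
  cap_upper <- (design$e1 - qnorm(al / 2)) / s1       # T = 2 cap
  cap_lower <- (design$e1 - qnorm(1 - al / 2)) / s1   # T = 1 floor
  t2 <- reps$stage == 2L & !cond$failed
  out$upper[t2] <- pmin(cond$upper[t2], cap_upper[t2])
  t1 <- reps$stage == 1L & !cond$failed
  out$lower[t1] <- pmax(cond$lower[t1], cap_lower[t1])
  out$empty <- !out$failed & out$lower > out$upper
  out$lower[out$empty] <- NA_real_
  out$upper[out$empty] <- NA_real_
  out
}

# ---- bootstrap-based methods ----

# percentile bounds per replicate from a rep-indexed vector of bootstrap
# estimates; reps with fewer retained draws than floor_n fail
boot_percentiles <- function(est, rep_idx, n_reps, level, floor_n = 1L) {
  al <- 1 - level
  keep <- is.finite(est)
  sp <- split(est[keep], factor(rep_idx[keep], levels = seq_len(n_reps)))
  counts <- lengths(sp)
  qs <- vapply(sp, function(v) {
    if (length(v) < max(floor_n, 1L)) return(c(NA_real_, NA_real_, NA_real_))
    c(quantile(v, c(al / 2, 1 - al / 2), names = FALSE), mean(v))
  }, numeric(3))
  list(lower = qs[1, ], upper = qs[2, ], point = qs[3, ], n_used = counts)
}

iv_parametric_bootstrap <- function(reps, design, level, boot_reps,
                                    seed = NULL) {
  n <- nrow(reps)
  out <- iv_blank(n)
  out$failed <- !reps$valid
  ok <- which(!out$failed)
  with_seed(seed, {
    chunk <- max(1L, floor(2e6 / boot_reps))
    for (start in chunk_starts(length(ok), chunk)) {
      idx <- ok[start:min(start + chunk - 1L, length(ok))]
      m <- length(idx)
      core <- generate_trials_core(
        design,
        rep(reps$pc_hat[idx], each = boot_reps),
        rep(reps$pt_hat[idx], each = boot_reps),
        m * boot_reps
      )
      ri <- rep(seq_len(m), each = boot_reps)
      pq <- boot_percentiles(core$theta_hat, ri, m, level)
      out$lower[idx] <- pq$lower
      out$upper[idx] <- pq$upper
      out$point[idx] <- pq$point
    }
  })
  out$failed[is.na(out$lower)] <- TRUE
  out
}

# conditional bootstrap: trials simulated at the observed stopping-stage
# rate estimates, retained only when they stop at the observed stage;
# the per-replicate estimate is the conditional MLE (or, for stage-1 stops
# under variant = "penalized", the penalized estimate at lambda*)
iv_conditional_bootstrap <- function(reps, design, level, boot_reps,
                                     seed = NULL, variant = "likelihood",
                                     retention_floor = 1e-4) {
  n <- nrow(reps)
  out <- iv_blank(n)
  out$failed <- !reps$valid |
    (reps$stage == 2L & reps$info2_obs <= reps$info1)
  ok <- which(!out$failed)
  lam1 <- if (variant == "penalized") lambda_star(design$e1) else 1
  with_seed(seed, {
    chunk <- max(1L, floor(2e6 / boot_reps))
    for (start in chunk_starts(length(ok), chunk)) {
      idx <- ok[start:min(start + chunk - 1L, length(ok))]
      m <- length(idx)
      core <- generate_trials_core(
        design,
        rep(reps$pc_hat[idx], each = boot_reps),
        rep(reps$pt_hat[idx], each = boot_reps),
        m * boot_reps
      )
      ri <- rep(seq_len(m), each = boot_reps)
      match_stage <- core$stage == rep(reps$stage[idx], each = boot_reps) &
        core$valid
      est <- rep(NA_real_, m * boot_reps)
      b1 <- which(match_stage & core$stage == 1L & core$z1 > design$e1)
      if (length(b1)) {
        est[b1] <- cmle_stage1(core$z1[b1], core$info1[b1], design$e1,
                               lambda = lam1)
      }
      b2 <- which(match_stage & core$stage == 2L &
                    core$info2_obs > core$info1)
      if (length(b2)) {
        fp <- cmle_stage2(core$theta_hat[b2], core$info1[b2],
                          core$info2_obs[b2], design$e1)
        est[b2] <- fp$est
      }
      pq <- boot_percentiles(est, ri, m, level,
                             floor_n = ceiling(retention_floor * boot_reps))
      out$lower[idx] <- pq$lower
      out$upper[idx] <- pq$upper
      out$point[idx] <- pq$point
    }
  })
  out$failed[is.na(out$lower)] <- TRUE
  out
}
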