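# Vectorized two-stage binomial trial generation.  The same core is used by
# the simulation engine and by the (conditional) bootstrap procedures.

# Essential per-replicate quantities as a plain list of vectors (kept lean
# because the bootstrap calls this with n up to several million).  p_control
# and p_treatment may be vectors (per-replicate rates).
generate_trials_core <- function(design, p_control, p_treatment, n) {
  n1c <- design$n1_control; n1t <- design$n1_treatment
  n2c <- design$n2_control; n2t <- design$n2_treatment
  s1c <- rbinom(n, n1c, p_control)
  s1t <- rbinom(n, n1t, p_treatment)
  pb1 <- (s1c + s1t) / (n1c + n1t)
  valid1 <- pb1 > 0 & pb1 < 1
  info1 <- ifelse(valid1, 1 / (pb1 * (1 - pb1) * (1 / n1c + 1 / n1t)),
                  NA_real_)
  z1 <- (s1t / n1t - s1c / n1c) * sqrt(info1)
  stop1 <- valid1 & z1 >= design$e1
  # stage-2 increments are drawn for every replicate (stopped ones simply
  # ignore them); this keeps the random stream a pure function of n
  s2c <- s1c + rbinom(n, n2c - n1c, p_control)
  s2t <- s1t + rbinom(n, n2t - n1t, p_treatment)
  pb2 <- (s2c + s2t) / (n2c + n2t)
  valid2 <- pb2 > 0 & pb2 < 1
  info2 <- ifelse(valid2, 1 / (pb2 * (1 - pb2) * (1 / n2c + 1 / n2t)),
                  NA_real_)
  z2 <- (s2t / n2t - s2c / n2c) * sqrt(info2)
  stage <- ifelse(stop1, 1L, 2L)
  theta_hat <- ifelse(stop1, s1t / n1t - s1c / n1c, s2t / n2t - s2c / n2c)
  list(s1c = s1c, s1t = s1t, s2c = s2c, s2t = s2t,
       stage = stage, theta_hat = theta_hat,
       z1 = z1, z2 = ifelse(stop1, NA_real_, z2),
       info1 = info1, info2_obs = ifelse(stop1, NA_real_, info2),
       valid = ifelse(stop1, valid1, valid1 & valid2),
       rejected = ifelse(stop1, TRUE, z2 >= design$e2))
}

#' Simulate two-stage group sequential trials
#'
#' Generates `n_reps` trials under the design: stage-1 successes are drawn
#' per arm from the true rates, the pooled-variance z statistic is compared
#' against the efficacy boundary, and continuing trials accrue independent
#' stage-2 increments.  Replicates whose pooled response rate is degenerate
#' (0 or 1) at an analysis it needs are flagged invalid and later counted as
#' failures rather than silently regenerated.
#'
#' @param design a [gs_design()].
#' @param p_control,p_treatment true response probabilities.
#' @param n_reps number of trial replicates.
#' @param seed optional integer seed (the replicate stream is a pure
#'   function of it).
#' @return A tibble with one row per replicate: cumulative counts, stopping
#'   stage, the MLE at the stopping stage, z statistics, information levels
#'   (`info2` is the stage-1 projection for early stops, `info2_obs` the
#'   observed final information), the unpooled standard error and rate
#'   estimates at the stopping stage, the test decision and a validity flag.
#' @export
simulate_gs_trials <- function(design, p_control, p_treatment, n_reps,
                               seed = NULL) {
  stopifnot(inherits(design, "gs_design"),
            p_control > 0, p_control < 1,
            all(p_treatment > 0), all(p_treatment < 1), n_reps >= 1)
  core <- with_seed(seed, generate_trials_core(design, p_control,
                                               p_treatment, n_reps))
  trials_frame(core, design)
}

# decorate the core list into the replicate frame used by the interval code
trials_frame <- function(core, design) {
  n1c <- design$n1_control; n1t <- design$n1_treatment
  n2c <- design$n2_control; n2t <- design$n2_treatment
  one <- core$stage == 1L
  sc <- ifelse(one, core$s1c, core$s2c)
  st <- ifelse(one, core$s1t, core$s2t)
  nc <- ifelse(one, n1c, n2c)
  nt <- ifelse(one, n1t, n2t)
  pc <- sc / nc
  pt <- st / nt
  tibble(
    rep = seq_along(core$stage),
    stage = core$stage,
    theta_hat = core$theta_hat,
    z1 = core$z1, z2 = core$z2,
    info1 = core$info1,
    info2_obs = core$info2_obs,
    info2 = ifelse(one, projected_info2(core$info1, design), core$info2_obs),
    se_w = sqrt(pt * (1 - pt) / nt + pc * (1 - pc) / nc),
    pc_hat = pc, pt_hat = pt,
    rejected = core$rejected,
    valid = core$valid,
    s2c = ifelse(one, NA_integer_, core$s2c),
    s2t = ifelse(one, NA_integer_, core$s2t)
  )
}
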