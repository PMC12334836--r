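# Stagewise-ordering p-value function and the conditional exceedance
# probability: the two monotone functions whose roots define the exact
# unconditional and exact conditional intervals and their median unbiased
# point estimators.

#' Stagewise-ordering p-value function
#'
#' One-sided probability, under effect `theta`, of a trial result as extreme
#' or more extreme (in the stagewise ordering) than the one observed.  For a
#' trial stopped at stage 1 with statistic `z1` this is
#' `Pr(Z1 >= z1)`; for a trial that continued and observed `z2` it is
#' `Pr(Z1 >= e1) + Pr(Z1 < e1, Z2 >= z2)` under the canonical bivariate
#' normal model.  The function is strictly increasing in `theta`; its 0.025,
#' 0.5 and 0.975 roots give the lower exact limit, the median unbiased
#' estimate (MUE) and the upper exact limit.
#'
#' @param theta effect size(s) at which to evaluate.
#' @param outcome a [run_stopping_rule()] result.
#' @return vector of probabilities, one per `theta`.
#' @export
stagewise_p_value <- function(theta, outcome) {
  stopifnot(inherits(outcome, "gs_outcome"))
  m <- outcome$model
  if (outcome$stop_stage == 1L) {
    pnorm(outcome$z1 - theta * sqrt(m$info1), lower.tail = FALSE)
  } else {
    if (m$degenerate) {
      stop("information decreased between the analyses; the bivariate ",
           "normal model is degenerate", call. = FALSE)
    }
    a <- m$e1 - theta * sqrt(m$info1)
    b <- outcome$z2 - theta * sqrt(m$info2)
    pnorm(a, lower.tail = FALSE) + pbvn_cont(a, b, m$rho)
  }
}

#' Conditional exceedance probability of the MLE
#'
#' `Pr(theta_hat >= theta_obs | T = t, theta)` under the canonical model,
#' conditioning on the observed stopping stage.  For a stage-1 stop the
#' conditional law of the MLE is the normal tail truncated to the rejection
#' region; for a continuing trial it is given by the bivariate normal
#' restricted to the continuation region.  Strictly increasing in `theta`;
#' its 0.5 root is the conditional median unbiased estimate (CMUE).
#'
#' @inheritParams stagewise_p_value
#' @export
conditional_exceedance <- function(theta, outcome) {
  stopifnot(inherits(outcome, "gs_outcome"))
  m <- outcome$model
  s1 <- sqrt(m$info1)
  if (outcome$stop_stage == 1L) {
    num <- pmax(outcome$z1, m$e1) - theta * s1
    den <- m$e1 - theta * s1
    exp(pnorm(num, lower.tail = FALSE, log.p = TRUE) -
          pnorm(den, lower.tail = FALSE, log.p = TRUE))
  } else {
    if (!is.finite(m$info2) || m$info2 <= m$info1) {
      stop("the conditional interval requires the information to increase ",
           "between the analyses (I2 > I1)", call. = FALSE)
    }
    pcond_exceed(m$e1 - theta * s1,
                 (outcome$theta_hat - theta) * sqrt(m$info2),
                 m$rho)
  }
}

#' Conditional maximum likelihood estimate
#'
#' Maximizer of the log-likelihood of the stopping-stage statistic
#' conditional on the stopping stage,
#' `Lc = -(z_t - theta*sqrt(I_t))^2/2 - log Pr(T = t | theta)`.
#' Setting the score to zero gives a fixed-point equation: for a continuing
#' trial `theta_c = theta_obs + (sqrt(I1)/I2) * phi(c)/Phi(c)` and for a
#' stage-1 stop `theta_c = theta_obs - phi(c)/(sqrt(I1) * (1 - Phi(c)))`,
#' with `c = e1 - theta_c*sqrt(I1)`.  The correction is positive after
#' continuation (the stopping rule selects small interim estimates into
#' stage 2) and negative after an early stop.
#'
#' @param outcome a [run_stopping_rule()] result.
#' @param tol convergence tolerance on theta.
#' @param max_iter iteration cap for the fixed point.
#' @return the conditional MLE (scalar).
#' @examples
#' musec <- musec_trial()
#' conditional_mle(run_stopping_rule(musec$counts, musec$design))  # 0.191
#' @export
conditional_mle <- function(outcome, tol = 1e-8, max_iter = 200L) {
  stopifnot(inherits(outcome, "gs_outcome"))
  m <- outcome$model
  if (outcome$stop_stage == 2L) {
    if (!is.finite(m$info2) || m$info2 <= m$info1) {
      stop("conditional MLE after continuation requires I2 > I1",
           call. = FALSE)
    }
    r <- cmle_stage2(outcome$theta_hat, m$info1, m$info2, m$e1,
                     tol = tol, max_iter = max_iter)
    if (!r$converged) stop("conditional MLE fixed point did not converge",
                           call. = FALSE)
    r$est
  } else {
    est <- cmle_stage1(outcome$z1, m$info1, m$e1, lambda = 1)
    if (!is.finite(est)) {
      stop("conditional MLE diverges: the stage-1 statistic is too close ",
           "to the efficacy boundary", call. = FALSE)
    }
    est
  }
}

# stage-2 conditional MLE by fixed-point iteration, vectorized; the map is a
# contraction with rate bounded by I1/I2 < 1.
cmle_stage2 <- function(theta_obs, info1, info2, e1,
                        tol = 1e-8, max_iter = 200L) {
  th <- theta_obs
  s1 <- sqrt(info1)
  delta <- rep(Inf, length(th))
  for (it in seq_len(max_iter)) {
    c1 <- e1 - th * s1
    hazard <- exp(dnorm(c1, log = TRUE) - pnorm(c1, log.p = TRUE))
    new <- theta_obs + s1 / info2 * hazard
    delta <- abs(new - th)
    th <- new
    if (all(!is.finite(delta) | delta < tol)) break
  }
  conv <- is.finite(th) & delta < tol
  list(est = ifelse(conv, th, NA_real_), converged = conv)
}

# stage-1 (penalized) conditional MLE, solved on the z scale where the score
# equation x = z - lambda * phi(e1 - x)/(1 - Phi(e1 - x)) does not involve
# the information; theta = x / sqrt(info1).  The score is strictly
# decreasing in x's residual, so bisection on the increasing function
# g(x) = x - z + lambda * h(e1 - x) is safe.
cmle_stage1 <- function(z1, info1, e1, lambda = 1) {
  g <- function(x, idx) {
    c1 <- e1 - x
    x - z1[idx] + lambda *
      exp(dnorm(c1, log = TRUE) - pnorm(c1, lower.tail = FALSE, log.p = TRUE))
  }
  n <- length(z1)
  r <- vroot_increasing(g, rep(0, n), lo = rep(-2, n), hi = z1,
                        max_double = 8L)
  r$root / sqrt(info1)
}

#' Penalized likelihood estimate
#'
#' Maximizer over `theta` of the penalized log-likelihood
#' `-(z - theta*sqrt(I_t))^2/2 - lambda * log Pr(T = t | theta)`.
#' `lambda = 0` returns the MLE `z/sqrt(I_t)` and `lambda = 1` the
#' conditional MLE.
#'
#' @param lambda penalty weight in `[0, 1]`.
#' @param z observed standardized statistic at stage `stage`.
#' @param stage stopping stage (1 or 2).
#' @param model a [canonical_model()].
#' @return the penalized estimate (vectorized over `z`).
#' @export
penalized_estimate <- function(lambda, z, stage, model) {
  stopifnot(lambda >= 0, lambda <= 1, stage %in% c(1, 2),
            inherits(model, "gs_model"))
  if (lambda == 0) {
    info_t <- if (stage == 1) model$info1 else model$info2
    return(z / sqrt(info_t))
  }
  if (stage == 1) {
    cmle_stage1(z, model$info1, model$e1, lambda = lambda)
  } else {
    if (!is.finite(model$info2) || model$info2 <= model$info1) {
      stop("penalized estimate after continuation requires I2 > I1",
           call. = FALSE)
    }
    th <- z / sqrt(model$info2)
    s1 <- sqrt(model$info1)
    for (it in 1:200) {
      c1 <- model$e1 - th * s1
      new <- z / sqrt(model$info2) + lambda * s1 / model$info2 *
        exp(dnorm(c1, log = TRUE) - pnorm(c1, log.p = TRUE))
      if (all(abs(new - th) < 1e-10)) { th <- new; break }
      th <- new
    }
    th
  }
}

#' Decision-consistent penalty weight
#'
#' The penalty weight `lambda*` for which the penalized estimate of a trial
#' stopping exactly on the stage-1 boundary is zero.  On the z scale the
#' stage-1 score equation does not involve the information, so the defining
#' condition `0 = e1 - lambda * phi(e1)/(1 - Phi(e1))` has the closed-form
#' solution `lambda* = e1 * (1 - Phi(e1)) / phi(e1)`, which lies in (0, 1)
#' for any boundary above roughly 0.84.  With this weight every bootstrap
#' replicate that stops at stage 1 (so with `z1 >= e1`) has a strictly
#' positive penalized estimate, making the resulting interval consistent
#' with the efficacy decision.
#'
#' @param e1 stage-1 efficacy boundary, or a [gs_design()] /
#'   [canonical_model()] carrying one.
#' @return the penalty weight `lambda*`.
#' @examples
#' lambda_star(2.797)
#' @export
lambda_star <- function(e1) {
  if (inherits(e1, "gs_design") || inherits(e1, "gs_model")) e1 <- e1$e1
  lam <- e1 * pnorm(e1, lower.tail = FALSE) / dnorm(e1)
  if (lam <= 0 || lam >= 1) {
    stop(sprintf(
      "no penalty weight in [0, 1] makes the boundary estimate zero (boundary %.3f gives lambda %.3f); penalized estimates at the endpoints are %.4f (lambda=0) and negative-divergent (lambda=1)",
      e1, lam, e1), call. = FALSE)
  }
  lam
}
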