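# Trial blueprint and O'Brien-Fleming boundary calibration.

#' Two-stage group sequential design
#'
#' The fixed blueprint of a two-arm, two-stage group sequential trial with a
#' binary endpoint: cumulative per-arm sample sizes at the interim and final
#' analyses, standardized one-sided efficacy boundaries, and the two-sided
#' error level of the confidence intervals reported at the end.  Stage 1 has
#' no binding futility rule by default (`futility1 = -Inf`): the trial can
#' stop early only to reject the null.
#'
#' @param n1_control,n1_treatment patients per arm at the interim analysis.
#' @param n2_control,n2_treatment cumulative patients per arm at the final
#'   analysis; must be at least the interim counts.
#' @param e1,e2 standardized efficacy boundaries (z scale).  For an
#'   O'Brien-Fleming design `e1 = e2 * sqrt(2)`; see [obf_boundaries()].
#' @param alpha two-sided error level of the confidence intervals
#'   (default 0.05, i.e. 95% intervals).
#' @param futility1 stage-1 futility bound (default `-Inf`, none).
#' @return An object of class `gs_design`.
#' @examples
#' gs_design(97, 101, 134, 143, e1 = 2.797, e2 = 1.977)
#' @export
gs_design <- function(n1_control, n1_treatment, n2_control, n2_treatment,
                      e1, e2, alpha = 0.05, futility1 = -Inf) {
  stopifnot(
    n1_control >= 1, n1_treatment >= 1,
    n2_control >= n1_control, n2_treatment >= n1_treatment,
    is.numeric(e1), is.numeric(e2), e1 >= e2,
    alpha > 0, alpha < 1
  )
  structure(
    list(n1_control = as.integer(n1_control),
         n1_treatment = as.integer(n1_treatment),
         n2_control = as.integer(n2_control),
         n2_treatment = as.integer(n2_treatment),
         e1 = e1, e2 = e2, alpha = alpha, futility1 = futility1),
    class = "gs_design"
  )
}

#' @export
print.gs_design <- function(x, ...) {
  cat("Two-stage group sequential design\n")
  cat(sprintf("  interim : %d control / %d treatment\n",
              x$n1_control, x$n1_treatment))
  cat(sprintf("  final   : %d control / %d treatment (cumulative)\n",
              x$n2_control, x$n2_treatment))
  cat(sprintf("  efficacy boundaries: e1 = %.3f, e2 = %.3f (one-sided)\n",
              x$e1, x$e2))
  cat(sprintf("  CI level: %.0f%%\n", 100 * (1 - x$alpha)))
  invisible(x)
}

#' Boundary-crossing probability of a group sequential test
#'
#' Probability that the standardized test statistic crosses the efficacy
#' boundary at any of `K` equally spaced analyses, for a given drift.  Under
#' the canonical joint distribution with equal information increments the
#' score process is a Gaussian random walk; the crossing probability is
#' computed by the classical continuation-density recursion: the sub-density
#' of the score among continuing paths is propagated numerically on a grid
#' from one analysis to the next, and the crossing mass at each analysis is
#' obtained by integrating the normal increment tail analytically against
#' that sub-density.
#'
#' @param boundaries numeric vector of standardized boundaries, one per
#'   analysis.
#' @param theta drift per unit information; `theta * sqrt(I_K)` is the mean
#'   of the final z statistic.  The default 0 gives the type I error.
#' @param info_total total information at the last analysis (only needed for
#'   `theta != 0`).
#' @param grid_step grid resolution on the score scale.
#' @return the probability of rejecting at any analysis.
#' @export
gs_crossing_probability <- function(boundaries, theta = 0, info_total = 1,
                                    grid_step = 0.01) {
  K <- length(boundaries)
  d_info <- info_total / K
  mu <- theta * sqrt(d_info)          # increment mean, score scale / sqrt(d)
  # work with the standardized partial sums S_k / sqrt(d_info): increments
  # are N(mu, 1), the boundary at analysis k is boundaries[k] * sqrt(k)
  thr <- boundaries * sqrt(seq_len(K))
  p_cross <- pnorm(thr[1] - mu, lower.tail = FALSE)
  if (K == 1) return(p_cross)
  x <- seq(mu - 8.5, thr[1], by = grid_step)
  f <- dnorm(x, mean = mu)            # continuation sub-density after look 1
  for (k in 2:K) {
    # crossing mass at look k: normal increment tail integrated analytically
    p_cross <- p_cross +
      sum(f * pnorm(thr[k] - x - mu, lower.tail = FALSE)) * grid_step
    if (k < K) {
      xk <- seq(min(x) + mu - 8.5, thr[k], by = grid_step)
      f <- colSums(f * outer(x, xk, function(u, s) dnorm(s - u - mu))) *
        grid_step
      x <- xk
    }
  }
  p_cross
}

#' One-sided O'Brien-Fleming efficacy boundaries
#'
#' Boundaries of the form `C * sqrt(K/k)` for analyses `k = 1, ..., K` with
#' equal information increments, where the constant `C` is calibrated so that
#' the overall probability of crossing at any analysis under the null equals
#' `alpha_one_sided`.  Calibration solves the crossing-probability equation
#' by bracketed root finding to an absolute tolerance of 1e-8 on the error
#' probability scale.
#'
#' @param k number of analyses.
#' @param alpha_one_sided one-sided type I error level.
#' @return numeric vector of `k` boundaries (decreasing).
#' @examples
#' round(obf_boundaries(2, 0.025), 3)  # 2.797 1.977
#' @export
obf_boundaries <- function(k, alpha_one_sided = 0.025) {
  stopifnot(k >= 1, alpha_one_sided > 0, alpha_one_sided < 1)
  if (k == 1) return(qnorm(1 - alpha_one_sided))
  shape <- sqrt(k / seq_len(k))
  err <- function(C) {
    if (k == 2) {
      # closed evaluation through the bivariate normal (exact to quadrature)
      pnorm(C * sqrt(2), lower.tail = FALSE) +
        pbvn_cont(C * sqrt(2), C, sqrt(1 / 2)) - alpha_one_sided
    } else {
      gs_crossing_probability(C * shape, grid_step = 0.005) - alpha_one_sided
    }
  }
  C <- uniroot(err, c(qnorm(1 - alpha_one_sided), 4), tol = 1e-8)$root
  C * shape
}

#' Stopping-stage probabilities under the canonical normal model
#'
#' `Pr(T = 1 | theta) = 1 - Phi(e1 - theta * sqrt(I1))` for a design with no
#' stage-1 futility bound, and `Pr(T = 2 | theta)` its complement.
#'
#' @param theta effect size (difference in response probabilities).
#' @param model a [canonical_model()].
#' @param stage which stopping stage to report the probability for.
#' @return vector of probabilities, one per `theta`.
#' @export
stop_probability <- function(theta, model, stage = 1) {
  stopifnot(inherits(model, "gs_model"), stage %in% c(1, 2))
  p1 <- pnorm(model$e1 - theta * sqrt(model$info1), lower.tail = FALSE)
  if (stage == 1) p1 else 1 - p1
}

#' Exact stage-1 stopping probability for binomial data
#'
#' Enumerates every pair of stage-1 success counts, applies the pooled-variance
#' z statistic and the efficacy boundary, and sums the binomial probabilities
#' of the rejecting pairs.  Outcome pairs with a degenerate pooled rate (all
#' successes or all failures) cannot cross the boundary and are counted as
#' continuing.
#'
#' @param design a [gs_design()].
#' @param p_control,p_treatment true response probabilities.
#' @return exact probability that the trial stops at stage 1.
#' @export
stop_probability_exact <- function(design, p_control, p_treatment) {
  stopifnot(inherits(design, "gs_design"))
  nc <- design$n1_control; nt <- design$n1_treatment
  sc <- 0:nc; st <- 0:nt
  pr <- outer(dbinom(sc, nc, p_control), dbinom(st, nt, p_treatment))
  z <- outer(sc, st, function(a, b) {
    pb <- (a + b) / (nc + nt)
    ifelse(pb <= 0 | pb >= 1, -Inf,
           (b / nt - a / nc) / sqrt(pb * (1 - pb) * (1 / nc + 1 / nt)))
  })
  sum(pr[z >= design$e1])
}
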