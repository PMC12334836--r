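# Shared fixtures: the embedded case-study trial plus a synthetic trial that
# stops at stage 1, built from counts chosen so the interim statistic clears
# the boundary comfortably.

musec <- musec_trial()
musec_outcome <- run_stopping_rule(musec$counts, musec$design)

# stage-1 stop: 12/97 control vs 40/101 treatment gives z1 well above 2.797
stage1_counts <- tibble::tibble(
  stage = c(1L, 1L),
  arm = c("control", "treatment"),
  successes = c(12L, 40L),
  total = c(97L, 101L)
)
stage1_outcome <- run_stopping_rule(stage1_counts, musec$design)

# counts landing just above the boundary at stage 1 (z1 = 2.7994, a gap of
# 0.0024 over the 2.797 boundary): boundary-stopping data exhibiting the
# near-degenerate conditional pathologies
near_boundary_counts <- function() {
  tibble::tibble(
    stage = c(1L, 1L), arm = c("control", "treatment"),
    successes = c(30L, 51L), total = c(97L, 101L)
  )
}

counts_to_list <- function(counts) {
  ctl <- counts[counts$arm == "control", ]
  trt <- counts[counts$arm == "treatment", ]
  list(s_control = ctl$successes, n_control = ctl$total,
       s_treatment = trt$successes, n_treatment = trt$total)
}

# independent oracle for Pr(Z1 < a, Z2 >= b): adaptive quadrature through
# stats::integrate, never the package's Gauss-Legendre path
pbvn_oracle <- function(a, b, rho) {
  stats::integrate(function(u) {
    dnorm(u) * pnorm((b - rho * u) / sqrt(1 - rho^2), lower.tail = FALSE)
  }, -38, a, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# absolute-tolerance comparison (expect_equal's tolerance is relative)
expect_close <- function(object, expected, tol) {
  testthat::expect_lt(max(abs(object - expected)), tol)
}

# conditional exceedance for generated (not observed) trials
conditional_exceedance_oracle <- function(theta_hat_obs, stage, m, theta) {
  if (stage == 1) {
    num <- pmax(theta_hat_obs * sqrt(m$info1), m$e1) - theta * sqrt(m$info1)
    den <- m$e1 - theta * sqrt(m$info1)
    exp(pnorm(num, lower.tail = FALSE, log.p = TRUE) -
          pnorm(den, lower.tail = FALSE, log.p = TRUE))
  } else {
    pcond_exceed(m$e1 - theta * sqrt(m$info1),
                 (theta_hat_obs - theta) * sqrt(m$info2), m$rho)
  }
}
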