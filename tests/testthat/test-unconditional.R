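# Stagewise-ordering p-value function and the unconditional intervals.

test_that("bivariate normal quadrature matches adaptive integration", {
  cases <- expand.grid(a = c(-3, -0.5, 0.37, 2.797, 6),
                       b = c(-2, 0.01, 2.718),
                       rho = c(0.3, sqrt(1 / 2), 0.95))
  got <- pbvn_cont(cases$a, cases$b, cases$rho)
  want <- mapply(pbvn_oracle, cases$a, cases$b, cases$rho)
  expect_equal(got, unname(want), tolerance = 1e-10)
})

test_that("the p-value function is monotone with ordered roots", {
  # grid kept inside the region where the tails have not saturated in
  # double precision
  grid <- seq(-0.1, 0.35, by = 0.025)
  p <- stagewise_p_value(grid, musec_outcome)
  expect_true(all(diff(p) > 0))
  expect_lt(stagewise_p_value(-5, musec_outcome), 1e-10)
  expect_gt(stagewise_p_value(5, musec_outcome), 1 - 1e-10)
  tab <- gs_ci(musec_outcome, methods = "final_unconditional")
  expect_lt(tab$lower, tab$point_estimate)
  expect_lt(tab$point_estimate, tab$upper)
  # the MUE is the 0.5 root by definition
  expect_equal(stagewise_p_value(tab$point_estimate, musec_outcome), 0.5,
               tolerance = 1e-8)
})

test_that("worked-example unconditional intervals match the trial report", {
  tab <- gs_ci(musec_outcome,
               methods = c("wald", "final_unconditional", "repeated"))
  wald <- tab[tab$method == "wald", ]
  expect_equal(round(c(wald$lower, wald$upper), 3), c(0.040, 0.234))
  expect_equal(round(wald$width, 3), 0.194)
  fin <- tab[tab$method == "final_unconditional", ]
  expect_equal(round(fin$point_estimate, 3), 0.134)
  expect_equal(round(c(fin$lower, fin$upper), 3), c(0.034, 0.234))
  rci <- tab[tab$method == "repeated", ]
  expect_equal(round(c(rci$lower, rci$upper), 3), c(0.037, 0.237))
  expect_true(is.na(rci$point_estimate))
  # repeated interval is symmetric about the MLE and, because the null was
  # rejected, lies above zero
  expect_equal(rci$lower + rci$upper, 2 * musec_outcome$theta_hat)
  expect_gte(rci$lower, 0)
})

test_that("stage-1 closed form equals numeric inversion of the p-value", {
  tab <- gs_ci(stage1_outcome, methods = "final_unconditional")
  lo_num <- root1(function(th) stagewise_p_value(th, stage1_outcome), 0.025)
  up_num <- root1(function(th) stagewise_p_value(th, stage1_outcome), 0.975)
  expect_equal(tab$lower, lo_num, tolerance = 1e-6)
  expect_equal(tab$upper, up_num, tolerance = 1e-6)
  m <- stage1_outcome$model
  expect_equal(tab$lower,
               (qnorm(0.025) + stage1_outcome$z1) / sqrt(m$info1))
})

test_that("adjusted asymptotic moments match a numerical-integration oracle", {
  m <- musec_outcome$model
  th <- musec_outcome$theta_hat
  # oracle: integrate the stopped-MLE moments over the stage-1 statistic
  mean_oracle <- function(theta) {
    c1 <- m$e1 - theta * sqrt(m$info1)
    stopped <- integrate(function(u) (theta + u / sqrt(m$info1)) * dnorm(u),
                         c1, 20, rel.tol = 1e-12)$value
    rho <- sqrt(m$info1 / m$info2)
    continued <- integrate(function(u) {
      (theta + rho * u / sqrt(m$info2)) * dnorm(u)
    }, -20, c1, rel.tol = 1e-12)$value
    stopped + continued
  }
  mom <- stopped_mle_moments(th, m$info1, m$info2, m$e1)
  expect_equal(th + mom$mean_bias, mean_oracle(th), tolerance = 1e-8)
  # early stopping inflates the unconditional mean: positive bias at the null
  expect_gt(stopped_mle_moments(0, m$info1, m$info2, m$e1)$mean_bias, 0)
  # with an unreachable stage-1 boundary the adjustment vanishes
  far <- stopped_mle_moments(th, m$info1, m$info2, e1 = 40)
  expect_equal(far$mean_bias, 0, tolerance = 1e-12)
  expect_equal(far$var, 1 / m$info2, tolerance = 1e-12)
  tab <- gs_ci(musec_outcome, methods = "adjusted_asymptotic")
  expect_equal(tab$point_estimate, th - mom$mean_bias)
  expect_equal(tab$width, 2 * qnorm(0.975) * sqrt(mom$var))
})

test_that("parametric bootstrap reproduces its sampling distribution", {
  tab <- gs_ci(musec_outcome, methods = "parametric_bootstrap",
               boot_reps = 4e4, seed = 9)
  expect_close(tab$point_estimate, 0.143, 2e-3)
  expect_close(tab$lower, 0.041, 5e-3)
  expect_close(tab$upper, 0.253, 5e-3)
  # determinism: same seed, identical result
  tab2 <- gs_ci(musec_outcome, methods = "parametric_bootstrap",
                boot_reps = 4e4, seed = 9)
  expect_identical(tab, tab2)
  # with an unreachable boundary the bootstrap targets the fixed-design
  # sampling distribution: percentiles near the normal-approximation limits
  design_ns <- gs_design(97, 101, 134, 143, e1 = 20, e2 = 1.977)
  out_ns <- run_stopping_rule(musec$counts, design_ns)
  tab_ns <- gs_ci(out_ns, methods = "parametric_bootstrap",
                  boot_reps = 1e5, seed = 10)
  se <- unpooled_se(21, 134, 42, 143)
  expect_close(tab_ns$lower, out_ns$theta_hat - qnorm(0.975) * se, 4e-3)
  expect_close(tab_ns$upper, out_ns$theta_hat + qnorm(0.975) * se, 4e-3)
})
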