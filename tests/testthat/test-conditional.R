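# Inference conditional on the stopping stage.

test_that("conditional exceedance is monotone and reproduces the CMUE", {
  grid <- seq(-0.2, 0.7, by = 0.02)
  p <- conditional_exceedance(grid, musec_outcome)
  expect_true(all(diff(p) > 0))
  tab <- gs_ci(musec_outcome, methods = "final_conditional")
  expect_equal(round(tab$point_estimate, 3), 0.185)
  expect_equal(conditional_exceedance(tab$point_estimate, musec_outcome),
               0.5, tolerance = 1e-7)
  expect_equal(round(c(tab$lower, tab$upper), 3), c(0.052, 0.358))
  # an observation exactly on the stage-1 boundary has the whole conditional
  # support above it
  bnd <- stage1_outcome
  bnd$z1 <- bnd$design$e1
  bnd$theta_hat <- bnd$z1 / sqrt(bnd$model$info1)
  expect_equal(conditional_exceedance(c(-0.5, 0, 0.5), bnd), rep(1, 3))
})

test_that("restricted interval is the conditional interval capped", {
  tabs <- gs_ci(musec_outcome,
                methods = c("final_conditional",
                            "restricted_final_conditional"))
  cond <- tabs[tabs$method == "final_conditional", ]
  restr <- tabs[tabs$method == "restricted_final_conditional", ]
  m <- musec_outcome$model
  cap <- (m$e1 - qnorm(0.025)) / sqrt(m$info1)
  expect_equal(round(cap, 3), 0.269)
  expect_equal(restr$lower, cond$lower)
  expect_equal(restr$upper, min(cond$upper, cap))
  expect_equal(round(restr$width, 3), 0.217)
  expect_equal(restr$point_estimate, cond$point_estimate)
})

test_that("restricted interval is a subset of the conditional interval", {
  reps <- simulate_gs_trials(musec$design, 21 / 134, 42 / 143, 2000, seed = 31)
  iv <- interval_table(reps, musec$design,
                       c("final_conditional", "restricted_final_conditional"),
                       level = 0.95, boot_reps = 0)
  wide <- tidyr::pivot_wider(iv, id_cols = "rep", names_from = "method",
                             values_from = c("lower", "upper", "empty"))
  ok <- !is.na(wide$lower_final_conditional) &
    !is.na(wide$lower_restricted_final_conditional)
  expect_true(all(
    wide$lower_restricted_final_conditional[ok] >=
      wide$lower_final_conditional[ok] - 1e-9))
  expect_true(all(
    wide$upper_restricted_final_conditional[ok] <=
      wide$upper_final_conditional[ok] + 1e-9))
})

test_that("conditional MLE solves the score equation and corrects upward", {
  est <- conditional_mle(musec_outcome)
  expect_equal(round(est, 3), 0.191)
  m <- musec_outcome$model
  # fixed point verified directly
  c1 <- m$e1 - est * sqrt(m$info1)
  expect_equal(est,
               musec_outcome$theta_hat +
                 sqrt(m$info1) / m$info2 * dnorm(c1) / pnorm(c1),
               tolerance = 1e-7)
  # grid-maximization oracle of the conditional log-likelihood
  lc <- function(th) {
    -0.5 * (musec_outcome$z2 - th * sqrt(m$info2))^2 -
      log(pnorm(m$e1 - th * sqrt(m$info1)))
  }
  grid <- seq(0.10, 0.30, by = 1e-4)
  expect_close(grid[which.max(lc(grid))], est, 2e-4)
  # conditioning on continuation corrects the MLE upward
  expect_gt(est, musec_outcome$theta_hat)
  # no interim look, no correction
  wide_open <- musec_outcome
  wide_open$model <- canonical_model(m$info1, m$info2, e1 = 30, e2 = 1.977)
  expect_equal(conditional_mle(wide_open), musec_outcome$theta_hat,
               tolerance = 1e-8)
})

test_that("penalized estimation interpolates between MLE and conditional MLE", {
  m <- musec_outcome$model
  z2 <- musec_outcome$z2
  expect_equal(penalized_estimate(0, z2, 2, m), z2 / sqrt(m$info2))
  expect_equal(penalized_estimate(1, z2, 2, m), conditional_mle(musec_outcome),
               tolerance = 1e-7)
  m1 <- stage1_outcome$model
  z1 <- stage1_outcome$z1
  expect_equal(penalized_estimate(0, z1, 1, m1), z1 / sqrt(m1$info1))
  expect_equal(penalized_estimate(1, z1, 1, m1), conditional_mle(stage1_outcome),
               tolerance = 1e-7)
  # grid oracle: the stage-1 penalized estimate moves monotonically with
  # lambda between the two endpoints
  lams <- seq(0, 1, by = 0.1)
  ests <- vapply(lams, function(l) penalized_estimate(l, z1, 1, m1),
                 numeric(1))
  expect_true(all(diff(ests) < 0))
  obj <- function(th, l) {
    -0.5 * (z1 - th * sqrt(m1$info1))^2 -
      l * log(pnorm(m1$e1 - th * sqrt(m1$info1), lower.tail = FALSE))
  }
  grid <- seq(0, 0.5, by = 1e-4)
  expect_close(grid[which.max(obj(grid, 0.5))], ests[6], 2e-4)
})

test_that("lambda* zeroes the boundary estimate and lies inside (0, 1)", {
  lam <- lambda_star(musec$design)
  expect_gt(lam, 0); expect_lt(lam, 1)
  m1 <- stage1_outcome$model
  expect_equal(penalized_estimate(lam, musec$design$e1, 1, m1), 0,
               tolerance = 1e-8)
  # grid oracle on the defining root: sign change of the boundary estimate
  est_at <- function(l) penalized_estimate(l, musec$design$e1, 1, m1)
  expect_gt(est_at(lam - 0.05), 0)
  expect_lt(est_at(lam + 0.05), 0)
  # a non-positive boundary has no decision-consistent weight in [0, 1]
  expect_error(lambda_star(-1), "no penalty weight")
})

test_that("conditional bootstrap reproduces the reported interval", {
  tabs <- gs_ci(musec_outcome,
                methods = c("conditional_likelihood", "penalized_likelihood"),
                boot_reps = 4e4, seed = 12)
  lik <- tabs[tabs$method == "conditional_likelihood", ]
  pen <- tabs[tabs$method == "penalized_likelihood", ]
  expect_equal(round(lik$point_estimate, 3), 0.191)
  expect_close(lik$lower, 0.034, 8e-3)
  expect_close(lik$upper, 0.304, 6e-3)
  # after continuation the penalized interval IS the conditional interval
  expect_identical(lik[-1], pen[-1])
  # determinism
  again <- gs_ci(musec_outcome, methods = "conditional_likelihood",
                 boot_reps = 4e4, seed = 12)
  expect_identical(lik, again)
})

test_that("penalized intervals after an early stop exclude zero", {
  tab <- gs_ci(stage1_outcome, methods = "penalized_likelihood",
               boot_reps = 5e3, seed = 13)
  expect_gt(tab$lower, 0)
  # and the same holds replicate-wise in simulation at a strong effect
  reps <- simulate_gs_trials(musec$design, 21 / 134, 0.40, 500, seed = 14)
  reps1 <- reps[reps$stage == 1L, ]
  iv <- iv_conditional_bootstrap(reps1, musec$design, 0.95, 500,
                                 seed = 15, variant = "penalized")
  expect_true(all(iv$lower[!iv$failed] > 0))
})

test_that("degenerate conditioning is reported, not silently computed", {
  # shrinking information between analyses: conditional machinery refuses
  degen <- musec_outcome
  degen$model <- canonical_model(400, 380, 2.797, 1.977)
  expect_error(conditional_exceedance(0.1, degen), "I2 > I1")
  expect_error(conditional_mle(degen), "I2 > I1")
  # retention floor: impossible conditioning fails loudly per replicate
  reps <- outcome_frame(stage1_outcome)
  iv <- iv_conditional_bootstrap(reps, musec$design, 0.95, 200,
                                 seed = 16, variant = "likelihood",
                                 retention_floor = 0.999)
  expect_true(iv$failed)
})

test_that("near-boundary stage-1 stops give pathological conditional limits", {
  nb <- run_stopping_rule(near_boundary_counts(), musec$design)
  expect_lt(nb$z1 - musec$design$e1, 0.25)
  tabs <- gs_ci(nb, methods = c("final_conditional",
                                "restricted_final_conditional"))
  cond <- tabs[tabs$method == "final_conditional", ]
  restr <- tabs[tabs$method == "restricted_final_conditional", ]
  # the conditional lower bound dives far below the parameter space
  expect_lt(cond$lower, -1)
  # the restricted interval collapses to (almost) nothing or is empty
  expect_true(grepl("empty_set", restr$flags) || restr$width < cond$width / 2)
  # truncation clamps and flags
  tr <- gs_ci(nb, methods = "final_conditional", truncate = TRUE)
  expect_gte(tr$lower, -1)
  expect_true(grepl("truncated_lower", tr$flags))
})
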