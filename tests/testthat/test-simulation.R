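# Simulation engine: generation, metrics accounting, oracles, sweeps.

test_that("simulation runs are pure functions of scenario and seed", {
  sc <- gs_scenario(musec$design, 21 / 134, 42 / 143, n_reps = 500,
                    boot_reps = 200,
                    methods = c("wald", "repeated", "parametric_bootstrap"),
                    seed = 77)
  m1 <- evaluate_metrics(gs_simulate(sc))
  m2 <- evaluate_metrics(gs_simulate(sc))
  expect_identical(m1, m2)
})

test_that("metric accounting identities hold exactly in every stratum", {
  sc <- gs_scenario(musec$design, 21 / 134, 42 / 143, n_reps = 4000,
                    methods = c("wald", "final_unconditional", "repeated",
                                "final_conditional",
                                "restricted_final_conditional"),
                    seed = 78)
  sim <- gs_simulate(sc)
  m <- evaluate_metrics(sim)
  # covered + lower_miss + upper_miss + (empty + failed)/n = 1 exactly
  total <- m$coverage + m$lower_miss + m$upper_miss +
    (m$n_empty + m$n_failed) / m$n
  expect_equal(total, rep(1, nrow(m)))
  # overall coverage is the stopping-probability-weighted stratum average
  wide <- tidyr::pivot_wider(m, id_cols = "method",
                             names_from = "conditioning",
                             values_from = c("coverage", "n"))
  expect_equal(
    wide$coverage_overall,
    (wide$coverage_stage1 * wide$n_stage1 +
       wide$coverage_stage2 * wide$n_stage2) / wide$n_overall)
})

test_that("a fixed full-space interval covers always", {
  sc <- gs_scenario(musec$design, 21 / 134, 42 / 143, n_reps = 200,
                    methods = "wald", seed = 79)
  sim <- gs_simulate(sc)
  sim$intervals$lower <- -1
  sim$intervals$upper <- 1
  m <- dplyr::filter(evaluate_metrics(sim), .data$conditioning == "overall")
  expect_equal(m$coverage, 1)
  expect_equal(m$lower_miss, 0)
  expect_equal(m$upper_miss, 0)
})

test_that("canonical-normal oracle: exact intervals attain their level", {
  # trials generated straight from the canonical joint normal, bypassing the
  # binomial layer, at the observed information levels
  m <- musec_outcome$model
  theta <- 0.137
  set.seed(80)
  n <- 1e5
  z1 <- rnorm(n, theta * sqrt(m$info1))
  z2 <- m$rho * z1 + sqrt(1 - m$rho^2) * rnorm(n) +
    (theta * sqrt(m$info2) - m$rho * theta * sqrt(m$info1))
  stop1 <- z1 >= m$e1
  # membership via the monotone p-value function: theta is inside the exact
  # interval iff alpha/2 < P(theta) < 1 - alpha/2
  p1 <- pnorm(z1 - theta * sqrt(m$info1), lower.tail = FALSE)
  a <- m$e1 - theta * sqrt(m$info1)
  p2 <- pnorm(a, lower.tail = FALSE) +
    pbvn_cont(rep(a, sum(!stop1)), z2[!stop1] - theta * sqrt(m$info2), m$rho)
  pval <- ifelse(stop1, p1, NA)
  pval[!stop1] <- p2
  cover <- pval > 0.025 & pval < 0.975
  mcse <- sqrt(0.95 * 0.05 / n)
  expect_lt(abs(mean(cover) - 0.95), 3 * mcse)
  # repeated intervals: conservative overall
  th_hat <- ifelse(stop1, z1 / sqrt(m$info1), z2 / sqrt(m$info2))
  half <- ifelse(stop1, m$e1 / sqrt(m$info1), m$e2 / sqrt(m$info2))
  cover_rci <- abs(th_hat - theta) < half
  expect_gt(mean(cover_rci), 0.95 - 3 * mcse)
  # conditional-exceedance membership: near-nominal coverage in both strata
  c1 <- conditional_exceedance_oracle(z1[stop1] / sqrt(m$info1), 1, m, theta)
  c2 <- conditional_exceedance_oracle(z2[!stop1] / sqrt(m$info2), 2, m, theta)
  cov1 <- mean(c1 > 0.025 & c1 < 0.975)
  cov2 <- mean(c2 > 0.025 & c2 < 0.975)
  expect_gt(cov1, 0.95 - 3 * sqrt(0.05 * 0.95 / sum(stop1)))
  expect_gt(cov2, 0.95 - 3 * sqrt(0.05 * 0.95 / sum(!stop1)))
})

test_that("repeated interval never contradicts the efficacy decision", {
  sc <- gs_scenario(musec$design, 21 / 134, 42 / 143, n_reps = 2e4,
                    methods = "repeated", seed = 81)
  sim <- gs_simulate(sc)
  d <- dplyr::left_join(sim$intervals,
                        dplyr::select(sim$replicates, "rep", "rejected"),
                        by = "rep")
  d <- d[!d$failed, ]
  # the defining guarantee: rejection iff the interval lies above the null
  expect_identical(d$rejected, d$lower >= 0)
})

test_that("sweeps vary the stopping probability monotonically", {
  sc <- gs_scenario(musec$design, 21 / 134, 42 / 143, n_reps = 3000,
                    methods = "wald", seed = 82)
  grid <- c(0.24, 0.30, 0.36, 0.42)
  sw <- gs_sweep(sc, grid)
  p1 <- dplyr::distinct(sw, .data$p_treatment, .data$prob_stop1)$prob_stop1
  expect_true(all(diff(p1) > 0))
  # grid endpoints span the published early-stopping range 0.05 to 0.94
  expect_equal(stop_probability_exact(musec$design, 21 / 134, 0.224), 0.05,
               tolerance = 0.1)
  expect_equal(stop_probability_exact(musec$design, 21 / 134, 0.434), 0.94,
               tolerance = 0.01)
  # qualitative pattern: the standard interval undercovers badly among
  # early-stopping replicates when early stopping is rare
  low <- gs_simulate(gs_scenario(musec$design, 21 / 134, 0.25,
                                 n_reps = 2e4, methods = "wald", seed = 83))
  mlow <- dplyr::filter(evaluate_metrics(low),
                        .data$conditioning == "stage1")
  expect_lt(mlow$coverage, 0.90)
})
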