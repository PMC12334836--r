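# Monte-Carlo evaluation of the interval procedures: trial generation,
# per-replicate intervals, and coverage / width / consistency metrics
# overall and conditional on the stopping stage.

#' Simulation scenario
#'
#' Bundles everything one simulation run needs: the design, the true
#' response rates, the replicate and bootstrap sizes, the methods to
#' evaluate and the seed.  Method comparisons are paired: every method sees
#' the same generated trials.
#'
#' @param design a [gs_design()].
#' @param p_control,p_treatment true response probabilities.
#' @param n_reps number of trial replicates.
#' @param boot_reps bootstrap replicates per trial for the bootstrap-backed
#'   methods (these dominate the run time; reduce `n_reps` via
#'   `methods` subsets when exploring).
#' @param methods subset of [ci_methods()] (the randomization interval is
#'   not available in simulation runs).
#' @param seed integer master seed.
#' @param truncate constrain interval limits to `[-1, 1]`.
#' @param level confidence level (defaults to `1 - alpha` of the design).
#' @return An object of class `gs_scenario`.
#' @export
gs_scenario <- function(design, p_control, p_treatment, n_reps = 10000,
                        boot_reps = 1000, methods = NULL, seed = 1,
                        truncate = FALSE, level = NULL) {
  stopifnot(inherits(design, "gs_design"))
  if (is.null(methods)) {
    methods <- setdiff(default_methods(),
                       c("parametric_bootstrap", "conditional_likelihood",
                         "penalized_likelihood"))
  }
  if ("randomization" %in% methods) {
    stop("the randomization interval is not available in simulation runs",
         call. = FALSE)
  }
  methods <- match.arg(methods, default_methods(), several.ok = TRUE)
  if (is.null(level)) level <- 1 - design$alpha
  structure(
    list(design = design, p_control = p_control, p_treatment = p_treatment,
         n_reps = as.integer(n_reps), boot_reps = as.integer(boot_reps),
         methods = methods, seed = as.integer(seed), truncate = truncate,
         level = level),
    class = "gs_scenario"
  )
}

#' Run a simulation scenario
#'
#' Generates the trial replicates and computes every requested interval for
#' each of them.
#'
#' @param scenario a [gs_scenario()].
#' @return An object of class `gs_sim`: a list with the scenario, the
#'   replicate frame (`$replicates`) and the long interval table
#'   (`$intervals`).
#' @export
gs_simulate <- function(scenario) {
  stopifnot(inherits(scenario, "gs_scenario"))
  reps <- simulate_gs_trials(scenario$design, scenario$p_control,
                             scenario$p_treatment, scenario$n_reps,
                             seed = scenario$seed)
  intervals <- interval_table(reps, scenario$design, scenario$methods,
                              scenario$level, scenario$boot_reps,
                              seed = seed_child(scenario$seed, 17L),
                              truncate = scenario$truncate)
  structure(list(scenario = scenario, replicates = reps,
                 intervals = intervals),
            class = "gs_sim")
}

#' @export
print.gs_sim <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("Group sequential CI simulation: %d replicates at p = (%.3f, %.3f)\n",
              sc$n_reps, sc$p_control, sc$p_treatment))
  cat(sprintf("  stopped at stage 1: %.3f of replicates\n",
              mean(x$replicates$stage == 1L)))
  cat("  methods:", paste(sc$methods, collapse = ", "), "\n")
  invisible(x)
}

#' Coverage, width and consistency metrics
#'
#' Summarizes a simulation run per method, overall and conditional on the
#' stopping stage.  Coverage is the fraction of replicates whose interval
#' contains the true effect; empty intervals count as non-covering and
#' failed (numerically degenerate) replicates are their own accounting
#' category, so that
#' `coverage + lower_miss + upper_miss + (n_empty + n_failed)/n = 1`
#' holds exactly in every stratum.  Width moments are taken over non-empty,
#' non-failed intervals.  Consistency is agreement with the test decision:
#' a rejecting replicate's interval must lie above zero and a non-rejecting
#' one must contain it; empty intervals are inconsistent, failed ones are
#' excluded from the denominator.
#'
#' @param sim a [gs_simulate()] result.
#' @param truth true effect; defaults to the scenario's
#'   `p_treatment - p_control`.
#' @return A tibble with one row per (method, conditioning) with columns
#'   `coverage`, `mcse_coverage`, `mean_width`, `sd_width`, `consistency`,
#'   `lower_miss`, `upper_miss`, `n`, `n_empty`, `n_failed`.
#' @export
evaluate_metrics <- function(sim, truth = NULL) {
  stopifnot(inherits(sim, "gs_sim"))
  if (is.null(truth)) {
    truth <- sim$scenario$p_treatment - sim$scenario$p_control
  }
  reps <- dplyr::select(sim$replicates, "rep", "stage", "rejected")
  long <- dplyr::left_join(sim$intervals, reps, by = "rep")
  strata <- list(overall = rep(TRUE, nrow(long)),
                 stage1 = long$stage == 1L,
                 stage2 = long$stage == 2L)
  out <- purrr::imap_dfr(strata, function(sel, label) {
    sub <- long[sel, ]
    if (nrow(sub) == 0) {
      warning("no replicates in stratum ", label, "; row withheld",
              call. = FALSE)
      return(NULL)
    }
    dplyr::group_by(sub, .data$method) |>
      dplyr::group_modify(~ metric_row(.x, truth)) |>
      dplyr::ungroup() |>
      dplyr::mutate(conditioning = label, .after = "method")
  })
  out
}

metric_row <- function(d, truth) {
  n <- nrow(d)
  failed <- d$failed
  empty <- d$empty & !failed
  live <- !failed & !empty
  cov <- live & d$lower < truth & d$upper > truth
  lmiss <- live & d$lower >= truth
  umiss <- live & d$upper <= truth & !lmiss
  w <- (d$upper - d$lower)[live]
  consistent <- !empty &
    ifelse(d$rejected, d$lower >= 0, d$lower <= 0 & d$upper >= 0)
  p <- mean(cov)
  tibble(
    coverage = p,
    mcse_coverage = sqrt(p * (1 - p) / n),
    mean_width = if (length(w)) mean(w) else NA_real_,
    sd_width = if (length(w) > 1) sd(w) else NA_real_,
    consistency = if (sum(!failed)) mean(consistent[!failed]) else NA_real_,
    lower_miss = mean(lmiss),
    upper_miss = mean(umiss),
    n = n,
    n_empty = sum(empty),
    n_failed = sum(failed)
  )
}

#' @describeIn evaluate_metrics overall metrics plus the stage-1 stopping
#'   fraction, one row per method.
#' @param x a `gs_sim`.
#' @param ... unused.
#' @export
glance.gs_sim <- function(x, ...) {
  m <- evaluate_metrics(x)
  dplyr::filter(m, .data$conditioning == "overall") |>
    dplyr::mutate(prob_stop1 = mean(x$replicates$stage == 1L))
}

#' Sweep a scenario over treatment response rates
#'
#' Re-runs a scenario across a grid of true treatment response rates with
#' independent sub-seeds, collecting the metrics and the stage-1 stopping
#' probability per grid point.  Failures at a grid point are isolated: the
#' point is dropped with a warning and the sweep continues.
#'
#' @param scenario a [gs_scenario()]; its `p_treatment` is ignored.
#' @param p_treatment_grid vector of true treatment response rates.
#' @return A tibble of class `gs_sweep` in long format: one row per
#'   (p_treatment, method, conditioning) with the metric columns of
#'   [evaluate_metrics()] plus `prob_stop1` and its Monte-Carlo SE.
#' @export
gs_sweep <- function(scenario, p_treatment_grid) {
  stopifnot(inherits(scenario, "gs_scenario"),
            length(p_treatment_grid) >= 1)
  rows <- purrr::imap(p_treatment_grid, function(p_trt, i) {
    sc <- scenario
    sc$p_treatment <- p_trt
    sc$seed <- seed_child(scenario$seed, 100L + i)
    res <- tryCatch({
      sim <- gs_simulate(sc)
      m <- evaluate_metrics(sim)
      p1 <- mean(sim$replicates$stage == 1L)
      dplyr::mutate(m, p_treatment = p_trt, prob_stop1 = p1,
                    mcse_prob_stop1 = sqrt(p1 * (1 - p1) / sc$n_reps),
                    .before = 1)
    }, error = function(e) {
      warning("sweep point p_treatment = ", p_trt, " failed: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("gs_sweep", class(out))
  out
}
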