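# Method registry and the user-facing interval table.

#' Confidence interval method labels
#'
#' The registry keys accepted by [gs_ci()] and the simulation engine, in the
#' conventional reporting order.  `"randomization"` requires re-running the
#' full group sequential analysis over re-randomized treatment labels and is
#' not part of the default set.
#'
#' @return character vector of method labels.
#' @export
ci_methods <- function() {
  c("wald", "final_unconditional", "repeated", "adjusted_asymptotic",
    "parametric_bootstrap", "randomization",
    "final_conditional", "restricted_final_conditional",
    "conditional_likelihood", "penalized_likelihood")
}

default_methods <- function() setdiff(ci_methods(), "randomization")

# dispatch a set of methods over a replicate frame; returns a long tibble
# rep x method with lower/upper/point/empty/failed
interval_table <- function(reps, design, methods, level, boot_reps,
                           seed = NULL, truncate = FALSE) {
  res <- list()
  cond_cache <- NULL
  need_cond <- any(c("final_conditional", "restricted_final_conditional")
                   %in% methods)
  if (need_cond) cond_cache <- iv_final_conditional(reps, design, level)
  for (mth in methods) {
    iv <- switch(
      mth,
      wald = iv_wald(reps, design, level),
      final_unconditional = iv_final_unconditional(reps, design, level),
      repeated = iv_repeated(reps, design, level),
      adjusted_asymptotic = iv_adjusted_asymptotic(reps, design, level),
      parametric_bootstrap = iv_parametric_bootstrap(
        reps, design, level, boot_reps, seed = seed_child(seed, 1L)),
      final_conditional = cond_cache,
      restricted_final_conditional = iv_restricted(cond_cache, reps,
                                                   design, level),
      conditional_likelihood = iv_conditional_bootstrap(
        reps, design, level, boot_reps, seed = seed_child(seed, 2L),
        variant = "likelihood"),
      # shares the likelihood variant's stream: the two estimators are
      # identical for replicates that continue to stage 2
      penalized_likelihood = iv_conditional_bootstrap(
        reps, design, level, boot_reps, seed = seed_child(seed, 2L),
        variant = "penalized"),
      stop("unknown CI method: ", mth, call. = FALSE)
    )
    iv$method <- mth
    iv$rep <- reps$rep
    res[[mth]] <- iv
  }
  out <- dplyr::bind_rows(res)
  if (truncate) {
    out <- dplyr::mutate(
      out,
      trunc_lower = !.data$failed & !.data$empty & .data$lower < -1,
      trunc_upper = !.data$failed & !.data$empty & .data$upper > 1,
      lower = pmax(.data$lower, -1),
      upper = pmin(.data$upper, 1)
    )
  } else {
    out$trunc_lower <- FALSE
    out$trunc_upper <- FALSE
  }
  dplyr::select(out, "rep", "method", "point", "lower", "upper",
                "empty", "failed", "trunc_lower", "trunc_upper")
}

# deterministic child seeds below 2^31
seed_child <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + 104729L * as.integer(k)) %% 2147483647L
}

#' Confidence intervals for an observed trial
#'
#' Computes any subset of the registered interval procedures for a completed
#' two-stage group sequential trial, together with each method's associated
#' point estimator where one exists (the overall MLE for the Wald interval,
#' the MUE for the exact unconditional interval, the bias-adjusted estimate
#' for the adjusted asymptotic interval, the bootstrap mean, the conditional
#' MUE for the conditional intervals, and the conditional/penalized MLE for
#' the likelihood-based intervals; the repeated interval has none).
#'
#' @param outcome a [run_stopping_rule()] result.
#' @param methods subset of [ci_methods()]; the default is every method
#'   except the randomization interval.
#' @param level confidence level; defaults to `1 - alpha` of the design.
#' @param boot_reps bootstrap replicates for the resampling-based methods.
#' @param resamples number of re-randomizations for the randomization
#'   interval.
#' @param seed integer seed controlling every stochastic method.
#' @param truncate constrain limits to the parameter space `[-1, 1]`
#'   (flagged in `flags` when active).
#' @return A tibble with one row per method: `method`, `point_estimate`,
#'   `lower`, `upper`, `width` and a comma-separated `flags` column
#'   (`empty_set`, `degenerate_information`, `truncated_lower`,
#'   `truncated_upper`, `zero_adjusted_pvalue`).
#' @examples
#' musec <- musec_trial()
#' out <- run_stopping_rule(musec$counts, musec$design)
#' gs_ci(out, methods = c("wald", "final_unconditional", "repeated"))
#' @export
gs_ci <- function(outcome, methods = NULL, level = NULL,
                  boot_reps = 10000, resamples = 10000, seed = NULL,
                  truncate = FALSE) {
  stopifnot(inherits(outcome, "gs_outcome"))
  design <- outcome$design
  if (is.null(level)) level <- 1 - design$alpha
  if (is.null(methods)) methods <- default_methods()
  methods <- match.arg(methods, ci_methods(), several.ok = TRUE)
  reps <- outcome_frame(outcome)
  std <- setdiff(methods, "randomization")
  tabs <- list()
  if (length(std)) {
    tab <- interval_table(reps, design, std, level, boot_reps,
                          seed = seed, truncate = truncate)
    tab$zero_p <- FALSE
    tabs <- c(tabs, list(tab))
  }
  if ("randomization" %in% methods) {
    tabs <- c(tabs, list(randomization_row(outcome, level, resamples,
                                           seed = seed_child(seed, 4L),
                                           truncate = truncate)))
  }
  tab <- dplyr::bind_rows(tabs)
  tab$point <- point_estimates(tab, outcome)
  tab$method <- factor(tab$method, levels = ci_methods())
  tab <- dplyr::arrange(tab, .data$method)
  tibble(
    method = as.character(tab$method),
    point_estimate = tab$point,
    lower = tab$lower,
    upper = tab$upper,
    width = tab$upper - tab$lower,
    flags = flag_string(tab)
  )
}

# associated point estimators by method (NA for the repeated interval,
# which has none)
point_estimates <- function(tab, outcome) {
  m <- outcome$model
  mue <- function() {
    root1(function(th) stagewise_p_value(th, outcome), 0.5)
  }
  cmue <- function() {
    root1(function(th) conditional_exceedance(th, outcome), 0.5,
          max_double = 14L, iters = 80L)
  }
  pen <- function() {
    if (outcome$stop_stage == 2L) return(conditional_mle(outcome))
    penalized_estimate(lambda_star(m$e1), outcome$z1, 1L, m)
  }
  vapply(seq_len(nrow(tab)), function(i) {
    if (tab$failed[i]) return(NA_real_)
    switch(tab$method[i],
           wald = outcome$theta_hat,
           final_unconditional = mue(),
           repeated = NA_real_,
           adjusted_asymptotic = tab$point[i],
           parametric_bootstrap = tab$point[i],
           randomization = tab$point[i],
           final_conditional = cmue(),
           restricted_final_conditional = cmue(),
           conditional_likelihood = conditional_mle(outcome),
           penalized_likelihood = pen(),
           NA_real_)
  }, numeric(1))
}

flag_string <- function(tab) {
  purrr::pmap_chr(
    list(tab$empty, tab$failed, tab$trunc_lower, tab$trunc_upper, tab$zero_p),
    function(empty, failed, tl, tu, zp) {
      f <- c(if (empty) "empty_set",
             if (failed) "degenerate_information",
             if (tl) "truncated_lower",
             if (tu) "truncated_upper",
             if (zp) "zero_adjusted_pvalue")
      paste(f, collapse = ",")
    }
  )
}

# one-row replicate frame for an observed outcome
outcome_frame <- function(outcome) {
  m <- outcome$model
  w <- counts_wide(outcome$counts, outcome$stop_stage)
  tibble(
    rep = 1L,
    stage = outcome$stop_stage,
    theta_hat = outcome$theta_hat,
    z1 = outcome$z1, z2 = outcome$z2,
    info1 = m$info1,
    info2_obs = outcome$observed_info2,
    info2 = m$info2,
    se_w = unpooled_se(w$s_control, w$n_control,
                       w$s_treatment, w$n_treatment),
    pc_hat = outcome$p_control, pt_hat = outcome$p_treatment,
    rejected = outcome$rejected,
    valid = TRUE,
    s2c = NA_integer_, s2t = NA_integer_
  )
}
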