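# Applying the stopping rule to observed data; the resulting trial outcome
# object carries everything the interval procedures need.

#' Apply the group sequential stopping rule to observed counts
#'
#' Computes the stage-1 standardized statistic, decides whether the trial
#' stops early, and (when it continues) evaluates the final analysis.  The
#' returned outcome records the stopping stage `T`, the MLE of the treatment
#' difference at the stopping stage, the standardized statistics, the
#' hypothesis test decision, and the canonical normal model built from the
#' observed information.
#'
#' Supplying stage-2 counts for a trial whose stage-1 statistic already
#' crosses the boundary (or omitting them for one that continues) is an
#' error: the counts table must describe a trial run under the design.
#'
#' @param counts a counts table (see [stage_summary()]); stage 2 rows are
#'   cumulative and may be absent for a trial stopped at stage 1.
#' @param design a [gs_design()].
#' @return An object of class `gs_outcome`: a list with `stop_stage`,
#'   `theta_hat`, `z1`, `z2` (`NA` when stopped early), `rejected`, `model`
#'   (a [canonical_model()]), the per-arm rate estimates at the stopping
#'   stage, and the design.
#' @examples
#' musec <- musec_trial()
#' run_stopping_rule(musec$counts, musec$design)
#' @export
run_stopping_rule <- function(counts, design) {
  stopifnot(inherits(design, "gs_design"))
  counts <- validate_counts(counts)
  w1 <- counts_wide(counts, 1)
  if (is.null(w1)) stop("stage 1 counts are required", call. = FALSE)
  info1 <- pooled_information(w1$s_control, w1$n_control,
                              w1$s_treatment, w1$n_treatment)
  if (is.na(info1)) {
    stop("degenerate stage-1 data: pooled response rate is 0 or 1",
         call. = FALSE)
  }
  z1 <- z_statistic(w1$s_control, w1$n_control,
                    w1$s_treatment, w1$n_treatment)
  w2 <- counts_wide(counts, 2)
  stops <- z1 >= design$e1
  if (stops && !is.null(w2)) {
    stop("stage 2 counts supplied but the stage-1 statistic crosses the ",
         "efficacy boundary (z1 = ", round(z1, 3), " >= ", design$e1, ")",
         call. = FALSE)
  }
  if (!stops && is.null(w2)) {
    stop("the trial continues (z1 = ", round(z1, 3), " < ", design$e1,
         ") but no stage 2 counts were supplied", call. = FALSE)
  }
  if (stops) {
    theta_hat <- mle_difference(w1$s_control, w1$n_control,
                                w1$s_treatment, w1$n_treatment)
    out <- list(
      stop_stage = 1L, theta_hat = theta_hat, z1 = z1, z2 = NA_real_,
      rejected = TRUE,
      p_control = w1$s_control / w1$n_control,
      p_treatment = w1$s_treatment / w1$n_treatment,
      model = canonical_model(info1, projected_info2(info1, design),
                              design$e1, design$e2),
      observed_info2 = NA_real_,
      design = design, counts = counts
    )
  } else {
    info2 <- pooled_information(w2$s_control, w2$n_control,
                                w2$s_treatment, w2$n_treatment)
    if (is.na(info2)) {
      stop("degenerate stage-2 data: pooled response rate is 0 or 1",
           call. = FALSE)
    }
    z2 <- z_statistic(w2$s_control, w2$n_control,
                      w2$s_treatment, w2$n_treatment)
    theta_hat <- mle_difference(w2$s_control, w2$n_control,
                                w2$s_treatment, w2$n_treatment)
    out <- list(
      stop_stage = 2L, theta_hat = theta_hat, z1 = z1, z2 = z2,
      rejected = z2 >= design$e2,
      p_control = w2$s_control / w2$n_control,
      p_treatment = w2$s_treatment / w2$n_treatment,
      model = canonical_model(info1, info2, design$e1, design$e2),
      observed_info2 = info2,
      design = design, counts = counts
    )
  }
  structure(out, class = "gs_outcome")
}

# Final-analysis information projected from stage-1 data, used by methods
# that need I2 when the trial stopped at stage 1: the stage-1 pooled rate is
# carried forward, so the information scales by the ratio of the harmonic
# sample size terms.
projected_info2 <- function(info1, design) {
  info1 * (1 / design$n1_control + 1 / design$n1_treatment) /
    (1 / design$n2_control + 1 / design$n2_treatment)
}

#' @export
print.gs_outcome <- function(x, ...) {
  cat(sprintf("Group sequential trial outcome: stopped at stage %d, H0 %s\n",
              x$stop_stage, if (x$rejected) "rejected" else "not rejected"))
  cat(sprintf("  theta_hat = %.4f (treatment %.4f - control %.4f)\n",
              x$theta_hat, x$p_treatment, x$p_control))
  if (x$stop_stage == 1L) {
    cat(sprintf("  z1 = %.3f (boundary %.3f)\n", x$z1, x$design$e1))
  } else {
    cat(sprintf("  z1 = %.3f (boundary %.3f), z2 = %.3f (boundary %.3f)\n",
                x$z1, x$design$e1, x$z2, x$design$e2))
  }
  cat(sprintf("  information: I1 = %.1f, I2 = %.1f%s\n", x$model$info1,
              x$model$info2,
              if (x$stop_stage == 1L) " (projected)" else ""))
  invisible(x)
}

#' @describeIn run_stopping_rule one row per analysis with its summary
#'   statistics.
#' @param x a `gs_outcome`.
#' @param ... unused.
#' @export
tidy.gs_outcome <- function(x, ...) {
  stage_summary(x$counts)
}

#' @describeIn run_stopping_rule one-row summary of the trial result.
#' @export
glance.gs_outcome <- function(x, ...) {
  tibble(stop_stage = x$stop_stage, theta_hat = x$theta_hat,
         z1 = x$z1, z2 = x$z2, rejected = x$rejected,
         info1 = x$model$info1, info2 = x$observed_info2)
}
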