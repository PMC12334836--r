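# Per-analysis summary statistics for a two-arm binary endpoint.
#
# Convention used throughout: the effect is theta = p_treatment - p_control,
# tested one-sided against theta > 0.  Test statistics and the information
# scale use the pooled variance estimate of the proportion difference; the
# Wald interval uses the unpooled variance.  This pairing reproduces the
# standardized statistics and the standard interval reported for the
# motivating trial.

#' Maximum likelihood estimate of the treatment difference
#'
#' @param s_control,n_control successes and totals on the control arm
#'   (cumulative at the analysis).
#' @param s_treatment,n_treatment same for the treatment arm.
#' @return `s_treatment/n_treatment - s_control/n_control`, vectorized.
#' @export
mle_difference <- function(s_control, n_control, s_treatment, n_treatment) {
  if (any(n_control <= 0) || any(n_treatment <= 0)) {
    stop("arm totals must be positive", call. = FALSE)
  }
  s_treatment / n_treatment - s_control / n_control
}

#' Fisher information of the treatment difference (pooled variance)
#'
#' The inverse of `pbar * (1 - pbar) * (1/n_control + 1/n_treatment)` with
#' `pbar` the pooled response rate.  Returns `NA` where the pooled rate is 0
#' or 1, in which case the information (and the z statistic) is undefined.
#'
#' @inheritParams mle_difference
#' @export
pooled_information <- function(s_control, n_control, s_treatment, n_treatment) {
  if (any(n_control <= 0) || any(n_treatment <= 0)) {
    stop("arm totals must be positive", call. = FALSE)
  }
  pbar <- (s_control + s_treatment) / (n_control + n_treatment)
  ifelse(pbar > 0 & pbar < 1,
         1 / (pbar * (1 - pbar) * (1 / n_control + 1 / n_treatment)),
         NA_real_)
}

#' Standardized test statistic
#'
#' The MLE of the difference times the square root of the pooled-variance
#' information, i.e. the usual two-sample pooled z statistic for proportions.
#'
#' @inheritParams mle_difference
#' @export
z_statistic <- function(s_control, n_control, s_treatment, n_treatment) {
  mle_difference(s_control, n_control, s_treatment, n_treatment) *
    sqrt(pooled_information(s_control, n_control, s_treatment, n_treatment))
}

#' Unpooled (Wald) standard error of the treatment difference
#'
#' @inheritParams mle_difference
#' @export
unpooled_se <- function(s_control, n_control, s_treatment, n_treatment) {
  if (any(n_control <= 0) || any(n_treatment <= 0)) {
    stop("arm totals must be positive", call. = FALSE)
  }
  pc <- s_control / n_control
  pt <- s_treatment / n_treatment
  sqrt(pt * (1 - pt) / n_treatment + pc * (1 - pc) / n_control)
}

# ---- tidy counts table helpers ----

# A counts table has one row per (stage, arm): columns stage, arm
# ("control"/"treatment"), successes, total, cumulative at each analysis.
validate_counts <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("stage", "arm", "successes", "total")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns stage, arm, successes, total",
         call. = FALSE)
  }
  if (!all(counts$arm %in% c("control", "treatment"))) {
    stop('arm must be "control" or "treatment"', call. = FALSE)
  }
  if (any(counts$successes < 0) || any(counts$successes > counts$total) ||
      any(counts$total <= 0)) {
    stop("need 0 <= successes <= total and total > 0", call. = FALSE)
  }
  counts
}

# wide per-stage list: for stage k, (s_control, n_control, s_treatment,
# n_treatment); NULL when the stage is absent.
counts_wide <- function(counts, stage) {
  rows <- counts[counts$stage == stage, ]
  if (nrow(rows) == 0) return(NULL)
  if (nrow(rows) != 2) stop("each stage needs one control and one treatment row",
                            call. = FALSE)
  ctl <- rows[rows$arm == "control", ]
  trt <- rows[rows$arm == "treatment", ]
  list(s_control = ctl$successes, n_control = ctl$total,
       s_treatment = trt$successes, n_treatment = trt$total)
}

#' Per-analysis summary of a stage counts table
#'
#' @param counts a counts table with columns `stage`, `arm` (`"control"` or
#'   `"treatment"`), `successes`, `total` (cumulative at each analysis).
#' @return A tibble with one row per analysis: the MLE of the difference,
#'   the pooled-variance information, the standardized statistic and the
#'   unpooled standard error.
#' @examples
#' stage_summary(musec_trial()$counts)
#' @export
stage_summary <- function(counts) {
  counts <- validate_counts(counts)
  purrr::map_dfr(sort(unique(counts$stage)), function(k) {
    w <- counts_wide(counts, k)
    tibble(
      stage = k,
      theta_hat = mle_difference(w$s_control, w$n_control,
                                 w$s_treatment, w$n_treatment),
      information = pooled_information(w$s_control, w$n_control,
                                       w$s_treatment, w$n_treatment),
      z = z_statistic(w$s_control, w$n_control,
                      w$s_treatment, w$n_treatment),
      se_unpooled = unpooled_se(w$s_control, w$n_control,
                                w$s_treatment, w$n_treatment)
    )
  })
}

#' Read / write a stage counts table
#'
#' Plain CSV with columns `stage`, `arm`, `successes`, `total` (cumulative
#' per analysis).
#'
#' @param file path to a CSV file.
#' @export
read_stage_counts <- function(file) {
  validate_counts(readr::read_csv(file, show_col_types = FALSE,
                                  col_types = "icii"))
}

#' @param counts a counts table.
#' @rdname read_stage_counts
#' @export
write_stage_counts <- function(counts, file) {
  readr::write_csv(validate_counts(counts), file)
  invisible(file)
}
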