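# Embedded case-study fixture: a two-stage, two-arm trial of an oral
# cannabis extract against placebo for relief from muscle stiffness in
# multiple sclerosis, run with one-sided O'Brien-Fleming efficacy stopping.

#' MUSEC trial data and design
#'
#' The observed cumulative success counts of the MUSEC trial at its interim
#' analysis (12/97 placebo vs 27/101 active) and final analysis (21/134 vs
#' 42/143), together with its two-stage design: one-sided O'Brien-Fleming
#' efficacy boundaries 2.797 and 1.977, no stage-1 futility bound, and 95%
#' confidence intervals.  The trial's interim statistic (2.540) fell just
#' short of the early-stopping boundary, so the trial continued and rejected
#' the null at the final analysis (2.718 >= 1.977).
#'
#' @return A list with elements `design` (a [gs_design()]) and `counts`
#'   (a counts table, see [stage_summary()]).
#' @examples
#' musec <- musec_trial()
#' stage_summary(musec$counts)
#' @export
musec_trial <- function() {
  design <- gs_design(
    n1_control = 97, n1_treatment = 101,
    n2_control = 134, n2_treatment = 143,
    e1 = 2.797, e2 = 1.977, alpha = 0.05
  )
  counts <- tibble(
    stage = c(1L, 1L, 2L, 2L),
    arm = c("control", "treatment", "control", "treatment"),
    successes = c(12L, 27L, 21L, 42L),
    total = c(97L, 101L, 134L, 143L)
  )
  list(design = design, counts = counts)
}

#' Render an interval table for reporting
#'
#' Formats a [gs_ci()] result the way trial reports print it: point
#' estimate, interval and width at a fixed number of decimals, with widths
#' computed from the unrounded limits before formatting.  Empty intervals
#' are rendered with an explicit marker.
#'
#' @param ci_table a [gs_ci()] result.
#' @param digits decimals to print (default 3).
#' @return A tibble of formatted strings with columns `method`, `estimate`,
#'   `ci` and `width`.
#' @export
render_ci_table <- function(ci_table, digits = 3) {
  fm <- function(x) ifelse(is.na(x), "-", sprintf("%.*f", digits, x))
  tibble(
    method = ci_table$method,
    estimate = fm(ci_table$point_estimate),
    ci = dplyr::if_else(
      grepl("empty_set", ci_table$flags),
      "(empty set)",
      paste0("(", fm(ci_table$lower), ", ", fm(ci_table$upper), ")")
    ),
    width = dplyr::if_else(grepl("empty_set", ci_table$flags), "-",
                           fm(ci_table$width))
  )
}
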