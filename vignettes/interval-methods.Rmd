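---
title: "Interval estimation after a two-stage group sequential trial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval estimation after a two-stage group sequential trial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsdci)
```

## The setting

A two-arm trial with a binary endpoint is monitored once before its planned
end.  Write $\theta = p_T - p_C$ for the difference in response
probabilities, $\hat\theta_k$ for its MLE on the cumulative data at analysis
$k$, and
$I_k = \left[\bar p_k(1-\bar p_k)(1/n_{Ck} + 1/n_{Tk})\right]^{-1}$
for the Fisher information based on the pooled response rate $\bar p_k$.
The standardized statistics $Z_k = \hat\theta_k \sqrt{I_k}$ follow, to the
usual asymptotic accuracy, the canonical joint normal model of group
sequential analysis: $Z_k \sim N(\theta\sqrt{I_k},\,1)$ with
$\mathrm{Cov}(Z_1, Z_2) = \sqrt{I_1/I_2}$.  The trial stops at the interim
analysis, rejecting $H_0\colon \theta \le 0$, if $Z_1 \ge e_1$; otherwise it
continues and rejects if $Z_2 \ge e_2$.  One-sided O'Brien–Fleming
boundaries take the form $e_k = C\sqrt{K/k}$ with $C$ calibrated so the
total null crossing probability equals the one-sided level
(`obf_boundaries(2, 0.025)` gives 2.797, 1.977).  There is no stage-1
futility rule.

Two conventions are fixed throughout and pinned by reproduction tests: the
*test statistics and the information scale use the pooled variance*, while
the *Wald interval uses the unpooled variance*.  This is the only pairing
that reproduces both the published interim/final statistics (2.540, 2.718)
and the published standard interval (0.040, 0.234) of the embedded
case-study trial.

After such a trial the standard Wald interval ignores the stopping rule; its
coverage can be badly wrong conditional on when the trial stopped.  The
package implements the spectrum of corrected procedures and a simulation
engine for judging them.

## The interval family

**Exact unconditional (stagewise ordering).**  The p-value function under
stagewise ordering is, for a trial that continued and observed $z_2$,
$$P(\theta) = \Pr_\theta(Z_1 \ge e_1) + \Pr_\theta(Z_1 < e_1,\ Z_2 \ge z_2),$$
and $\Pr_\theta(Z_1 \ge z_1)$ for a stage-1 stop.  $P$ is strictly
increasing in $\theta$; the interval takes the $\alpha/2$ and $1-\alpha/2$
roots and the median unbiased estimate (MUE) the $0.5$ root.  At a stage-1
stop the roots have the closed form $(\Phi^{-1}(q) + z_1)/\sqrt{I_1}$, which
the root-finder must (and does, to $10^{-6}$) agree with.

**Repeated.**  $\hat\theta_T \pm e_T/\sqrt{I_T}$ — the simultaneous
interval, valid at every analysis, always consistent with the boundary
decision, conservative and correspondingly wide after early stops.  It has
no associated point estimator.

**Adjusted asymptotic.**  The stopped MLE has exact canonical-model moments
available in closed form because the stopping region is a half-line in
$Z_1$: with $c_1 = e_1 - \theta\sqrt{I_1}$,
$$\mu(\theta) = \mathrm{E}_\theta[\hat\theta_T] - \theta
  = \varphi(c_1)\left(\tfrac{1}{\sqrt{I_1}} - \tfrac{\sqrt{I_1}}{I_2}\right),$$
and a matching closed form for
$\sigma^2(\theta) = I_T\,\mathrm{Var}_\theta[\hat\theta_T]$.  The interval
is $(\hat\theta - \mu(\hat\theta)) \pm z_{1-\alpha/2}\,
\sigma(\hat\theta)/\sqrt{I_T}$; both functions are unit-tested against
numerical integration and Monte Carlo.  For a trial stopped at stage 1 the
final information is not observed; it is projected by carrying the stage-1
pooled rate to the final sample sizes.  When the observed information
*decreases* between analyses (possible with binary data when the pooled
rate is near 0 or 1 at the interim) this method — and every method built on
the bivariate normal — is reported as failed rather than computed.

**Parametric bootstrap.**  Whole two-stage trials are resimulated at the
stopping-stage rate estimates, the stopping rule is applied to each, and the
percentile interval of the stopped MLEs is reported; the point estimate is
their mean.

**Randomization-based.**  Treatment labels are re-randomized within each
stage with outcomes held fixed; the adjusted p-value is the proportion of
allocations whose (stopping stage, statistic) pair is at least as extreme in
the stagewise ordering, with the hypothesized effect removed from treated
outcomes before each evaluation, and the interval inverts that p-value over
the effect with a common allocation set.  The statistic is studentized by
the allocation-invariant dispersion of the effect-removed outcomes, so
allocations with identical group compositions are exactly equivalent.  With
finitely many resamples the adjusted p-value can be exactly zero on extreme
data; the result then carries a `zero_adjusted_pvalue` flag.

**Exact conditional.**  Conditioning on the stopping stage, the exceedance
probability $\Pr(\hat\theta \ge \hat\theta_{obs} \mid T = t, \theta)$ is a
renormalized normal tail (stage 1) or a bivariate-normal ratio (stage 2),
again strictly increasing in $\theta$; roots at $\alpha/2$, $0.5$ (the
conditional MUE) and $1-\alpha/2$ define the interval.  Near-boundary
stage-1 stops make the conditional lower limit dive — below $-1$, outside
the parameter space — which is reported as-is unless `truncate = TRUE`
clamps to $[-1, 1]$ with flags.  The *restricted* variant intersects with
the effect region where the observed stopping stage is not too improbable:
after continuation the upper limit is capped at
$(e_1 - \Phi^{-1}(\alpha/2))/\sqrt{I_1}$, after an early stop the lower
limit is floored at $(e_1 - \Phi^{-1}(1-\alpha/2))/\sqrt{I_1}$; the
intersection can be empty, which is a first-class flagged result (the
simulation engine counts it as non-covering and inconsistent), not an error.

**Conditional and penalized likelihood.**  The conditional MLE maximizes
$-(z_t - \theta\sqrt{I_t})^2/2 - \log \Pr(T = t \mid \theta)$; its score
fixed point is
$\hat\theta_c = \hat\theta_{obs} + (\sqrt{I_1}/I_2)\,\varphi(c)/\Phi(c)$
after continuation (an upward correction: small interim estimates are
selected into stage 2) and
$\hat\theta_c = \hat\theta_{obs} - \varphi(c)/(\sqrt{I_1}(1-\Phi(c)))$
after an early stop, with $c = e_1 - \hat\theta_c\sqrt{I_1}$.  Weighting
the penalty by $\lambda \in [0,1]$ interpolates between the MLE
($\lambda=0$) and the conditional MLE ($\lambda=1$).  On the z scale the
stage-1 score does not involve the information, so the weight that zeroes
the estimate of a trial stopping exactly on the boundary is the closed form
$\lambda^* = e_1\,(1-\Phi(e_1))/\varphi(e_1) \approx 0.910$ for
$e_1 = 2.797$.  Confidence intervals for both estimators use a conditional
bootstrap: trials are resimulated at the observed stopping-stage rates,
only replicates stopping at the observed stage are retained (an error is
raised if retention falls below $10^{-4}$), the (penalized) conditional MLE
is computed per retained replicate, and percentile limits are reported.
Because every retained stage-1 replicate has $z_1 \ge e_1$, the
$\lambda^*$-penalized estimates are all positive and the resulting interval
is guaranteed consistent with the early-efficacy decision.  After
continuation the penalized and conditional procedures are the same
estimator, and the implementation shares one bootstrap stream so the two
intervals are identical.

The plug-in rates for the conditional bootstrap were a genuinely open
design point.  Resampling at rates implied by the conditional MLE shifts
the conditional sampling distribution upward and gives an interval near
(0.077, 0.379) for the case study; resampling at the *observed* rates
reproduces the published (0.034, 0.304).  The package resamples at the
observed rates.

### A caveat on the adjusted asymptotic interval

The mean and variance functions used here are the *exact* canonical-model
moments of the stopped MLE (verified against independent integration and
simulation oracles).  For the case-study trial they give a width of 0.212.
The originating literature's tabulated value (0.196) implies an adjustment
that is nearly inactive at this data ($\hat\mu \approx 0$,
$\hat\sigma \approx 0.99$), i.e. an asymptotic expansion whose exact form
we could not recover from the available sources.  The reproduction test for
this one cell is left failing rather than fitting an ad-hoc formula to the
printed number; all other tabulated cells reproduce.

## Numerical choices

- Bivariate-normal rectangle probabilities are one-dimensional integrals
  of $\varphi(u)\,\bar\Phi((b-\rho u)/\sqrt{1-\rho^2})$.  The inner factor
  transitions from 0 to 1 on a band of width $17\sqrt{1-\rho^2}/\rho$;
  outside the band the integral is an exact normal-CDF difference, inside
  it composite Gauss–Legendre panels (6 × 16 nodes) resolve the
  transition.  Absolute error is below $10^{-14}$ at any correlation
  (oracle-tested against adaptive quadrature).
- Conditional (stage-2) probabilities are evaluated as shared-formula
  ratios with exact denominators, and switch to the truncated-normal
  asymptote when the continuation probability underflows.
- Root finding is bracketed bisection on the monotone p-value /
  exceedance functions, vectorized across simulation replicates; brackets
  start at $[-1.5, 1.5]$ and expand by doubling (the conditional methods
  allow up to $\pm 2.5\times 10^4$ on the effect scale, since near-boundary
  stage-1 stops genuinely have limits of that magnitude).  60–80 bisection
  steps leave the roots at floating-point resolution, far inside the
  $10^{-6}$ contract.
- The stage-2 conditional-MLE fixed point is a contraction with rate
  $\le I_1/I_2 < 1$ and is iterated to $10^{-8}$; replicates whose
  information decreased (where the iteration can diverge) are failed and
  counted, mirroring how rarely this occurs in practice (order $10^{-5}$
  per replicate at case-study-like rates).
- O'Brien–Fleming calibration solves the crossing-probability equation to
  $10^{-8}$; for more than two analyses the crossing probability comes
  from the continuation-density grid recursion with analytic increment
  tails.

## What the simulation engine emulates — and what it does not

`gs_simulate()` draws stage-1 successes per arm from the true rates,
applies the pooled-variance z statistic and the boundary, accrues
independent stage-2 increments for continuing replicates, and computes all
requested intervals per replicate (method comparisons are paired: every
method sees the same trials).  Replicates with a degenerate pooled rate are
failed and counted, never silently regenerated.  Metrics follow the exact
accounting identity
$\text{coverage} + \Pr(L>\theta) + \Pr(U<\theta) + (\text{empty} +
\text{failed})/n = 1$
per stratum (overall, stopped-at-1, continued-to-2), with width moments
over non-empty intervals and consistency defined against the one-sided
decision (a rejecting replicate's interval must lie above 0; a
non-rejecting one must contain it).

The generator emulates exactly the binomial two-stage mechanism the
procedures assume, plus the normal approximation error that binomial data
induce.  It does not emulate overdispersion, covariate adjustment,
staggered entry, non-binding futility behavior, or the sample-size
re-estimation that adaptive designs may layer on top; passing tests
therefore certify the procedures under the canonical two-stage binomial
model, not robustness beyond it.

Default problem sizes are chosen so that a laptop run is informative:
$10^5$ replicates for non-bootstrap methods (Monte-Carlo SE on coverage
$< 0.0016$), $10^4$ replicates with $10^3$ bootstrap samples for
bootstrap-backed methods; the sweep helper accepts any grid and derives
independent sub-seeds per point.  The case-study bootstrap intervals use
$10^5$ replicates in tests (percentile MCSEs of a few $10^{-3}$), against
the $10^6$ used for the published table.

## Reproducing the case study

```{r table2, eval = FALSE}
musec <- musec_trial()
outcome <- run_stopping_rule(musec$counts, musec$design)
render_ci_table(gs_ci(outcome, boot_reps = 1e5, seed = 1))
```

## Known limitations

- Two analyses only for the interval procedures (boundary calibration
  supports any number); no futility bounds; no alternative sample-space
  orderings for the exact interval; no bias-corrected/accelerated bootstrap
  variants.
- The adjusted asymptotic interval uses exact stopped-MLE moments, not the
  (unrecoverable) expansion behind the published table cell; see the caveat
  above.
- The randomization interval re-runs the full analysis per resample and is
  priced accordingly; it is excluded from simulation sweeps.
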