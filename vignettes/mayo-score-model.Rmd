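---
title: "Linked longitudinal models of the Mayo Clinical Score: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linked longitudinal models of the Mayo Clinical Score: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Placebo/standard-of-care (SoC) arms of ulcerative colitis (UC) trials show
high and variable response, and their patients are progressively removed
from the trial — at the end of the induction phase (responder-based
re-randomization, rescue therapy) and during maintenance.  Any longitudinal
description of disease activity in such arms must therefore model the
scores *and* the score-driven dropout jointly, or simulated trials will not
look like real ones.

`ucmayo` implements a linked model of the Mayo Clinical Score (MCS) and
its components in placebo/SoC-treated adults with moderate to severe
active UC.  The MCS is the sum of four 0-3 subscores: rectal bleeding
(RB), stool frequency (SF), physician's global assessment (PGA) and
endoscopy (ENDO).  RB and SF are combined into a single 0-6 ordinal
endpoint (RB+SF).  The *modified* MCS (RB+SF+ENDO, 0-9) is the
regulator-preferred endpoint; the full MCS adds PGA.

## Model structure

Each subscore is described by a proportional-odds (PO) model for the
cumulative probabilities of the ordered categories.  For subject $i$ at
time $t_j$, the cut-point logits are

$$\mathrm{logit}\, P(Y_{ij} \ge m \mid \eta_i) = \alpha_m + \mathrm{PLB}(t_j) + \eta_i,$$

with $\alpha_m = \alpha_{m-1} + \mathrm{DF}_m$ and every
$\mathrm{DF}_m < 0$, which enforces the ordering of the cumulative
probabilities by construction.  $\eta_i \sim N(0, \omega^2)$ is a
subject-level random intercept shared across cut-points and visits of one
submodel; the $\eta$'s of the three submodels are independent.  The
placebo effect is piecewise linear in time with separate induction and
maintenance slopes (units 1/day),

$$\mathrm{PLB}(t) = -\theta_\mathrm{ind}\,\min(t, T_\mathrm{ind})
                    -\theta_\mathrm{maint}\,\max(0, t - T_\mathrm{ind}),$$

continuous with a kink at the end of induction $T_\mathrm{ind}$.

Covariates act multiplicatively on the first cut-point intercept:
$1 + \theta\,(x - x_\mathrm{ref})$ for continuous covariates and
$1 + \theta$ for categorical flags.  The three submodels are linked
through *observed* scores, not shared parameters:

* **RB+SF** (0-6): baseline RB+SF (continuous) and prior anti-TNF
  exposure (categorical) on the intercept; its own placebo slopes;
  $\omega^2 = 3.47$.
* **ENDO** (0-3): baseline ENDO level (categorical, 3 vs 2) and the
  RB+SF subscore carried forward from the same or most recent symptom
  visit (continuous, uncentered).  No separate time effect: the placebo
  response enters through the time course of RB+SF.
* **PGA** (0-3): baseline PGA and the carried-forward modified MCS
  (uncentered), plus its own placebo slopes.  PGA is modeled only at
  endoscopy visits.

Dropout is a visit-level logistic regression on the most recent RB+SF
score, $\mathrm{logit}\,P_\mathrm{drop} = \theta_0 + \theta_1
(\mathrm{RB{+}SF})$, with one parameter pair for the single
end-of-induction event (only in trials that continue into maintenance)
and another for the per-scheduled-visit maintenance hazard.  Dropout
never occurs before the end of induction; induction-only trials end
administratively.

The packaged configuration (`inst/extdata/default_config.yaml`) carries
the complete reference parameter set of the pooled five-trial analysis,
so `simulate_trial()` works with zero user input.

### Covariate reference values

Two readings of the covariate linkage are possible: the factors can
multiply the first cut-point only (with the `DF` offsets added
unscaled), or every cut-point.  The parameter naming of the reference
analysis ties the covariate effects to $\alpha_1$, and scaling *all*
cut-points is numerically untenable for the ENDO model (the large
carried-forward RB+SF factor would push $\alpha_2 \times$ factor to
$-25$, emptying categories 2-3 that dominate the data).  The package
therefore defaults to the $\alpha_1$ scope and exposes
`covariate_scope = "all"` as a sensitivity switch.

Baseline subscore covariates are *centered* at the pooled baseline
median (RB+SF at 4, PGA at 2), so $\alpha_1$ is the intercept of a
reference patient.  This is a deliberate design choice: with raw
baseline values the $\alpha_1$-scope model implies strong score
escalation under placebo (simulated mean RB+SF rising from 4.0 to ~5.0
by week 8) and end-of-induction dropout that retains only ~19% of
patients into maintenance, whereas the reference analysis reports
declining scores and 220/487 (~45%) maintenance entry.  With centered
baselines the simulated cohort declines (placebo response) and ~48%
enter maintenance.  The carried-forward covariates must stay uncentered:
with $\theta_{\mathrm{PDV,RB+SF}} = 1.63$ and
$\theta_{\mathrm{PDV,mMCS}} = 130$, any centering would make the
$1+\theta x$ factor non-positive over part of the observed range, which
the package rejects as a sign flip of the cut-point scale.

## The synthetic cohort generator

No patient-level data are distributed or required: the generator
emulates the five pooled placebo/SoC arms — enrollments 222/256/96/135/46
(total 755), induction 8/8/8/12/8 weeks, maintenance —/44/44/40/— weeks,
prior-anti-TNF fractions 0/0.40/0/0.20/0.26.  Symptom (RB+SF) and PGA
visits are scheduled 2-weekly in induction and 4-weekly in maintenance;
endoscopy at day 0, the end of induction, week 32 (36 for the 12-week
induction trial) and the final week.  The published assessment frequency
is only "every 2-6 weeks", so this concrete calendar is an assumption,
recorded in the configuration where it can be changed.

Baseline profiles are drawn from the per-study category marginals of the
reference analysis, coupled by an exchangeable Gaussian copula, and
profiles violating the trial inclusion criteria (MCS 6-12 and ENDO 2-3)
are rejected and redrawn.  The copula correlation (0.5) was calibrated
once so that the pooled baseline MCS standard deviation matches the
reported 1.63; independent sampling plus truncation underdisperses the
total score (SD 1.36) and even induces a slight negative correlation
between subscores, because the truncation conditions on their sum.
Setting `baseline_correlation: 0` in the configuration restores fully
independent marginals.

What the generator does *not* emulate: site effects, calendar-time
enrollment, re-randomization arms, rescue pathways, missed visits, or
any within-subject serial correlation beyond the shared random
intercepts and observed-score linkage.  Passing tests on synthetic data
therefore demonstrate self-consistency of the machinery and
recoverability of the parameters under the stated design — not fidelity
of the model to any particular real trial.

## Estimation

The marginal likelihood of each submodel integrates the conditional
ordinal likelihood over the subject random effect.  The package uses
adaptive Gauss-Hermite quadrature: for each subject the conditional mode
of $h(\eta) = \ell_i(\eta) - \eta^2/2\omega^2$ is found by Newton steps
(the ordinal log-likelihood is concave in $\eta$, so clipped undamped
Newton converges), and the nodes are centered at the mode and scaled by
the curvature.  `method = "laplace"` is the one-node special case and
mirrors the estimation method of the reference analysis; the default is
21 nodes, which agrees with a brute-force 20,001-point trapezoid
integral over an $8\sigma$ grid to better than $10^{-6}$ (enforced by
the test suite on randomized instances).

Transforms keep the parameter space unconstrained for the quasi-Newton
optimizer (`nlminb`, relative tolerance $10^{-8}$): $\mathrm{DF}_m =
-e^{\xi_m}$ and $\omega^2 = e^{\zeta}$; covariate coefficients and
slopes are free, with factor positivity checked at the data points.
Starting values are data-driven (empirical cumulative logits for the
cut-points, null covariate effects), and the default fit is two-stage: a
cheap one-node (Laplace) pre-fit travels the long approach path — in
particular the flat intercept/coefficient ridge of the PGA model — before
the full 21-node quadrature objective refines from that point.  Apparent
non-convergence triggers a warm continuation (after an iteration-limit
stop) or up to two deterministic jittered restarts.  Cut-points above the
highest observed category are fixed at a $-15$ increment with a warning
rather than left free.  Curvature standard errors come from a central
finite-difference Hessian (step $10^{-4}$ on the transformed scale) via
the delta method; `bootstrap_se()` offers nonparametric subject
resampling, stratified by study so every replicate preserves the trial
designs.

Only post-baseline, non-sentinel observations enter the likelihood;
baseline scores act purely as covariates, so the model does not predict
baseline.  Fitting is sequential — RB+SF, then ENDO (carried-forward
observed RB+SF), then PGA (observed modified MCS), then dropout — with
no shared parameters, matching the linkage through observed covariates.

Identifiability note: in the PGA model the tiny intercept
($\alpha_1 = 0.009$) and the huge modified-MCS coefficient
($\theta = 130$) are individually poorly determined — the likelihood is
nearly flat along their product, consistent with the large reported
uncertainties — while the implied cut-point logits are well determined.
Recovery checks therefore target the RB+SF, ENDO and dropout parameters.

Stepwise covariate modeling (`scm_select()`) adds candidate factors on
$\alpha_1$ greedily while the OFV ($-2\log L$) drops by more than 3.84
($\chi^2_1$, $p<0.05$) and then removes them unless deletion costs more
than 10.8 ($p<0.001$); both thresholds live in the configuration.

## Simulation, dropout and VPCs

`simulate_trial()` simulates every subject on the complete planned-visit
grid, then applies dropout and replaces observations strictly after the
dropout day with sentinel (`-99`) imputed rows at the planned visits, so
that a visual predictive check can censor replicates exactly as the
observed data were censored.  Sentinel rows are excluded from every
summary.  Maintenance dropout is a discrete per-scheduled-visit hazard —
the dropout model is a visit-level logistic regression, not a
continuous-time model — using the same-visit (else most recent) RB+SF.

Categorical VPCs (`categorical_vpc()`, default 500 replicates) bin by
nominal visit week and show, per category, the proportion of remaining
patients relative to everyone enrolled in the phase: the full cohort for
induction bins, and for maintenance bins the subjects of
maintenance-capable trials who did not drop at the end of induction.
Proportions across ENDO/PGA and dropout panels need not sum to one
because the endpoints differ in time resolution.  The continuous VPC of
the modified MCS summarizes the median and outer percentiles among
patients remaining in the trial, starting at the first post-baseline
endoscopy window.

## Problem sizes and numerical choices in the test suite

The suite fits the full 755-subject five-trial design over five seeds
for the recovery check (~45 s per seed), uses a 5,000+-subject cohort
for the rank-correlation check, 500 replicates of a 200-subject design
for VPC self-calibration, $10^4$ randomized draws for the
simplex/monotonicity property suites, and 20 seeded runs of the stepwise
engine on 150-subject induction-only datasets (Laplace approximation for
speed).  These sizes were chosen to keep Monte-Carlo error well inside
the asserted tolerances.

## Known limitations

* The model is built for moderate-to-severe baseline disease (MCS 6-12,
  ENDO >= 2); nothing constrains predictions for milder populations.
* No Markov/serial-correlation terms: the model targets population-level
  summaries, not individual forecasting.
* No drug effect, PK linkage, or treatment-arm mechanics; the dropout
  model is a single reduced-form logistic per phase.
* The exact per-study visit calendars and the baseline joint
  distribution beyond the printed marginals and MCS dispersion are
  assumptions of the emulation.
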