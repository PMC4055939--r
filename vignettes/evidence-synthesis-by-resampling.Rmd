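---
title: "Incorporating external evidence into bootstrap CEAs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Incorporating external evidence into bootstrap CEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceaboot)
```

## The model

A parallel-arm trial yields, per patient, a total cost, an effectiveness
outcome (QALYs), and a count of clinical events (e.g. COPD exacerbations)
over a fixed follow-up window. The CEA targets the posterior of the
arm-level mean costs and effects, and reports the ICER
$\Delta C / \Delta E$, credible intervals, the cost-effectiveness plane
and the CEAC.

The no-evidence posterior $P(\theta\mid D)$ is sampled nonparametrically:
within each arm, a probability vector over that arm's patients is drawn —
$\mathrm{Dirichlet}(1,\dots,1)$ for the Bayesian bootstrap, scaled
multinomial counts for the ordinary bootstrap — and the weighted arm
means constitute one posterior draw $\theta^*$. The two schemes are used
interchangeably; the suite verifies empirically that their posterior
means agree within Monte-Carlo error.

External evidence about an evidence parameter $\theta_e$ — here the log
rate ratio of events between the comparison arms, with
$\mathrm{rate}(a) = \sum_i w_i e_i / \sum_i w_i t_i$ over arm $a$ (events
$e_i$, follow-up $t_i$) — enters through

$$P(\theta \mid D, D_e) \propto P(\theta \mid D)\, P(D_e \mid \theta_e),$$

valid when the external data are independent of the trial, the weight
function is continuous and bounded, and $\theta_e$ is identified in every
resample. The package enforces boundedness by construction: the normal
likelihood is used as the kernel $\exp(-(\theta_e-\mu)^2/2\sigma^2)$,
i.e. scaled by its maximum so weights are valid acceptance probabilities.
Mixed-type ("lump-and-smear") priors have unbounded density and cannot
be registered; `custom_evidence()` probes any user-supplied weight
function on a grid and rejects values outside $[0,1]$.

Two converters are provided. **Rejection sampling** accepts each
replicate with probability $P^* = P(D_e\mid\theta_e^*)$ and runs until
$M$ acceptances; the output is an unweighted posterior sample.
**Importance sampling** keeps all $M$ replicates and weights every
downstream summary by $P^*$; the ICER becomes the ratio of the weighted
mean $\Delta C$ over the weighted mean $\Delta E$. Both engines execute
the same per-replicate recipe — draw weights, impute missing values
under those weights, compute arm means and $\theta_e^*$ — inside a
deterministic RNG substream per replicate index, so runs sharing a
master seed share the identical replicate stream. That common-random-
numbers design is what makes the scheme-equivalence checks sharp, and it
mirrors how the two engines are meant to be compared: the importance run
reuses the rejection run's bootstrap stream, accepted and rejected alike.

## Parameters that matter

* `M` (draws): posterior sample size; 10,000 is the reference run size.
  Monte-Carlo SEs of reported means scale as $M^{-1/2}$ (through the
  effective sample size for importance runs).
* `max_attempts` (rejection; default $100M$): converts prior–data
  conflict from a hang into an error carrying the running acceptance
  rate. Low acceptance rate / low ESS is the operational signature of
  conflict, and results under conflict deserve suspicion regardless.
* Evidence `mu`, `sigma` (log-ratio scale): from `pool_evidence()`. The
  between-study variance $\tau^2$ (default 0) widens `sigma` to
  acknowledge cross-setting transfer; with the worked inputs
  (RR 0.38, CI 0.25–0.57, $\tau^2 = 0.01783$) it yields
  $\mu=-0.968,\ \sigma=0.246$.
* `level` (default 0.95): credible level for interval reporting.
* `lambda_grid` (default 0–500,000 by 5,000, currency per QALY): CEAC
  grid; the default covers the region where acceptability decisions
  plausibly flip in chronic-disease CEAs.

## Numerical and design choices

**CI-to-SE convention.** A published 95% CI can be converted to a
log-scale SE from its upper half-width
($(\ln hi - \ln point)/1.959964$, the default) or its full width
($(\ln hi - \ln lo)/3.92$). The conventions differ when the reported CI
is asymmetric on the log scale (0.246 vs 0.249 for the worked inputs);
the choice is recorded in the evidence object's provenance. A related
wrinkle: a pooled statement of "RR 0.38 (0.24–0.59)" is not exactly
$\exp(\mu \pm 1.96\sigma)$ for the worked $\mu,\sigma$; the package
treats the stated $\mu$ and $\sigma$ as authoritative and keeps the raw
inputs in provenance.

**Ratio of means, not mean of ratios.** Per-draw ICERs are never
averaged: draw-level $\Delta E$ can pass through zero, making the ratio
unstable. The ICER is $\bar{\Delta C}/\bar{\Delta E}$ on the
(normalized-weight) posterior means, and is reported as undefined, with
numerator and denominator, when $\bar{\Delta E}=0$. Negative-$\Delta E$
draws are retained everywhere; the CEAC, not the ICER's sign, carries
the decision meaning.

**Weighted percentiles.** Credible intervals use the step inverse of the
weighted empirical CDF (the weighted analogue of `quantile(type = 1)`):
the smallest value at which cumulative weight reaches $q$. With uniform
weights this reproduces the unweighted type-1 quantile exactly, which is
what the equivalence test asserts.

**Zero-event replicates.** If a resample gives either comparison arm a
zero weighted event total, $\log RR$ is undefined. Such replicates get
weight 0 (always rejected / zero importance weight) and are counted in
diagnostics (`n_invalid_theta`); no continuity correction is applied, so
the estimator is untouched in the common case and the issue is surfaced
rather than hidden.

**Imputation.** Missing costs, QALYs or event counts are imputed *inside
each replicate*, after the replicate's weights are drawn, so imputation
uncertainty propagates into the posterior spread. Two methods:
`weighted_arm_mean` (default) replaces a missing cell with the
bootstrap-weighted mean of observed same-arm values (events rounded);
`hot_deck` draws an observed same-arm donor with probability
proportional to bootstrap weight. Both are deliberately within-arm and
non-parametric; no method with between-imputation variance bookkeeping
is attempted, and the real trial that motivated this design did not
document its imputation procedure, so these are reasoned stand-ins, not
reconstructions. In the corner case where a replicate's bootstrap mass
falls entirely on missing rows, the imputation falls back to equal
weights over the observed values.

**Multi-arm trials.** All arms are bootstrapped every replicate; the
evidence weight is computed only on the designated comparison pair, so a
three-arm trial can carry evidence about one contrast.

## The synthetic world

`synth_trial_spec()` defaults describe the stated world used throughout
the tests, chosen once: three arms sized 156/148/145 over 52 weeks;
annual exacerbation rates 1.8 / 1.75 / 1.1 (the comparison arm T3 is the
effective, costlier combination therapy — observed RR vs T1 about 0.61);
heavily right-skewed gamma base costs (shape 0.5; means 2000/2900/3500)
plus 450 per exacerbation; QALYs $0.74 - 0.03 \times \text{events} +
N(0, 0.075^2)$, clamped to the attainable $[0, \text{followup}/52]$.
This induces the dependence structure the method exploits — costs rise
and QALYs fall with events — so evidence favoring T3's event reduction
(pooled RR 0.38) pulls $\theta_e$ down, upweights replicates where T3
looks better on *both* dimensions, and lowers the ICER and the CEAC
crossing: a signed, testable analogue of the motivating finding. Event
rates near 1–2 per year, four-figure annual costs with occasional
high-cost outliers, and utility decrements of a few hundredths per
exacerbation are all realistic magnitudes for moderate-to-severe COPD.

What the generator does *not* emulate: covariate-driven heterogeneity,
informative missingness (only MCAR masks are generated), censoring,
correlated cost components, or the real trial's unit costs and utility
instrument. A green suite therefore establishes that the machinery is
correct under the stated world, not that any real-data result is
reproduced; the motivating study's patient-level data are not public,
and its table values are deliberately not targets.

## Validation design

Two oracles are independent of the sampling engines:

* `conjugate_posterior()` — when the bootstrap distribution of
  $\theta_e^*$ is approximately normal (large arms), the evidence-
  weighted posterior has the closed normal–normal form
  (precision-weighted mean, summed precisions). The suite estimates
  `data_mean`/`data_se` from an unweighted run and requires the
  importance-weighted mean (within 3 combined MC SEs) and SD (within 10%
  relative) to match. The oracle evidence $N(-0.7, 0.1)$ was picked, in
  advance, to make the shift large against Monte-Carlo noise while
  keeping the ESS healthy.
* `enumerate_ordinary_bootstrap()` — for $\le 8$ patients the ordinary
  bootstrap's weight vectors are finite; the exact evidence-weighted
  expectation of any statistic is a sum over all per-arm multinomial
  count vectors. The suite compares a 200,000-draw importance run
  against the exact values within 3 MC SEs.

The scheme-equivalence criterion uses a milder evidence spec
(RR 0.70, CI 0.50–0.98, $\tau^2=0.01783$) than the headline one: with
the full-strength evidence the rejection sampler's acceptance rate
against this synthetic trial drops to a few percent — exactly the
prior–data-conflict regime the method itself warns about — which would
burn the runtime budget without sharpening the check. The directional
criterion does use the full-strength evidence, with the importance
engine.

## Known limitations

* Single evidence parameter only; with several simultaneous evidence
  parameters the acceptance rate/ESS degrades quickly, and the package
  deliberately does not offer it.
* Prior–data conflict is diagnosed, not resolved: the engines refuse
  (rejection) or warn through ESS (importance), but no robustified
  synthesis is attempted.
* Cluster and crossover designs, censored costs, and parametric (MCMC)
  synthesis are out of scope.
* The ordinary bootstrap is an approximation to the Bayesian bootstrap,
  not formal Bayesian inference; the package treats agreement between
  the two as an empirical check, not a theorem.
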