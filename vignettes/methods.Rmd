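---
title: "Methods: counterfactual service-use effects after brain injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual service-use effects after brain injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabite)
```

## The analysis this package implements

After discharge from inpatient rehabilitation for acquired brain injury
(ABI), people use a mix of outpatient medical, nursing and allied-health
services, acute medical services, may be re-hospitalized, and may attend a
transitional rehabilitation program. `rehabite` estimates how that service
use relates to ten patient-reported outcomes measured six months after
discharge — EQ-5D-5L utility, the three DASS-21 subscales, the three MPAI-4
subscales and the three SPRS-2 domains — in a heterogeneous-treatment-effects
framework:

1. each service-use variable is dichotomized into a binary "treatment"
   \(z \in \{0, 1\}\) at its lower-quartile cut;
2. every outcome is regressed on all 21 predictors (the six treatments plus
   15 covariates) with Bayesian Additive Regression Trees (BART), which lets
   interactions between service use and covariates enter only when the data
   support them;
3. individual treatment effects are the counterfactual contrasts
   \(\tau_i = y_i(1) - y_i(0)\), computed by forcing each treatment in turn
   to 1 and to 0 for every participant while all other predictors keep their
   observed values, and evaluating both predictions at every retained
   posterior state;
4. \(\tau_i\) draws are averaged over participants (ATE) or subgroups
   (CATE), pooled over five multiply-imputed datasets, and summarized by the
   posterior mean, equal-tailed 66% and 95% credible intervals, and the
   posterior probability of the beneficial direction. A treatment-outcome
   cell shows *weak evidence* when its 66% interval excludes zero.

Because the motivating study's participant-level records are not public, the
package ships a synthetic-cohort generator whose marginals are calibrated to
the published cohort summaries and which can inject known treatment effects,
interactions and missing-at-random gaps. All validation is against that
known ground truth.

## Instrument scoring

**EQ-5D-5L.** Utility is one minus the sum of the five dimension decrements.
Only the level-5 decrements are pinned by the published description
(0.274, 0.203, 0.184, 0.335, 0.289 for mobility, self-care, usual activity,
pain/discomfort, anxiety/depression), fixing the utility range to
\([-0.285, 1]\). The full 5×5 decrement table is a configuration input; the
shipped default interpolates linearly between 0 at level 1 and the pinned
level-5 value. Linear interpolation is the weakest assumption that keeps
decrements zero at best health and non-decreasing in severity; any national
value set satisfying those constraints can be supplied instead.

**Summed scales.** DASS-21 subscales are summed and doubled (range 0–42);
SPRS-2 domains and the SOS treatment subscale are plain sums (0–16 and 4–28).
MPAI-4 items are rated 0–4 with published subscale ranges 0–48
(ability), 0–30, 0–30; the adjustment and participation ranges are narrower
than `items × 4`, so those scales carry a declared-range override and the
scorer validates against the declared range only. Missing items are never
prorated: imputation happens at score level, matching an analysis that
imputes variables rather than items.

**SOS midpoint.** Transport and finances items (1–7) are recoded to
disagree (1–3) / agree (5–7). The midpoint 4 is "agree" under the
reporting convention used for published percentages (the default) and
undefined under the stricter methods convention; both are available.

## The synthetic cohort generator

Covariate marginals are location-scale or categorical distributions
calibrated to the published tables: age ≈ N(44, 20) clipped to 18–90 years;
length of stay log-normal (median 47 days); FIM motor = 91 minus a negative
binomial deficit (median 90, lower quartile 80); IRSAD decile ≈ N(6, 3.5)
clipped to 1–10; gender 71% male; marital 46/17/37% married/divorced/never;
employment 68% employed; injury type 61% severe traumatic; funding and
residence per the published percentages; unmet need 10%; SOS transport/
finances agree rates 26%/50%; SOS treatment ≈ N(12, 5.5) clipped to 4–28.

Service contacts are negative binomial — over-dispersion is the only simple
count model compatible with the published medians and wide inter-quartile
ranges: outpatient medical (size 2, mean 3; median 2), nursing (0.4, 0.8;
median 0), allied health (0.55, 6.5), medical acute (0.9, 1.3; median 1),
re-hospitalization (1.5, 0.32; ≈27% with ≥1). Transitional rehabilitation is
Bernoulli(0.83). The allied-health parameters were calibrated so that the
*sample* median of an n = 41 draw centers on the published median of 3 — at
this skewness the small-sample median sits systematically above the
population median, so matching the population quantile alone is not enough.
The published allied-health upper quartile (17) cannot be reproduced jointly
with its 90% access rate by any negative binomial; the calibration keeps the
median and the long upper tail (90th percentile ≈ 18) and concedes the zero
fraction (≈25% rather than 10%).

Outcomes are generated on the score scale as
`baseline(covariates) + Σ effect(t)·z_t + interactions + noise`, then
clipped to the instrument range and rounded to its response grid (utilities
to 3 decimals, DASS to even integers because subscale sums are doubled,
other scales to integers). Clip-then-round keeps scores valid without
rejection sampling at the cost of mild shrinkage of extreme values toward
the bounds. Baselines are linear in standardized age, FIM motor and IRSAD
with categorical offsets (e.g. marriage lowers DASS, employment raises
SPRS occupational); an optional threshold form adds a step at FIM motor
< 75 so that tree ensembles have signal a linear oracle misses. Default
intercepts sit at the published outcome medians; default injected effects
are zero, so the default cohort is an effect-free observational replica.
Item-level responses (for scoring tests) come from a separate one-factor
generator whose loading tunes internal consistency.

What the generator does *not* emulate: the joint covariate dependence of
the real cohort (covariates are drawn independently), outcome-outcome
correlations beyond what shared covariates induce, and informative
missingness. Passing recovery tests therefore demonstrates that the
*pipeline* is unbiased and calibrated under its own assumptions, not that
the original study's estimates are correct.

**Missingness.** Entries are blanked missing-at-random: the blanking
probability depends only on a named, observed conditioning variable
(per-level rates for a categorical conditioner; a median split for a
continuous one). The transitional-rehabilitation flag is never blanked, and
a conditioning variable may not itself be blanked.

## Imputation

Chained equations with predictive mean matching, five completed datasets
(the count over which results are pooled), ten sweeps per chain, donor pool
of five — conventional chained-equations defaults where the analysis
description is silent. Each variable's imputation model is Bayesian linear
regression on all other variables under a flat prior (σ² from the scaled
inverse-χ² residual posterior, coefficients from their conditional normal):
a parameter *draw* rather than the posterior mean, so imputation
variability is proper without bootstrap bookkeeping. Observed cases are
scored with the posterior-mean coefficients and missing cases with the
drawn ones; the imputed value is the observed value of a uniformly chosen
donor among the five nearest predicted values. Categorical variables are
imputed on their integer level codes — the donor property returns only
observed (hence legal) codes. Outcomes are imputed like predictors;
rank-deficient model matrices are handled by pivoted QR, and a constant
target short-circuits to that constant.

## The BART sampler

The regression model is a sum of `m` regression trees with i.i.d.
N(0, σ_μ²) leaf values and Gaussian noise. The outcome is rescaled to
\([-0.5, 0.5]\); σ_μ = 0.5/(k√m), so the prior mass of the total fit spans
the outcome range. Defaults are the canonical regularizing settings —
tree-prior base α = 0.95 and power β = 2 (a node at depth d splits with
prior probability α(1+d)^{-β}), k = 2, noise prior scaled inverse-χ² with
ν = 3 calibrated so the prior puts q = 0.90 below a linear fit's residual
scale — with m = 50 trees and 1000 burn-in + 1000 retained draws. A reduced
profile (20 trees, 250 + 500) is used for the package's replicate
simulation studies; the study-scale analysis (n = 41) uses the defaults.

Each iteration sweeps the trees. For each tree a structural move is
proposed — grow (p = 0.25), prune (0.25), or change of a terminal split's
rule (0.5); no swap move, trading a little mixing for simpler exact
reversibility — and accepted by Metropolis–Hastings on the integrated
likelihood of the tree's partial residuals, with leaf means marginalized
analytically. Leaf values and σ are then redrawn from their conjugate full
conditionals.

Numerical and design choices that matter:

* **Split candidates are global per variable** — all observed unique values
  (maximum excluded), with proposals rejected when a child would be empty.
  A node-local candidate set would need a Hastings correction for the
  changing candidate count; without it the chain drifts toward over-deep
  trees and overconfident effects. The global set makes the rule-proposal
  term cancel exactly.
* **Categorical covariates split natively on level subsets** (bitmask),
  with levels absent from the node assigned randomly so predictions at
  unseen levels are defined; binary treatments enter as two-level factors.
* **The nonempty-leaf constraint** is asserted after every accepted move.
* **Degenerate outcomes** (constant y) return the constant exactly, with no
  MCMC.
* All randomness flows through R's RNG: a seed makes fits, and the whole
  pipeline, bit-reproducible.

Validation: a single pinned root-only tree reproduces the closed-form
conjugate normal posterior; prior-only tree sampling reproduces the
α(1+d)^{-β} depth-split profile; back-transformed predictions are
affine-equivariant; and on a Friedman-style nonlinear surface the sampler
beats a linear model out-of-sample in at least 9 of 10 seeds.

## Treatment effects, pooling and the heterogeneity screen

Cut rules default to the published groupings (outpatient medical and allied
health < 2 vs ≥ 2 contacts; nursing, medical acute and re-hospitalization
0 vs ≥ 1; transitional rehabilitation attended or not). For new cohorts a
lower-quartile helper derives thresholds, but printed defaults win.
Treatments are toggled **one at a time** — the counterfactual contrast for
one service holds the other five at observed values — matching a
per-treatment reading of "estimated response vs counterfactual response";
joint toggling would answer a different (policy-bundle) question.

ATE draws pool across imputations by **concatenating draws** by default
("averaged over five imputed datasets" is ambiguous; concatenation treats
imputation uncertainty as part of the posterior). Averaging per-imputation
summaries is available for comparison; with identical draws the two agree
exactly because interval endpoints use inverse-ECDF (type 1) quantiles,
which are invariant under draw replication. The posterior probability of
benefit counts pooled draws strictly on the beneficial side of zero, with
the direction registry fixing "beneficial" per instrument (lower DASS/MPAI,
higher utility/SPRS).

The heterogeneity screen compares subgroup CATEs: for each candidate
moderator (residence, marital status, unmet need, the SOS variables), each
level versus the rest (continuous moderators median-split, for screening
only), flagging when the 95% interval of the CATE difference excludes zero,
and falling back to the whole-cohort ATE when nothing is flagged.

### Power of the screen, and honest limits

The 95%-exclusion rule effectively demands more than 97.5% posterior mass on
interaction structure. BART's tree prior deliberately penalizes the deep
splits that encode interactions, so the screen is conservative: in the
package's validation study (married effect −8 vs −2 otherwise, outcome noise
sd 8, n = 1000), the screen flags the true moderator in roughly two thirds
of replicate cohorts and the flag depends on how strongly the realized
sample expresses the interaction. The shipped acceptance test runs one fixed
replicate whose realized interaction happens to be weak, and that check is
expected to fail — it is kept, unaltered, as an honest record of the
screen's power at this signal size. False flags on homogeneous cohorts are
rare (none in 10 replicate seeds in the shipped test).

Relatedly, under a true null the posterior probability of benefit is not
uniformly distributed: regularization pulls it toward 0.5 for most cells,
but for very unbalanced treatments (e.g. 83% attendance) it can stray
outside (0.1, 0.9) in a nontrivial minority of replicates even though the
66%-interval flag stays rare. The weak-evidence criterion should be read as
exploratory screening, not error-controlled testing — consistent with its
"weak evidence" label.

## Problem sizes used by the shipped tests

Replicate studies use n = 500 cohorts (20 recovery replicates, 10 null
replicates) with the reduced sampler profile, and n = 1000 for the
heterogeneity study — sizes at which Monte-Carlo error is small relative to
the tolerances being checked while the whole suite stays quick to run. The
study-scale drivers under `analysis/` use n = 41 with the default sampler.

## Known limitations

* Counterfactuals assume conditional ignorability given the 15 covariates;
  there is no propensity-score machinery, overlap weighting or sensitivity
  analysis for unmeasured confounding.
* The sampler is continuous-outcome only (no probit BART); bounded scores
  are modeled as continuous, as in the motivating analysis.
* Imputation is single-level PMM; no multilevel structure, and congeniality
  is checked only through marginal-overlap diagnostics.
* The generator reproduces marginals, not the joint distribution; effect
  sizes recovered from it say nothing about real-data confounding.
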