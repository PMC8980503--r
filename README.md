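# rehabite

Counterfactual treatment-effect analysis of post-discharge health-service
use after acquired brain injury (ABI).

## The problem

After discharge from inpatient brain-injury rehabilitation, people draw on
outpatient medical, nursing and allied-health services, acute medical care,
sometimes re-hospitalization, and transitional rehabilitation programs.
Whether that service use relates to better quality of life, psychological
wellbeing, global function and participation — and whether personal factors
such as marital status, place of residence, unmet need or service obstacles
moderate the relationship — is an open question in rehabilitation health
services research. `rehabite` is for biostatisticians and rehabilitation
researchers who want to run (or stress-test) that analysis end to end:
instrument scoring, multiple imputation, flexible outcome regression, and
counterfactual effect estimation, with a synthetic-cohort generator that
provides known ground truth.

## The method

Service-use variables are dichotomized at lower-quartile cuts into binary
treatments *z*. Each of ten outcomes (EQ-5D-5L utility; DASS-21 depression,
anxiety, stress; MPAI-4 ability, adjustment, participation; SPRS-2
occupational, interpersonal, independent living) is modeled with Bayesian
Additive Regression Trees:

    y_i = sum_{j=1}^{m} g(x_i; T_j, M_j) + e_i,   e_i ~ N(0, sigma^2)

a sum of m regularized regression trees sampled by backfitting MCMC
(grow/prune/change Metropolis–Hastings on the integrated likelihood, node
depth-d split prior alpha (1+d)^-beta, conjugate leaf and sigma updates).
Individual treatment effects are counterfactual contrasts per participant
and posterior state,

    tau_i = y_i(1) - y_i(0),

obtained by forcing each treatment to 1 and to 0 while all other covariates
keep their observed values. Averaging tau_i over participants gives the ATE,
over subgroups the CATE; draws are pooled across five PMM-imputed datasets
and summarized by posterior means, equal-tailed 66% and 95% credible
intervals and the posterior probability of the beneficial direction. A
treatment-outcome pair shows *weak evidence* when its 66% interval excludes
zero; a moderator is flagged for heterogeneity when the 95% interval of a
subgroup CATE difference excludes zero.

The BART sampler is implemented from scratch in C++ (via Rcpp); imputation
is chained equations with predictive-mean-matching draws, also implemented
in the package.

## Worked example

Simulate a cohort with a known injected effect (transitional rehabilitation
lowers DASS-21 depression by 5 points) and run the pipeline:

```r
library(rehabite)

spec <- cohort_spec(n = 300, seed = 42,
                    true_effects = list(trans_rehab = c(dass_depression = -5)),
                    baseline_intercepts = c(dass_depression = 20))
cohort <- generate_cohort(spec)

cfg <- run_config(cohort, outcomes = "dass_depression",
                  treatments = c("trans_rehab", "medical_acute"),
                  bart = bart_fast_profile(),
                  imputation = imputation_config(m_datasets = 1), seed = 1)
res <- run_analysis(cfg)
print(res)
```

```
rehabite analysis: 300 participants, 1 outcome(s) x 2 treatment(s), 1 completed dataset(s)

     treatment         outcome ate_mean   lo66    hi66  lo95   hi95
   trans_rehab dass_depression   -5.250 -6.420 -4.0700 -7.69 -3.030
 medical_acute dass_depression   -0.195 -0.704  0.0459 -1.62  0.856
 prob_beneficial evidence       direction
           1.000     TRUE lower_is_better
           0.352    FALSE lower_is_better

heterogeneity screen: 0 flagged contrast(s)
```

The injected −5-point effect is recovered (posterior mean −5.25, 95% CI
[−7.69, −3.03], weak-evidence flag set, posterior probability of lower
depression 1.00), while the null treatment in the same model shows no
evidence (interval straddles zero, probability 0.35). Scoring works
standalone too:

```r
score_eq5d(c(1, 1, 1, 1, 1))   # 1      (best health)
score_eq5d(c(5, 5, 5, 5, 5))   # -0.285 (worst health)
```

## The analysis workflow

Numbered drivers under `analysis/` reproduce the study shape on a simulated
41-participant cohort and write their tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_cohort.R` | simulate the study-scale cohort with MAR gaps |
| `02_score_instruments.R` | scoring + Cronbach's alpha on item-level fixtures |
| `03_impute.R` | chained PMM imputation, five completed datasets |
| `04_fit_effects.R` | 10 outcomes x 6 treatments effect table + heterogeneity screen |
| `05_recovery_study.R` | known-truth recovery and null-calibration replicates |

Run them in order with `Rscript analysis/01_simulate_cohort.R`, etc.

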