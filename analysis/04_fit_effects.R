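#!/usr/bin/env Rscript
# The main analysis: one BART model per outcome and completed dataset (all 21
# predictors), counterfactual individual treatment effects for each of the
# six discretized service-use treatments, ATE posteriors pooled over the five
# imputations, 66%/95% credible intervals, posterior probabilities of the
# beneficial direction, and the heterogeneity screen over personal factors,
# unmet need and service obstacles.  Writes results/study/.

suppressPackageStartupMessages(library(rehabite))

cfg <- run_config(
  cohort = "results/cohort.csv",
  bart = bart_config(n_trees = 50, n_burn = 500, n_draws = 500),
  imputation = imputation_config(m_datasets = 5, seed = 20260931),
  out_dir = "results/study", seed = 20260932)

res <- run_analysis(cfg)
print(res)

flagged <- res$effects[res$effects$evidence, c("treatment", "outcome",
                                               "ate_mean", "prob_beneficial")]
cat("\ncells with weak evidence (66% credible interval excluding zero):\n")
if (nrow(flagged)) print(as.data.frame(flagged), row.names = FALSE) else
  cat("  none - consistent with a cohort generated without injected effects\n")
cat("\ntables written under results/study/\n")
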