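#!/usr/bin/env Rscript
# Step 3: environmental prediction of limitation status.
#
# Imputes the covariate table by predictive mean matching, fits a tuned
# random-forest presence/absence model for Fe limitation (80/20 stratified
# split, grid over mtry x maxnodes x ntree, no-information-rate gate), and
# for the well-performing model extracts partial-dependence curves and
# their detected thresholds. Finishes by screening the cohort against the
# recovered DRP/N_DEP rule.
#
# Reads results/sim/ and results/classify/; writes results/predict/.

suppressMessages(library(colimstat))

reports <- run_predict("results/classify/element_presence.csv",
                       "results/sim/covariates.csv",
                       out_dir = "results/predict", elements = "Fe",
                       seed = 1L)
rep_fe <- reports$Fe
print(rep_fe)

if (rep_fe$well_performing) {
  for (feat in utils::head(rep_fe$importance$variable, 2)) {
    thr <- detect_threshold(partial_dependence(rep_fe, feat))
    cat(sprintf("%s threshold: %.2f (%s)\n", feat, thr$threshold,
                thr$direction))
  }
}

cov <- read_covariates("results/sim/covariates.csv")
wide <- covariates_wide(impute_pmm(cov, seed = 1L))
presence <- read.csv("results/classify/element_presence.csv",
                     stringsAsFactors = FALSE)
scr <- screen_by_thresholds(wide, fe_rule(),
                            labels = setNames(presence$Fe == 1,
                                              presence$stream_id))
cat("streams with DRP > 5.6 and N_DEP < 3.6:", scr$n, "\n")
print(scr$crosstab)
cat("outputs under results/predict/\n")
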