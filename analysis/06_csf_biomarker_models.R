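#!/usr/bin/env Rscript
# Stage 6 -- CSF biomarker models.
#
# For each retained LV, takes the brain score of its driving condition
# (largest condition contribution) and regresses it on each CSF biomarker
# analog (pTau181, A-beta-42) with sex and years of education as covariates
# (age was already residualized out of the maps). Biomarker p-values are
# Bonferroni-corrected for the two tests per score; the CSF-to-MRI delay is
# screened as a single interaction term and kept only if it lowers the AIC.

library(idcwm)

truth <- readRDS("results/phantom.rds")
pls <- readRDS("results/pls.rds")
tab <- generate_subject_table(truth)

rows <- list()
for (l in seq_len(pls$decomposition$n_keep)) {
  cond <- rownames(pls$contributions)[which.max(pls$contributions[, l])]
  score <- pls$brain_scores[, cond, l]
  for (bm in c("ptau181", "ab42")) {
    fit <- brainscore_biomarker_regression(score, tab[[bm]], tab$sex,
                                           tab$education_years, m = 2)
    inter <- interaction_aic_check(score, tab[[bm]], tab$sex,
                                   tab$education_years, tab$csf_mri_delay_days)
    rows[[paste(l, bm)]] <- data.frame(
      lv = l, condition = cond, biomarker = bm,
      beta = round(fit$beta, 3), t = round(fit$t, 2),
      p = signif(fit$p, 3), p_adj = signif(fit$p_adj, 3),
      aic_base = round(inter$aic_base, 1),
      aic_interaction = round(inter$aic_interaction, 1),
      interaction_kept = inter$keep)
  }
}
models <- do.call(rbind, c(rows, make.row.names = FALSE))
write.table(models, "results/biomarker_models.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(models, row.names = FALSE)

# partial correlations of IdC metrics with the biomarker analogs,
# controlling for age, sex and education
pc_rows <- lapply(colnames(truth$behavior)[1:8], function(m) {
  pc <- partial_correlation(truth$behavior[, m], tab$ptau181,
                            cbind(tab$age, tab$sex, tab$education_years))
  data.frame(metric = m, r = round(pc$r, 3), t = round(pc$t, 2),
             p = signif(pc$p, 3))
})
pc_tab <- do.call(rbind, pc_rows)
write.table(pc_tab, "results/idc_ptau_partial_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Outputs: results/biomarker_models.tsv, results/idc_ptau_partial_correlations.tsv\n")
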