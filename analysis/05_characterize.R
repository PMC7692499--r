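#!/usr/bin/env Rscript
# Downstream characterization of the discovered subtypes: mutation
# enrichment (one-vs-rest chi-squared + BH), survival stratification
# (KM / log-rank / Cox), tumor purity by group, and concordance of the
# consensus classes with the generating truth.

source("analysis/common.R")

co <- study_cohort()
dbu <- study_dbu(co)

enr <- mutation_enrichment(co$mutations, dbu$consensus)
top <- enr[enr$p_adj < 0.05, ]
message(sprintf("mutation enrichment: %d significant gene-group pairs (BH < 0.05)",
                nrow(top)))
save_tsv(enr, "mutation_enrichment.tsv")

surv <- km_logrank(co$clinical, dbu$consensus)
print(surv)
save_tsv(surv$km, "km_curves.tsv")
save_tsv(surv$hazard_ratios, "hazard_ratios.tsv")

pur <- purity_by_group(co$purity, dbu$consensus)
print(pur$summary, digits = 3)
message(sprintf("purity ANOVA p = %.3g", pur$anova_p))
save_tsv(pur$summary, "purity_by_group.tsv")

conc <- concordance(dbu$consensus, co$true_subtype)
print(conc)
save_tsv(data.frame(conc$table), "concordance.tsv")
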