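#!/usr/bin/env Rscript
# Gene-signature construction and the ensemble model-gene dictionary:
# one-vs-rest DE, curated-gene injection, six expression-pattern groups,
# then 200 dictionary entries by per-group half-sampling + RFE, filtered at
# the 95% cross-validated accuracy floor.

source("analysis/common.R")

co <- study_cohort()
dbu <- study_dbu(co)

# curated list: ten informative genes, standing in for the analyst-supplied
# brain-cancer genes of a real study
curated <- co$informative_gene_ids[1:10]
sig <- build_signature(co$expression, dbu$consensus, curated_genes = curated,
                       seed = 3)
print(sig)
message("pattern group sizes: ",
        paste(table(sig$group_assignment), collapse = ", "))

dic <- build_model_dictionary(co$expression, dbu$consensus, sig,
                              n_models = 200L, seed = 4)
print(dic)
filt <- cv_filter_models(dic, co$expression, dbu$consensus, floor = 0.95,
                         seed = 5)
message(sprintf("retained %d/%d entries; mean CV accuracy %.3f",
                length(filt$entries), length(dic$entries),
                mean(filt$cv_accuracy)))

jsonlite::write_json(
  list(gene_ids = sig$gene_ids, curated_gene_ids = sig$curated_gene_ids,
       selected_gene_ids = sig$selected_gene_ids,
       group_assignment = as.list(sig$group_assignment)),
  res_path("signature.json"), digits = NA, auto_unbox = TRUE)
jsonlite::write_json(
  list(entries = filt$entries, cv_accuracy = filt$cv_accuracy),
  res_path("dictionary.json"), digits = NA, auto_unbox = TRUE)
save_tsv(sig$de_table[sig$de_table$p_adj < 0.05, ], "de_significant.tsv")
message("wrote signature.json / dictionary.json")
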