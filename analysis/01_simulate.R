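#!/usr/bin/env Rscript
# Generate the synthetic glioma-like study cohort: 400 samples x 2000 genes,
# four latent transcriptomic subtypes of unequal prevalence, one of which
# shares its tumor profile with another and differs only by tumor-purity
# dilution (median 0.60 vs 0.77); plus mutations, survival and purity.

source("analysis/common.R")

co <- study_cohort()
print(co)

message("subtype counts: ",
        paste(names(table(co$true_subtype)), table(co$true_subtype),
              sep = "=", collapse = ", "))
message("purity medians by subtype: ",
        paste(names(tapply(co$purity, co$true_subtype, median)),
              round(tapply(co$purity, co$true_subtype, median), 2),
              sep = "=", collapse = ", "))

save_tsv(co$clinical, "cohort_clinical.tsv")
save_tsv(data.frame(sample_id = names(co$true_subtype),
                    true_subtype = co$true_subtype,
                    purity = round(co$purity, 4)), "cohort_truth.tsv")
save_tsv(data.frame(gene_id = co$informative_gene_ids),
         "cohort_informative_genes.tsv")

# round-trip check of the expression I/O on a slice of the cohort
slice <- co$expression[1:50, 1:20]
path <- res_path("cohort_expression_head.tsv")
write_expression(slice, path)
stopifnot(max(abs(read_expression(path) - slice)) < 1e-12)
message("expression I/O round-trip exact on a 50x20 slice")
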