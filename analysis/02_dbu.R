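#!/usr/bin/env Rscript
# Unsupervised subtype discovery: 100 iterations of {500 random genes ->
# UMAP -> DBSCAN}, iteration filtering, Hungarian label alignment, and 70%
# plurality consensus with the ambiguity rule.

source("analysis/common.R")

co <- study_cohort()
res <- study_dbu(co)
print(res)

lab <- setNames(res$consensus$calls$consensus_class,
                res$consensus$calls$sample_id)
ok <- lab != "ambiguous"
ari <- adjusted_rand(lab[ok], co$true_subtype[names(lab)[ok]])
message(sprintf("iterations removed: %d; ambiguous samples: %d; ARI vs truth (non-ambiguous): %.3f",
                res$n_removed, sum(!ok), ari))
print(table(consensus = lab, truth = co$true_subtype[names(lab)]))

save_tsv(res$consensus$calls, "dbu_calls.tsv")
save_tsv(data.frame(sample_id = rownames(res$consensus$votes),
                    res$consensus$votes, check.names = FALSE),
         "dbu_votes.tsv")
save_tsv(data.frame(iteration_id = vapply(res$iterations, `[[`, 0L, "iteration_id"),
                    n_clusters = vapply(res$iterations, `[[`, 0L, "n_clusters"),
                    eps_used = vapply(res$iterations, `[[`, 0, "eps_used")),
         "dbu_iteration_log.tsv")
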