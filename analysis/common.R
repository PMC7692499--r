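# Shared study conditions for the analysis scripts. Every script regenerates
# what it needs from these seeds (generation is cheap and deterministic), so
# each script can be run on its own; derived tables land under results/.

library(gliotype)

RESULTS_DIR <- "results"
COHORT_SEED <- 1L

study_cohort <- function() generate_cohort(cohort_config(seed = COHORT_SEED))

# DBU scaled to the 400-sample cohort: min_points ~ a third of a typical
# group, eps fixed from k-NN distance inspection of the embeddings.
study_dbu_params <- function() {
  dbu_params(n_iterations = 100L, genes_per_iteration = 500L,
             min_points = 25L, eps = 1, expected_groups = "auto", seed = 7L)
}

study_dbu <- function(cohort = study_cohort()) {
  run_dbu(cohort$expression, study_dbu_params())
}

res_path <- function(...) {
  dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
  file.path(RESULTS_DIR, ...)
}

save_tsv <- function(df, name) {
  write.table(df, res_path(name), sep = "\t", quote = FALSE,
              row.names = FALSE)
  message("wrote ", res_path(name))
}
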