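# Shared fixtures, built once per test run and cached. Everything is
# generated in code from fixed seeds; the heavy objects (default cohort,
# 100-iteration DBU run, 200-entry dictionary) are reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

default_cohort <- function() {
  cached("cohort", generate_cohort(cohort_config(seed = 1)))
}

# DBU parameters scaled to the 400-sample synthetic cohort: min_points ~ a
# third of a typical group size, eps fixed from k-NN distance inspection.
default_dbu_params <- function(n_iterations = 100L) {
  dbu_params(n_iterations = n_iterations, genes_per_iteration = 500L,
             min_points = 25L, eps = 1, expected_groups = "auto", seed = 7L)
}

default_dbu <- function() {
  cached("dbu", suppressMessages(
    run_dbu(default_cohort()$expression, default_dbu_params())))
}

default_signature <- function() {
  cached("signature", {
    co <- default_cohort()
    suppressMessages(build_signature(
      co$expression, default_dbu()$consensus,
      curated_genes = co$informative_gene_ids[1:10], seed = 3))
  })
}

default_dictionary <- function() {
  cached("dictionary", {
    co <- default_cohort()
    suppressMessages(build_model_dictionary(
      co$expression, default_dbu()$consensus, default_signature(),
      n_models = 200L, seed = 4))
  })
}

default_filtered_dictionary <- function() {
  cached("filtered_dictionary", {
    co <- default_cohort()
    suppressMessages(cv_filter_models(
      default_dictionary(), co$expression, default_dbu()$consensus,
      floor = 0.95, seed = 5))
  })
}

default_crossfit <- function() {
  cached("crossfit", {
    co <- default_cohort()
    crossfit_calls(co$expression, default_dbu()$consensus,
                   default_filtered_dictionary(), seed = 6)
  })
}

# A small standardized expression matrix with two well-separated sample
# groups, for fast clustering tests.
two_blob_expr <- function(n_per = 150L, n_genes = 120L, shift = 4,
                          seed = 42L) {
  set.seed(seed)
  mu <- matrix(0, n_genes, 2L)
  mu[seq_len(n_genes / 2L), 2L] <- shift
  lab <- rep(1:2, each = n_per)
  x <- mu[, lab] + matrix(rnorm(n_genes * 2L * n_per), n_genes)
  dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(2L * n_per)))
  attr(x, "standardized") <- FALSE
  list(expr = standardize(x), labels = lab)
}

# Structured fake DBU iterations: a true 3-group labeling over n samples,
# each iteration a noisy copy (a few samples flipped or set to noise 0),
# with cluster ids randomly permuted per iteration.
fake_iterations <- function(n_iter = 30L, n = 120L, k = 3L, flip = 0.05,
                            noise = 0.05, seed = 123L) {
  set.seed(seed)
  truth <- rep(seq_len(k), length.out = n)
  samples <- sprintf("s%03d", seq_len(n))
  lapply(seq_len(n_iter), function(m) {
    lab <- truth
    nf <- round(flip * n)
    idx <- sample.int(n, nf)
    lab[idx] <- sample(seq_len(k), nf, replace = TRUE)
    lab[sample.int(n, round(noise * n))] <- 0L
    perm <- sample(seq_len(k))
    nz <- lab != 0L
    lab[nz] <- perm[lab[nz]]
    structure(list(iteration_id = m, sampled_gene_ids = character(),
                   labels = setNames(as.integer(lab), samples),
                   n_clusters = k, eps_used = NA_real_),
              class = "dbu_iteration")
  })
}

# Randomly permute each iteration's non-noise cluster ids.
permute_iteration_labels <- function(iterations) {
  lapply(iterations, function(it) {
    k <- max(it$labels)
    perm <- sample(seq_len(k))
    nz <- it$labels != 0L
    it$labels[nz] <- perm[it$labels[nz]]
    it
  })
}
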