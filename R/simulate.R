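#' Configuration for a synthetic glioma-like cohort
#'
#' Defines the generative model used by [generate_cohort()]: a cohort with
#' `n_subtypes` latent transcriptomic subtypes of unequal prevalence, where
#' expression is a purity-weighted mixture of a tumor profile and a shared
#' "normal tissue" profile,
#' \deqn{x = p (\mu_{subtype} + \epsilon_1) + (1 - p)(\nu + \epsilon_2),}
#' with independent unit-variance Gaussian noise on each component, genes
#' standardized afterwards. One designated subtype (`diluted_subtype`)
#' carries the *same* tumor profile as `diluted_profile_source` but a lower
#' tumor-purity distribution, so that only dilution by normal tissue
#' distinguishes it — mimicking a subtype dominated by non-malignant
#' neuronal tissue. Mutations live in a separate gene namespace and are
#' Bernoulli with enriched odds in designated subtypes; survival is
#' exponential with subtype-specific log hazards and uniform administrative
#' censoring calibrated to `censoring_rate`.
#'
#' Each informative gene carries, in every subtype, a tumor-profile mean
#' shift of magnitude `effect_size` with an independent random sign, so any
#' two subtypes differ (in expectation) on about half the informative genes.
#' The normal profile assigns shifts of magnitude `normal_magnitude` to
#' `normal_profile_genes` random genes; non-malignant brain differs from
#' glioma across a large fraction of the transcriptome, which is what makes
#' purity dilution detectable.
#'
#' @param n_samples Cohort size.
#' @param n_genes Number of expression genes.
#' @param n_subtypes Number of latent subtypes (>= 2).
#' @param subtype_prevalence Probability vector of length `n_subtypes`.
#' @param n_informative_genes Number of genes carrying subtype signal.
#' @param effect_size Tumor-profile mean shift for informative genes, in
#'   pre-standardization noise-sd units.
#' @param purity_beta Two-column matrix (shape1, shape2) of Beta parameters,
#'   one row per subtype.
#' @param diluted_subtype Index of the low-purity subtype (its row of
#'   `purity_beta` should be centered lower).
#' @param diluted_profile_source Index of the subtype whose tumor profile the
#'   diluted subtype copies.
#' @param normal_profile_genes,normal_magnitude Extent and size of the
#'   normal-tissue expression program.
#' @param mutation_genes_per_subtype,mutation_enrichment_odds,mutation_baseline_rate,n_mutation_genes
#'   Mutation-matrix model: each subtype gets `mutation_genes_per_subtype`
#'   dedicated genes whose mutation odds are multiplied by
#'   `mutation_enrichment_odds` in that subtype; all other gene/sample cells
#'   mutate at `mutation_baseline_rate`.
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @param subtype_log_hazard Log hazard ratio per subtype (reference scale 0).
#' @param censoring_rate Target marginal probability of censoring in `[0, 1)`.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 400L,
                          n_genes = 2000L,
                          n_subtypes = 4L,
                          subtype_prevalence = c(0.40, 0.25, 0.22, 0.13),
                          n_informative_genes = 200L,
                          effect_size = 2,
                          purity_beta = NULL,
                          diluted_subtype = n_subtypes,
                          diluted_profile_source = 2L,
                          normal_profile_genes = 1500L,
                          normal_magnitude = 6,
                          n_mutation_genes = 60L,
                          mutation_genes_per_subtype = 5L,
                          mutation_enrichment_odds = 6,
                          mutation_baseline_rate = 0.1,
                          baseline_hazard = log(2) / 80,
                          subtype_log_hazard = c(2.4, 0, 0.35, 0),
                          censoring_rate = 0.3,
                          seed = 1L) {
  if (is.null(purity_beta)) {
    # medians ~0.77 for tumor-dominated subtypes, ~0.60 for the diluted one
    purity_beta <- matrix(rep(c(154, 46), each = n_subtypes), ncol = 2)
    purity_beta[diluted_subtype, ] <- c(120, 80)
  }
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_subtypes = as.integer(n_subtypes),
    subtype_prevalence = subtype_prevalence,
    n_informative_genes = as.integer(n_informative_genes),
    effect_size = effect_size, purity_beta = purity_beta,
    diluted_subtype = as.integer(diluted_subtype),
    diluted_profile_source = as.integer(diluted_profile_source),
    normal_profile_genes = as.integer(normal_profile_genes),
    normal_magnitude = normal_magnitude,
    n_mutation_genes = as.integer(n_mutation_genes),
    mutation_genes_per_subtype = as.integer(mutation_genes_per_subtype),
    mutation_enrichment_odds = mutation_enrichment_odds,
    mutation_baseline_rate = mutation_baseline_rate,
    baseline_hazard = baseline_hazard,
    subtype_log_hazard = subtype_log_hazard,
    censoring_rate = censoring_rate,
    seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_subtypes >= 2,
            length(cfg$subtype_prevalence) == cfg$n_subtypes,
            length(cfg$subtype_log_hazard) == cfg$n_subtypes,
            nrow(cfg$purity_beta) == cfg$n_subtypes,
            cfg$effect_size >= 0,
            cfg$baseline_hazard > 0,
            cfg$mutation_enrichment_odds > 0,
            cfg$censoring_rate >= 0, cfg$censoring_rate < 1)
  if (abs(sum(cfg$subtype_prevalence) - 1) > 1e-9) {
    stop("subtype_prevalence must sum to 1")
  }
  if (cfg$n_informative_genes > cfg$n_genes) {
    stop("n_informative_genes exceeds n_genes")
  }
  invisible(cfg)
}

#' Simulate subtype labels and survival only
#'
#' The survival arm of the generative model on its own: subtype labels drawn
#' from the prevalence vector, exponential event times with per-subtype
#' hazard `baseline_hazard * exp(log_hazard[s])`, and independent uniform
#' administrative censoring on `[0, M]` with `M` calibrated so the marginal
#' censoring probability equals `censoring_rate`.
#'
#' @param n Number of samples.
#' @param prevalence Subtype prevalence vector.
#' @param baseline_hazard,subtype_log_hazard,censoring_rate See
#'   [cohort_config()].
#' @param seed Integer seed.
#' @return data.frame with `sample_id`, `subtype`, `survival_time`, `event`.
#' @export
simulate_survival <- function(n, prevalence, baseline_hazard,
                              subtype_log_hazard, censoring_rate, seed) {
  with_seed(seed, {
    s <- sample.int(length(prevalence), n, replace = TRUE, prob = prevalence)
    lambda <- baseline_hazard * exp(subtype_log_hazard[s])
    t_event <- rexp(n, rate = lambda)
    if (censoring_rate > 0) {
      m <- censor_horizon(prevalence, baseline_hazard * exp(subtype_log_hazard),
                          censoring_rate)
      t_cens <- runif(n, 0, m)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(
      sample_id = sprintf("smp_%04d", seq_len(n)),
      subtype = paste0("S", s),
      survival_time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stringsAsFactors = FALSE)
  })
}

# Horizon M of Uniform(0, M) censoring such that the marginal probability of
# censoring equals `rate`. For exponential event times with hazard lambda,
# P(censored | M) = (1 / (lambda M)) (1 - exp(-lambda M)) per subtype.
censor_horizon <- function(prevalence, lambdas, rate) {
  p_cens <- function(m) {
    sum(prevalence * (1 - exp(-lambdas * m)) / (lambdas * m)) - rate
  }
  uniroot(p_cens, lower = 1e-6, upper = 1e8, tol = 1e-10)$root
}

#' Generate a synthetic cohort with known subtype ground truth
#'
#' Draws a full multi-modal cohort from the model described in
#' [cohort_config()]: a standardized expression matrix, clinical table
#' (survival), binary mutation matrix in its own gene namespace, per-sample
#' tumor purity, and the true subtype labels.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (standardized genes x samples), `expression_raw` (pre-standardization),
#'   `clinical`, `mutations`, `purity`, `true_subtype`,
#'   `informative_gene_ids`, `expected_group_means` (raw-scale expected mean
#'   of every gene in every subtype), `tumor_profiles`, `normal_profile`,
#'   and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 4L)

  clinical <- simulate_survival(cfg$n_samples, cfg$subtype_prevalence,
                                cfg$baseline_hazard, cfg$subtype_log_hazard,
                                cfg$censoring_rate, seeds[1L])
  s <- as.integer(sub("^S", "", clinical$subtype))
  samples <- clinical$sample_id
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))

  expr <- with_seed(seeds[2L], {
    informative <- sort(sample.int(cfg$n_genes, cfg$n_informative_genes))
    # tumor profiles: magnitude effect_size, independent random sign per
    # (gene, subtype); the diluted subtype copies its source profile
    delta <- matrix(0, cfg$n_genes, cfg$n_subtypes)
    delta[informative, ] <- cfg$effect_size *
      sample(c(-1, 1), cfg$n_informative_genes * cfg$n_subtypes, replace = TRUE)
    delta[, cfg$diluted_subtype] <- delta[, cfg$diluted_profile_source]
    # shared normal-tissue program
    nu <- numeric(cfg$n_genes)
    normal_idx <- sample.int(cfg$n_genes, cfg$normal_profile_genes)
    nu[normal_idx] <- cfg$normal_magnitude *
      sample(c(-1, 1), cfg$normal_profile_genes, replace = TRUE)
    purity <- rbeta(cfg$n_samples, cfg$purity_beta[s, 1L], cfg$purity_beta[s, 2L])
    purity[cfg$purity_beta[s, 2L] == 0] <- 1  # degenerate Beta: pure tumor
    tumor <- delta[, s, drop = FALSE] +
      matrix(rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes)
    normal <- nu + matrix(rnorm(cfg$n_genes * cfg$n_samples), cfg$n_genes)
    raw <- sweep(tumor, 2L, purity, "*") + sweep(normal, 2L, 1 - purity, "*")
    dimnames(raw) <- list(genes, samples)
    list(raw = raw, delta = delta, nu = nu, purity = purity,
         informative = informative)
  })

  mutations <- with_seed(seeds[3L], {
    mgenes <- sprintf("mg%03d", seq_len(cfg$n_mutation_genes))
    prob <- matrix(cfg$mutation_baseline_rate, cfg$n_mutation_genes, cfg$n_samples)
    base_odds <- cfg$mutation_baseline_rate / (1 - cfg$mutation_baseline_rate)
    enr_odds <- base_odds * cfg$mutation_enrichment_odds
    p_enr <- enr_odds / (1 + enr_odds)
    for (k in seq_len(cfg$n_subtypes)) {
      rows <- (k - 1L) * cfg$mutation_genes_per_subtype +
        seq_len(cfg$mutation_genes_per_subtype)
      if (max(rows) > cfg$n_mutation_genes) {
        stop("n_mutation_genes too small for mutation_genes_per_subtype")
      }
      prob[rows, s == k] <- p_enr
    }
    m <- matrix(rbinom(length(prob), 1L, prob), nrow(prob),
                dimnames = list(mgenes, samples))
    m
  })

  p_mean <- cfg$purity_beta[, 1L] / rowSums(cfg$purity_beta)
  expected <- sweep(expr$delta, 2L, p_mean, "*") +
    outer(expr$nu, 1 - p_mean)
  dimnames(expected) <- list(genes, paste0("S", seq_len(cfg$n_subtypes)))

  raw <- expr$raw
  attr(raw, "standardized") <- FALSE
  out <- list(
    expression = standardize(raw),
    expression_raw = raw,
    clinical = clinical[, c("sample_id", "survival_time", "event")],
    mutations = mutations,
    purity = setNames(expr$purity, samples),
    true_subtype = setNames(clinical$subtype, samples),
    informative_gene_ids = genes[expr$informative],
    expected_group_means = expected,
    tumor_profiles = `dimnames<-`(expr$delta,
                                  list(genes, paste0("S", seq_len(cfg$n_subtypes)))),
    normal_profile = setNames(expr$nu, genes),
    config = cfg)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples x %d genes, %d subtypes (%s)\n",
              ncol(x$expression), nrow(x$expression), x$config$n_subtypes,
              paste(table(x$true_subtype), collapse = "/")))
  invisible(x)
}

#' Degrade an expression matrix to mimic a different measurement platform
#'
#' Emulates cross-platform validation: a random subset of genes is retained
#' (as when a signature is only partly measurable on an older array), each
#' retained gene is passed through a monotone nonlinearity
#' `x + cubic * x^3` plus Gaussian noise, and the result is re-standardized
#' within the new "dataset".
#'
#' @param cohort A `synthetic_cohort` or a standardized expression matrix.
#' @param gene_retention Fraction of genes retained, in `(0, 1]`.
#' @param distortion List with elements `cubic` (>= 0, monotone cubic
#'   coefficient) and `noise_sd` (measurement noise on the standardized
#'   scale).
#' @param seed Integer seed.
#' @return Standardized expression matrix on the retained genes.
#' @export
degrade_to_platform <- function(cohort, gene_retention = 1,
                                distortion = list(cubic = 0.15, noise_sd = 0.3),
                                seed = 1L) {
  expr <- if (inherits(cohort, "synthetic_cohort")) cohort$expression else cohort
  stopifnot(is.matrix(expr), gene_retention > 0, gene_retention <= 1,
            distortion$cubic >= 0, distortion$noise_sd >= 0)
  with_seed(seed, {
    n_keep <- max(1L, round(gene_retention * nrow(expr)))
    keep <- sort(sample.int(nrow(expr), n_keep))
    out <- expr[keep, , drop = FALSE]
    out <- out + distortion$cubic * out^3
    if (distortion$noise_sd > 0) {
      out <- out + matrix(rnorm(length(out), sd = distortion$noise_sd),
                          nrow(out))
    }
    attr(out, "standardized") <- FALSE
    standardize(out)
  })
}
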