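#' Validate a pipeline configuration
#'
#' A configuration is a named list (typically parsed from YAML) with blocks
#' `simulate` or `input`, plus optional `dbu`, `signature`, `dictionary`,
#' `ensemble`, `characterize`, and scalars `seed` and `out_dir`. Unknown
#' keys are rejected, referenced input files must exist, and seeds must be
#' integers — all checked before any computation.
#'
#' @param config Named list, or path to a YAML file.
#' @return The validated config list (invisibly classed
#'   `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  allowed <- c("seed", "out_dir", "simulate", "input", "dbu", "signature",
               "dictionary", "ensemble", "characterize")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) config$seed <- 1L
  if (abs(config$seed - round(config$seed)) > 0) stop("seed must be an integer")
  config$seed <- as.integer(config$seed)
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (is.null(config$simulate) && is.null(config$input)) {
    stop("config needs either a 'simulate' or an 'input' block")
  }
  if (!is.null(config$input)) {
    for (key in intersect(c("expression", "clinical", "mutations", "purity",
                            "probe_map", "compare"), names(config$input))) {
      if (!file.exists(config$input[[key]])) {
        stop("input file for '", key, "' not found: ", config$input[[key]])
      }
    }
    if (is.null(config$input$expression)) stop("input block needs 'expression'")
  }
  class(config) <- c("pipeline_config", "list")
  invisible(config)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full subtyping pipeline from a configuration
#'
#' Executes, in order: cohort simulation (or loading and standardization of
#' input tables), DBU consensus clustering, signature construction, model
#' dictionary building and accuracy filtering, leak-free cross-fitted
#' ensemble classification, and downstream characterization. All artifacts
#' are plain TSV/JSON under `out_dir`; `run_info.json` records the seed, an
#' MD5 hash of the resolved configuration, and the counts a run is judged
#' by (removed iterations, consensus-ambiguous and ensemble-ambiguous
#' samples). One master seed spawns per-stage seeds so stages are
#' individually reproducible.
#'
#' @param config A [pipeline_config()] (list or YAML path).
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 5L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  loaded <- stage("load", {
    if (!is.null(cfg$simulate)) {
      sim_args <- cfg$simulate
      sim_args$seed <- seeds[1L]
      cohort <- generate_cohort(do.call(cohort_config, sim_args))
      write_tsv(data.frame(sample_id = names(cohort$true_subtype),
                           true_subtype = cohort$true_subtype),
                file.path(cfg$out_dir, "truth.tsv"))
      list(expr = cohort$expression, cohort = cohort,
           clinical = cohort$clinical, mutations = cohort$mutations,
           purity = cohort$purity)
    } else {
      x <- read_expression(cfg$input$expression)
      if (!is.null(cfg$input$probe_map)) {
        x <- collapse_probes(x, read_sample_table_free(cfg$input$probe_map))
      }
      if (!isTRUE(attr(x, "standardized"))) x <- standardize(x)
      clinical <- NULL
      mutations <- NULL
      purity <- NULL
      if (!is.null(cfg$input$clinical)) {
        clinical <- validate_clinical(read_sample_table(cfg$input$clinical))
      }
      if (!is.null(cfg$input$mutations)) {
        m <- read_sample_table(cfg$input$mutations)
        mutations <- t(as.matrix(m[, -match("sample_id", colnames(m)),
                                   drop = FALSE]))
        colnames(mutations) <- m$sample_id
      }
      if (!is.null(cfg$input$purity)) {
        p <- read_sample_table(cfg$input$purity)
        purity <- setNames(p$purity, p$sample_id)
      }
      list(expr = x, cohort = NULL, clinical = clinical,
           mutations = mutations, purity = purity)
    }
  })
  expr <- loaded$expr
  cohort <- loaded$cohort
  clinical <- loaded$clinical
  mutations <- loaded$mutations
  purity <- loaded$purity

  dbu_args <- cfg$dbu %||% list()
  dbu_args$seed <- seeds[2L]
  dbu <- stage("dbu", run_dbu(expr, do.call(dbu_params, dbu_args)))
  write_tsv(dbu$consensus$calls, file.path(cfg$out_dir, "calls.tsv"))
  write_tsv(data.frame(sample_id = rownames(dbu$consensus$votes),
                       dbu$consensus$votes, check.names = FALSE),
            file.path(cfg$out_dir, "votes.tsv"))

  sig_args <- cfg$signature %||% list()
  curated <- sig_args$curated_genes %||% character()
  if (!is.null(cohort) && is.numeric(curated) && length(curated) == 1L) {
    # simulated runs may request "n curated genes": drawn from the truth
    curated <- with_seed(seeds[3L],
                         sample(cohort$informative_gene_ids, curated))
  }
  sig <- stage("signature", build_signature(
    expr, dbu$consensus, curated_genes = curated,
    n_select = sig_args$n_select %||% 60L,
    n_candidates = sig_args$n_candidates %||% 60L,
    n_groups = sig_args$n_groups %||% 6L,
    step = sig_args$step %||% 5L, seed = seeds[3L]))
  jsonlite::write_json(
    list(gene_ids = sig$gene_ids, curated_gene_ids = sig$curated_gene_ids,
         selected_gene_ids = sig$selected_gene_ids,
         group_assignment = as.list(sig$group_assignment)),
    file.path(cfg$out_dir, "signature.json"), digits = NA, auto_unbox = TRUE)

  dic_args <- cfg$dictionary %||% list()
  dic <- stage("dictionary", {
    d <- build_model_dictionary(expr, dbu$consensus, sig,
                                n_models = dic_args$n_models %||% 1000L,
                                step = dic_args$step %||% 5L,
                                folds = dic_args$folds %||% 3L,
                                seed = seeds[4L])
    cv_filter_models(d, expr, dbu$consensus,
                     folds = dic_args$folds %||% 3L,
                     floor = dic_args$floor %||% 0.95, seed = seeds[4L])
  })

  ens_args <- cfg$ensemble %||% list()
  etc <- stage("classify", crossfit_calls(expr, dbu$consensus, dic,
                                          n_folds = ens_args$n_folds %||% 4L,
                                          seed = seeds[5L]))
  write_tsv(etc$calls, file.path(cfg$out_dir, "predictions.tsv"))

  char <- stage("characterize", {
    out <- list()
    if (!is.null(mutations)) {
      out$mutation <- mutation_enrichment(mutations, etc)
      write_tsv(out$mutation, file.path(cfg$out_dir, "mutation_enrichment.tsv"))
    }
    if (!is.null(clinical)) {
      out$survival <- km_logrank(clinical, etc,
                                 reference = cfg$characterize$reference_group)
      write_tsv(out$survival$km, file.path(cfg$out_dir, "km_curves.tsv"))
      write_tsv(out$survival$hazard_ratios,
                file.path(cfg$out_dir, "hazard_ratios.tsv"))
    }
    if (!is.null(purity)) {
      out$purity <- purity_by_group(purity, etc)
      write_tsv(out$purity$summary, file.path(cfg$out_dir, "purity.tsv"))
    }
    if (!is.null(cohort)) {
      out$concordance <- concordance(etc, cohort$true_subtype)
      write_tsv(data.frame(out$concordance$table),
                file.path(cfg$out_dir, "concordance.tsv"))
    }
    out
  })

  cfg_plain <- unclass(cfg)
  cfg_json <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg_plain, cfg_json, digits = NA, auto_unbox = TRUE)
  info <- list(
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(cfg_json)),
    n_iterations_removed = dbu$n_removed,
    n_dbu_ambiguous = sum(dbu$consensus$calls$consensus_class == "ambiguous"),
    n_etc_ambiguous = sum(etc$calls$call == "ambiguous"),
    n_models_retained = length(dic$entries),
    mean_model_accuracy = mean(dic$cv_accuracy))
  jsonlite::write_json(info, file.path(cfg$out_dir, "run_info.json"),
                       digits = NA, auto_unbox = TRUE)
  message(sprintf(
    "pipeline done: %d iterations removed, %d DBU-ambiguous, %d ETC-ambiguous",
    info$n_iterations_removed, info$n_dbu_ambiguous, info$n_etc_ambiguous))

  invisible(list(cohort = cohort, expr = expr, dbu = dbu, signature = sig,
                 dictionary = dic, etc = etc, characterization = char,
                 run_info = info, out_dir = cfg$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Read a two-column probe map without requiring a sample_id column.
read_sample_table_free <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
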