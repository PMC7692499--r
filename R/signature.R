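#' One-vs-rest differential expression (Welch t with BH adjustment)
#'
#' For each consensus group, every gene is tested group-vs-rest with a
#' Welch two-sample t statistic; p-values are Benjamini-Hochberg adjusted
#' across genes within each contrast. Ambiguous samples are excluded before
#' testing. The signature path only needs a ranking of subtype-informative
#' genes, so a plain moderately-powered two-sample test is used.
#'
#' @param expr Gene-by-sample matrix.
#' @param labels Consensus labels (a `consensus_calls`, data.frame, or
#'   named vector); `"ambiguous"` entries are dropped.
#' @return data.frame with `gene`, `group`, `statistic`, `log_fc`
#'   (difference of group means), `p`, `p_adj`. Contrasts for groups with
#'   fewer than 3 samples are skipped with a warning.
#' @export
one_vs_rest_de <- function(expr, labels) {
  lab <- call_labels(labels)
  lab <- lab[lab != "ambiguous"]
  common <- intersect(colnames(expr), names(lab))
  if (length(common) < 6L) stop("too few labeled samples for DE")
  expr <- expr[, common, drop = FALSE]
  lab <- lab[common]
  groups <- sort(unique(lab))
  if (length(groups) < 2L) stop("need at least 2 groups for one-vs-rest DE")
  res <- lapply(groups, function(g) {
    in_g <- lab == g
    n1 <- sum(in_g); n2 <- sum(!in_g)
    if (n1 < 3L || n2 < 3L) {
      warning("contrast ", g, " skipped: fewer than 3 samples on one side")
      return(NULL)
    }
    m1 <- matrixStats::rowMeans2(expr, cols = which(in_g))
    m2 <- matrixStats::rowMeans2(expr, cols = which(!in_g))
    v1 <- matrixStats::rowVars(expr, cols = which(in_g))
    v2 <- matrixStats::rowVars(expr, cols = which(!in_g))
    se2 <- v1 / n1 + v2 / n2
    tt <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                 1)
    p <- ifelse(se2 > 0, 2 * pt(-abs(tt), df), 1)
    data.frame(gene = rownames(expr), group = g, statistic = tt,
               log_fc = m1 - m2, p = p, p_adj = p.adjust(p, "BH"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Partition signature genes into expression-pattern groups
#'
#' Genes are clustered by the shape of their expression across subtypes:
#' each gene's per-subtype mean profile is z-scored across subtypes and the
#' profiles are k-means clustered (`nstart` restarts, fixed seed). Genes
#' with identical centroid profiles always co-cluster; adding a constant to
#' all of a gene's subtype means does not change its group.
#'
#' @param expr Gene-by-sample matrix.
#' @param labels Consensus labels; ambiguous samples excluded.
#' @param genes Character vector of genes to partition.
#' @param n_groups Number of pattern groups (reduced with a warning if the
#'   profiles support fewer distinct centers).
#' @param seed Seed for k-means restarts.
#' @return Named integer vector: group index (1..n_groups) per gene.
#' @export
partition_gene_groups <- function(expr, labels, genes, n_groups = 6L,
                                  seed = 1L) {
  stopifnot(all(genes %in% rownames(expr)))
  if (length(genes) < n_groups) stop("fewer genes than requested groups")
  lab <- call_labels(labels)
  lab <- lab[lab != "ambiguous"]
  common <- intersect(colnames(expr), names(lab))
  lab <- lab[common]
  groups <- sort(unique(lab))
  prof <- vapply(groups, function(g) {
    matrixStats::rowMeans2(expr, rows = match(genes, rownames(expr)),
                           cols = which(colnames(expr) %in% common[lab == g]))
  }, numeric(length(genes)))
  rownames(prof) <- genes
  mu <- rowMeans(prof)
  s <- matrixStats::rowSds(prof)
  s[s < .Machine$double.eps^0.5] <- 1
  z <- (prof - mu) / s
  n_distinct <- nrow(unique(round(z, 10)))
  k <- min(n_groups, n_distinct)
  if (k < n_groups) {
    warning("only ", n_distinct, " distinct profiles; using ", k, " groups")
  }
  km <- with_seed(seed, kmeans(z, centers = k, nstart = 50L, iter.max = 100L))
  setNames(km$cluster, genes)
}

#' Recursive feature elimination with a linear SVC
#'
#' Starting from the full candidate list, repeatedly fits a one-vs-rest
#' linear SVC, records the stratified cross-validated accuracy at the
#' current size, and removes the `step` genes with the smallest sum of
#' squared weights across classes — until no further batch can be removed.
#' Returns the smallest gene set that attains the maximum recorded CV
#' accuracy ("optimal accuracy with the minimal number of genes").
#'
#' @param expr Gene-by-sample matrix.
#' @param labels Class labels (ambiguous samples excluded).
#' @param candidate_genes Genes to start from.
#' @param step Genes removed per iteration.
#' @param folds CV folds used to score each size.
#' @param seed Seed for fold assignment.
#' @param cost SVM cost.
#' @return Character vector of selected genes; attribute `trace` is a
#'   data.frame of (size, cv_accuracy) over the elimination schedule.
#' @export
rfe_select <- function(expr, labels, candidate_genes, step = 5L, folds = 3L,
                       seed = 1L, cost = 1) {
  path <- rfe_path(expr, labels, candidate_genes, step = step, folds = folds,
                   seed = seed, cost = cost)
  best <- which(path$accs == max(path$accs))
  chosen <- best[which.min(path$sizes[best])]
  out <- path$sets[[chosen]]
  attr(out, "trace") <- data.frame(size = path$sizes, cv_accuracy = path$accs)
  out
}

# Shared RFE engine: full elimination path from the candidate list down,
# recording the gene set and CV accuracy at every visited size, plus the
# last fit's importance ranking (for exact-size trimming).
rfe_path <- function(expr, labels, candidate_genes, step = 5L, folds = 3L,
                     seed = 1L, cost = 1) {
  stopifnot(length(candidate_genes) >= 1,
            all(candidate_genes %in% rownames(expr)))
  lab <- call_labels(labels)
  lab <- lab[lab != "ambiguous"]
  common <- intersect(colnames(expr), names(lab))
  lab <- lab[common]
  x_full <- t(expr[candidate_genes, common, drop = FALSE])
  current <- candidate_genes
  sizes <- integer(0)
  accs <- numeric(0)
  sets <- list()
  importance <- NULL
  repeat {
    acc <- lsvc_cv_accuracy(x_full[, current, drop = FALSE], lab,
                            folds = folds, seed = seed, cost = cost)
    sizes <- c(sizes, length(current))
    accs <- c(accs, acc)
    sets[[length(sets) + 1L]] <- current
    if (length(current) <= step) break
    fit <- lsvc_fit(x_full[, current, drop = FALSE], lab, cost = cost)
    imp <- lsvc_importance(fit)
    importance <- imp
    drop_genes <- names(sort(imp))[seq_len(step)]
    current <- setdiff(current, drop_genes)
    if (length(current) < 1L) break
  }
  list(sets = sets, sizes = sizes, accs = accs, importance = importance)
}

#' Assemble a classification gene signature
#'
#' Combines a curated gene list (supplied by the analyst, exempt from
#' pruning) with genes chosen by [rfe_select()] from differential-expression
#' candidates, then partitions the signature into expression-pattern groups
#' used for per-model gene half-sampling.
#'
#' @param expr Gene-by-sample matrix.
#' @param labels Consensus labels.
#' @param curated_genes Genes always included (may be empty).
#' @param n_select Number of genes the recursive elimination keeps as the
#'   RFE-selected complement of the curated list.
#' @param n_candidates Number of top DE genes (per contrast, by adjusted p
#'   then |statistic|) pooled as RFE candidates.
#' @param n_groups Number of expression-pattern groups.
#' @param step,folds,seed,cost Passed to the RFE engine (see
#'   [rfe_select()]).
#' @return A list of class `signature`: `gene_ids`, `curated_gene_ids`,
#'   `selected_gene_ids`, `group_assignment` (named integer), `de_table`.
#' @export
build_signature <- function(expr, labels, curated_genes = character(),
                            n_select = 60L, n_candidates = 60L,
                            n_groups = 6L, step = 5L,
                            folds = 3L, seed = 1L, cost = 1) {
  stopifnot(all(curated_genes %in% rownames(expr)))
  de <- one_vs_rest_de(expr, labels)
  cand <- unique(unlist(lapply(split(de, de$group), function(d) {
    d <- d[order(d$p_adj, -abs(d$statistic)), ]
    head(d$gene, n_candidates)
  })))
  cand <- setdiff(cand, curated_genes)
  if (length(cand) <= n_select) {
    selected <- cand
  } else {
    # eliminate down the RFE path and cut at the target signature size;
    # within the last removed batch, rank by the final fit's weights
    path <- rfe_path(expr, labels, cand, step = step, folds = folds,
                     seed = seed, cost = cost)
    at <- which(path$sizes >= n_select)
    set_above <- path$sets[[at[length(at)]]]
    if (length(set_above) > n_select) {
      lab <- call_labels(labels)
      lab <- lab[lab != "ambiguous"]
      common <- intersect(colnames(expr), names(lab))
      fit <- lsvc_fit(t(expr[set_above, common, drop = FALSE]), lab[common],
                      cost = cost)
      imp <- lsvc_importance(fit)
      set_above <- names(sort(imp, decreasing = TRUE))[seq_len(n_select)]
    }
    selected <- set_above
  }
  gene_ids <- union(curated_genes, selected)
  grp <- partition_gene_groups(expr, labels, gene_ids, n_groups = n_groups,
                               seed = seed)
  structure(list(gene_ids = gene_ids,
                 curated_gene_ids = curated_genes,
                 selected_gene_ids = as.character(selected),
                 group_assignment = grp,
                 de_table = de),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature: %d genes (%d curated + %d RFE-selected), %d pattern groups\n",
              length(x$gene_ids), length(x$curated_gene_ids),
              length(x$selected_gene_ids), length(unique(x$group_assignment))))
  invisible(x)
}

#' Build the ensemble model-gene dictionary
#'
#' For each of `n_models` entries, half of the genes of each expression
#' pattern group (rounded down) are sampled, and recursive feature
#' elimination reduces the pooled half-sample to the smallest gene set with
#' maximal cross-validated accuracy. The result is a dictionary of diverse,
#' small gene lists, each defining one linear classifier of the ensemble.
#'
#' @param expr Gene-by-sample matrix.
#' @param labels Consensus labels (ambiguous excluded for training).
#' @param signature A [build_signature()] object.
#' @param n_models Number of dictionary entries.
#' @param step,folds,cost Passed to [rfe_select()].
#' @param seed Master seed; each entry consumes a derived sub-seed.
#' @return A list of class `model_dictionary`: `entries` (list of gene-id
#'   vectors), `cv_accuracy` (per-entry RFE-time CV accuracy), `signature`.
#' @export
build_model_dictionary <- function(expr, labels, signature, n_models = 1000L,
                                   step = 5L, folds = 3L, seed = 1L,
                                   cost = 1) {
  grp <- signature$group_assignment
  split_genes <- split(names(grp), grp)
  if (any(lengths(split_genes) < 2L)) {
    stop("every pattern group needs at least 2 genes for half-sampling")
  }
  seeds <- derive_seeds(seed, n_models)
  entries <- vector("list", n_models)
  acc <- numeric(n_models)
  for (m in seq_len(n_models)) {
    pool <- with_seed(seeds[m], {
      unlist(lapply(split_genes, function(g) {
        sample(g, floor(length(g) / 2))
      }), use.names = FALSE)
    })
    sel <- rfe_select(expr, labels, pool, step = step, folds = folds,
                      seed = seeds[m], cost = cost)
    entries[[m]] <- as.character(sel)
    acc[m] <- max(attr(sel, "trace")$cv_accuracy)
  }
  structure(list(entries = entries, cv_accuracy = acc, signature = signature),
            class = "model_dictionary")
}

#' @export
print.model_dictionary <- function(x, ...) {
  sz <- lengths(x$entries)
  cat(sprintf("model dictionary: %d entries, %d-%d genes (median %d)\n",
              length(sz), min(sz), max(sz), as.integer(median(sz))))
  invisible(x)
}

#' Filter dictionary entries by cross-validated accuracy
#'
#' Each entry's linear SVC is scored by mean stratified k-fold CV accuracy
#' on its gene subset; entries below the accuracy floor are dropped.
#'
#' @param dictionary A [build_model_dictionary()] object.
#' @param expr Gene-by-sample matrix.
#' @param labels Consensus labels (ambiguous excluded).
#' @param folds CV folds.
#' @param floor Minimum mean CV accuracy to retain an entry.
#' @param seed Seed for fold assignment.
#' @param cost SVM cost.
#' @return The filtered `model_dictionary`; `cv_accuracy` holds the new
#'   scores, attribute `n_dropped` the number removed.
#' @export
cv_filter_models <- function(dictionary, expr, labels, folds = 3L,
                             floor = 0.95, seed = 1L, cost = 1) {
  lab <- call_labels(labels)
  lab <- lab[lab != "ambiguous"]
  common <- intersect(colnames(expr), names(lab))
  lab <- lab[common]
  x <- t(expr[, common, drop = FALSE])
  acc <- vapply(dictionary$entries, function(genes) {
    lsvc_cv_accuracy(x[, genes, drop = FALSE], lab, folds = folds,
                     seed = seed, cost = cost)
  }, numeric(1))
  keep <- acc >= floor
  if (!any(keep)) {
    stop("all entries fall below the accuracy floor; lower the floor or ",
         "revisit the consensus labels")
  }
  out <- dictionary
  out$entries <- dictionary$entries[keep]
  out$cv_accuracy <- acc[keep]
  attr(out, "n_dropped") <- sum(!keep)
  message(sum(!keep), " entr(ies) dropped below accuracy floor ", floor,
          "; mean retained accuracy ", round(mean(acc[keep]), 4))
  out
}
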