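#' Parameters of the density-based UMAP consensus clustering (DBU)
#'
#' Defaults follow the original application to the combined TCGA glioma
#' cohort (1032 samples, 12,717 genes): 1000 iterations, each embedding the
#' samples with UMAP on 1000 randomly drawn genes (5 nearest neighbors,
#' minimum distance 0, manhattan metric in gene space), then clustering the
#' 2-D embedding with DBSCAN (`min_points` 100, `eps` 1.55). Smaller cohorts
#' need `min_points` rescaled to roughly a third of a typical group size and
#' profit from `eps = "auto"` (per-iteration knee of the k-NN distance
#' curve, k = `min_points`).
#'
#' @param n_iterations Number of subsample/embed/cluster iterations.
#' @param genes_per_iteration Genes drawn (without replacement) per iteration.
#' @param n_neighbors,min_dist,metric UMAP parameters (see [uwot::umap()]).
#' @param min_points DBSCAN minimum neighborhood size.
#' @param eps DBSCAN radius, or `"auto"` for the k-NN-distance knee.
#' @param expected_groups Cluster count an iteration must report to be
#'   retained, or `"auto"` (the mode across iterations).
#' @param ambiguity_threshold Minimum plurality vote fraction for a
#'   non-ambiguous consensus call; the comparison is strict ("less than"),
#'   so a fraction exactly at the threshold passes.
#' @param seed Master seed; each iteration consumes a derived sub-seed.
#' @return A list of class `dbu_params`.
#' @export
dbu_params <- function(n_iterations = 1000L,
                       genes_per_iteration = 1000L,
                       n_neighbors = 5L,
                       min_dist = 0,
                       metric = "manhattan",
                       min_points = 100L,
                       eps = 1.55,
                       expected_groups = "auto",
                       ambiguity_threshold = 0.70,
                       seed = 1L) {
  p <- list(n_iterations = as.integer(n_iterations),
            genes_per_iteration = as.integer(genes_per_iteration),
            n_neighbors = as.integer(n_neighbors),
            min_dist = min_dist, metric = metric,
            min_points = as.integer(min_points), eps = eps,
            expected_groups = expected_groups,
            ambiguity_threshold = ambiguity_threshold,
            seed = as.integer(seed))
  stopifnot(p$n_iterations >= 1, p$min_points >= 2,
            p$ambiguity_threshold > 0, p$ambiguity_threshold <= 1,
            identical(p$eps, "auto") || (is.numeric(p$eps) && p$eps > 0))
  class(p) <- "dbu_params"
  p
}

#' Run one DBU iteration: gene subsample, UMAP embedding, DBSCAN labels
#'
#' @param expr Standardized gene-by-sample matrix.
#' @param params A [dbu_params()] object.
#' @param iteration_seed Integer seed for this iteration (gene draw and
#'   UMAP initialization).
#' @param iteration_id Identifier stored with the labeling.
#' @return A list of class `dbu_iteration` with `labels` (named integer
#'   vector per sample, 0 = noise), `n_clusters`, `sampled_gene_ids`,
#'   `eps_used`, `iteration_id`.
#' @export
run_dbu_iteration <- function(expr, params, iteration_seed,
                              iteration_id = NA_integer_) {
  stopifnot(is.matrix(expr))
  if (!isTRUE(attr(expr, "standardized"))) {
    stop("expression matrix must be standardized before DBU")
  }
  if (params$genes_per_iteration > nrow(expr)) {
    stop("genes_per_iteration exceeds the number of available genes")
  }
  with_seed(iteration_seed, {
    gsel <- sort(sample.int(nrow(expr), params$genes_per_iteration))
    emb <- uwot::umap(t(expr[gsel, , drop = FALSE]),
                      n_neighbors = params$n_neighbors,
                      min_dist = params$min_dist,
                      metric = params$metric,
                      n_threads = 1, n_sgd_threads = 1)
    eps <- if (identical(params$eps, "auto")) {
      select_eps_knee(emb, k = params$min_points)
    } else {
      params$eps
    }
    labels <- dbscan_points(emb, eps = eps, min_points = params$min_points)
    names(labels) <- colnames(expr)
    structure(list(iteration_id = iteration_id,
                   sampled_gene_ids = rownames(expr)[gsel],
                   labels = labels,
                   n_clusters = length(setdiff(unique(labels), 0L)),
                   eps_used = eps),
              class = "dbu_iteration")
  })
}

#' Drop iterations that found the wrong number of clusters
#'
#' Iterations whose cluster count differs from `expected_groups` (or from
#' the modal count, when `"auto"`) are removed before consensus voting; the
#' number removed is reported.
#'
#' @param iterations List of `dbu_iteration` objects.
#' @param expected_groups Integer >= 2 or `"auto"`.
#' @return The retained sublist; attributes `n_removed` and
#'   `expected_groups` record what was filtered.
#' @export
filter_iterations <- function(iterations, expected_groups = "auto") {
  ks <- vapply(iterations, function(it) as.integer(it$n_clusters), integer(1))
  if (identical(expected_groups, "auto")) {
    tab <- table(ks)
    expected_groups <- as.integer(names(tab)[which.max(tab)])
  }
  stopifnot(expected_groups >= 2)
  keep <- ks == expected_groups
  if (!any(keep)) stop("no iteration found the expected ", expected_groups, " groups")
  if (any(!keep)) {
    message(sum(!keep), " iteration(s) with cluster count != ",
            expected_groups, " removed")
  }
  out <- iterations[keep]
  attr(out, "n_removed") <- sum(!keep)
  attr(out, "expected_groups") <- expected_groups
  out
}

# Renumber non-noise cluster labels 1..K by order of first occurrence, so a
# labeling is invariant to arbitrary permutations of its cluster ids.
canonicalize_labels <- function(labels) {
  nz <- labels != 0L
  old <- unique(labels[nz])
  new <- match(labels[nz], old)
  labels[nz] <- new
  labels
}

#' Align cluster labels across iterations by optimal assignment
#'
#' Cluster ids are arbitrary within each iteration. Each iteration's labels
#' are matched to a reference labeling by solving the linear sum assignment
#' problem (Hungarian algorithm, [clue::solve_LSAP()]) on the cluster
#' overlap contingency matrix, maximizing the number of co-labeled samples.
#' The noise label 0 is never remapped. Both the reference and every
#' iteration are first canonicalized (clusters renumbered by first
#' occurrence), which makes the aligned result invariant to arbitrary label
#' permutations of the inputs. When no reference is given, the retained
#' iteration with the highest mean adjusted Rand index against all others
#' is used.
#'
#' @param iterations List of `dbu_iteration` objects (after filtering).
#' @param reference A `dbu_iteration` to align to, or `NULL` to choose
#'   automatically.
#' @return List of aligned iterations; attributes `reference_id` and
#'   `excluded` (iteration ids whose cluster count mismatched the
#'   reference — these are dropped with a warning).
#' @export
align_iteration_labels <- function(iterations, reference = NULL) {
  stopifnot(length(iterations) >= 1)
  if (is.null(reference)) {
    if (length(iterations) == 1L) {
      reference <- iterations[[1L]]
    } else {
      lab <- lapply(iterations, `[[`, "labels")
      n_it <- length(lab)
      agr <- matrix(0, n_it, n_it)
      for (i in seq_len(n_it - 1L)) {
        for (j in (i + 1L):n_it) {
          agr[i, j] <- agr[j, i] <- adjusted_rand(lab[[i]], lab[[j]])
        }
      }
      reference <- iterations[[which.max(rowMeans(agr))]]
    }
  }
  ref_lab <- canonicalize_labels(reference$labels)
  k_ref <- length(setdiff(unique(ref_lab), 0L))
  excluded <- integer(0)
  out <- vector("list", length(iterations))
  for (m in seq_along(iterations)) {
    it <- iterations[[m]]
    lab <- canonicalize_labels(it$labels)
    k <- length(setdiff(unique(lab), 0L))
    if (k != k_ref) {
      excluded <- c(excluded, m)
      next
    }
    both <- lab != 0L & ref_lab != 0L
    cont <- table(factor(lab[both], levels = seq_len(k_ref)),
                  factor(ref_lab[both], levels = seq_len(k_ref)))
    perm <- as.integer(clue::solve_LSAP(matrix(as.numeric(cont), k_ref),
                                        maximum = TRUE))
    new_lab <- lab
    nz <- lab != 0L
    new_lab[nz] <- perm[lab[nz]]
    it$labels <- new_lab
    out[[m]] <- it
  }
  if (length(excluded)) {
    warning(length(excluded),
            " iteration(s) excluded: cluster count differs from reference")
    out <- out[-excluded]
  }
  attr(out, "reference_id") <- reference$iteration_id
  attr(out, "excluded") <- excluded
  out
}

#' Plurality-vote consensus over aligned DBU iterations
#'
#' For every sample, the fraction of retained iterations voting for each
#' cluster is computed (the denominator is the number of retained, aligned
#' iterations; the remainder of each row is the noise-vote fraction). The
#' consensus class is the plurality cluster, unless the sample is
#' "ambiguous": either fewer than `threshold` of the iterations agree on one
#' cluster, or the most common label across iterations is the noise label 0.
#' A vote fraction exactly equal to the threshold is a confident call.
#'
#' @param aligned List of aligned `dbu_iteration` objects.
#' @param threshold Plurality fraction below which a sample is ambiguous.
#' @return A list of class `consensus_calls`: `calls` (data.frame with
#'   `sample_id`, `consensus_class`, `vote_fraction`), `votes` (sample x
#'   cluster fraction matrix), `noise_fraction`, `n_retained_iterations`.
#' @export
consensus_call <- function(aligned, threshold = 0.70) {
  if (length(aligned) == 0L) stop("no iterations to build a consensus from")
  stopifnot(threshold > 0, threshold <= 1)
  lab <- do.call(cbind, lapply(aligned, `[[`, "labels"))  # samples x iterations
  n_it <- ncol(lab)
  k <- max(lab)
  counts <- vapply(0:k, function(cl) rowSums(lab == cl), numeric(nrow(lab)))
  if (is.null(dim(counts))) {
    counts <- matrix(counts, nrow = 1L, dimnames = list(rownames(lab), NULL))
  }
  frac <- counts / n_it
  colnames(frac) <- as.character(0:k)
  if (k == 0L) {
    calls <- data.frame(sample_id = rownames(lab),
                        consensus_class = "ambiguous", vote_fraction = 0,
                        stringsAsFactors = FALSE)
    return(structure(list(calls = calls,
                          votes = frac[, 0, drop = FALSE],
                          noise_fraction = frac[, 1L],
                          n_retained_iterations = n_it,
                          threshold = threshold),
                     class = "consensus_calls"))
  }
  winner_all <- max.col(frac, ties.method = "first") - 1L  # 0 = noise wins
  cluster_frac <- frac[, -1L, drop = FALSE]
  top <- max.col(cluster_frac, ties.method = "first")
  top_frac <- cluster_frac[cbind(seq_along(top), top)]
  class_chr <- ifelse(winner_all == 0L | top_frac < threshold,
                      "ambiguous", as.character(top))
  calls <- data.frame(sample_id = rownames(lab),
                      consensus_class = class_chr,
                      vote_fraction = top_frac,
                      stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 votes = cluster_frac,
                 noise_fraction = frac[, 1L],
                 n_retained_iterations = n_it,
                 threshold = threshold),
            class = "consensus_calls")
}

#' @export
print.consensus_calls <- function(x, ...) {
  tab <- table(x$calls$consensus_class)
  cat(sprintf("consensus over %d iterations: %s\n", x$n_retained_iterations,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

# Extract a named character label vector from consensus_calls, etc_calls,
# a data.frame with sample_id + a label column, or a plain (named) vector.
call_labels <- function(x) {
  if (inherits(x, "consensus_calls")) {
    return(setNames(x$calls$consensus_class, x$calls$sample_id))
  }
  if (inherits(x, "etc_calls")) {
    return(setNames(x$calls$call, x$calls$sample_id))
  }
  if (is.data.frame(x)) {
    stopifnot("sample_id" %in% colnames(x))
    lab_col <- setdiff(colnames(x), "sample_id")[1L]
    return(setNames(as.character(x[[lab_col]]), x$sample_id))
  }
  setNames(as.character(x), names(x))
}

#' Run the full DBU consensus clustering
#'
#' Convenience driver: derives one sub-seed per iteration from the master
#' seed, runs [run_dbu_iteration()] for each, filters iterations with the
#' wrong cluster count, aligns labels, and forms the plurality consensus.
#'
#' @param expr Standardized gene-by-sample matrix.
#' @param params A [dbu_params()] object.
#' @return A list of class `dbu_result`: `consensus` (a `consensus_calls`),
#'   `iterations` (aligned retained iterations), `n_removed`,
#'   `expected_groups`, `reference_id`, `params`.
#' @export
run_dbu <- function(expr, params = dbu_params()) {
  seeds <- derive_seeds(params$seed, params$n_iterations)
  iterations <- lapply(seq_len(params$n_iterations), function(m) {
    run_dbu_iteration(expr, params, seeds[m], iteration_id = m)
  })
  retained <- filter_iterations(iterations, params$expected_groups)
  aligned <- align_iteration_labels(retained)
  consensus <- consensus_call(aligned, params$ambiguity_threshold)
  structure(list(consensus = consensus,
                 iterations = aligned,
                 n_removed = attr(retained, "n_removed"),
                 expected_groups = attr(retained, "expected_groups"),
                 reference_id = attr(aligned, "reference_id"),
                 params = params),
            class = "dbu_result")
}

#' @export
print.dbu_result <- function(x, ...) {
  cat(sprintf("DBU: %d/%d iterations retained (%d groups expected)\n",
              length(x$iterations), x$params$n_iterations, x$expected_groups))
  print(x$consensus)
  invisible(x)
}

#' Re-run DBU within one consensus group to test for substructure
#'
#' The samples of one consensus group are re-embedded and re-clustered with
#' `min_points` rescaled in proportion to the subset size (the full-cohort
#' value reflects full-cohort group sizes). If more than one subgroup is
#' found, subgroups are labeled `<group>a`, `<group>b`, ...; a homogeneous
#' subset keeps its original label.
#'
#' @param expr Standardized gene-by-sample matrix (full cohort).
#' @param calls A `consensus_calls` from the top-level run.
#' @param group Cluster id (character or integer) to subcluster.
#' @param params The top-level [dbu_params()].
#' @return A `consensus_calls` for the subset, classes renamed as above;
#'   attribute `n_subgroups` gives the subgroup count.
#' @export
subcluster_group <- function(expr, calls, group, params) {
  lab <- call_labels(calls)
  in_group <- names(lab)[lab == as.character(group)]
  min_sub <- max(5L, as.integer(round(params$min_points *
                                        length(in_group) / length(lab))))
  if (length(in_group) < 2L * min_sub) {
    stop("group ", group, " too small to subcluster (", length(in_group),
         " samples, need >= ", 2L * min_sub, ")")
  }
  sub_expr <- expr[, in_group, drop = FALSE]
  attr(sub_expr, "standardized") <- TRUE
  sub_params <- params
  sub_params$min_points <- min_sub
  sub_params$expected_groups <- "auto"
  sub_params$n_neighbors <- min(params$n_neighbors, length(in_group) - 1L)
  res <- tryCatch(run_dbu(sub_expr, sub_params),
                  error = function(e) NULL)
  if (is.null(res) || res$expected_groups < 2L) {
    # no reproducible split: report the subset as one subgroup
    cc <- list(calls = data.frame(sample_id = in_group,
                                  consensus_class = as.character(group),
                                  vote_fraction = 1,
                                  stringsAsFactors = FALSE),
               votes = NULL, noise_fraction = NULL,
               n_retained_iterations = 0L, threshold = params$ambiguity_threshold)
    class(cc) <- "consensus_calls"
    attr(cc, "n_subgroups") <- 1L
    return(cc)
  }
  cc <- res$consensus
  amb <- cc$calls$consensus_class == "ambiguous"
  ids <- suppressWarnings(as.integer(cc$calls$consensus_class[!amb]))
  cc$calls$consensus_class[!amb] <- paste0(group, letters[ids])
  if (!is.null(cc$votes)) {
    colnames(cc$votes) <- paste0(group, letters[as.integer(colnames(cc$votes))])
  }
  attr(cc, "n_subgroups") <- res$expected_groups
  cc
}
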