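#' Plurality vote with confidence score
#'
#' Combines per-model class votes for one or more samples. `p1` and `p2`
#' are the vote proportions of the most and second-most popular class; the
#' confidence score is `p1 / p2` (infinite when `p2 = 0`, i.e. unanimity is
#' maximal confidence). A sample is called to its plurality class when the
#' confidence score is strictly greater than 3 and is `"ambiguous"`
#' otherwise — so an exact tie (confidence 1) or a score of exactly 3 is
#' ambiguous. The score is scale-free: multiplying all counts by a constant
#' changes nothing.
#'
#' @param votes Named numeric vector of per-class vote counts, or a matrix
#'   (rows = samples, columns = classes).
#' @param confidence_cutoff Calls require confidence strictly above this.
#' @return data.frame with `call`, `p1`, `p2`, `confidence`,
#'   `n_models_voting` (one row per sample).
#' @export
plurality_confidence <- function(votes, confidence_cutoff = 3) {
  if (is.null(dim(votes))) {
    votes <- matrix(votes, nrow = 1, dimnames = list(NULL, names(votes)))
  }
  stopifnot(!is.null(colnames(votes)), all(votes >= 0))
  total <- rowSums(votes)
  if (any(total <= 0)) stop("each sample needs at least one vote")
  out <- data.frame(call = character(nrow(votes)), p1 = NA_real_,
                    p2 = NA_real_, confidence = NA_real_,
                    n_models_voting = total, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(votes))) {
    v <- sort(votes[i, ], decreasing = TRUE)
    p1 <- v[1L] / total[i]
    p2 <- if (length(v) > 1L) v[2L] / total[i] else 0
    conf <- if (p2 == 0) Inf else p1 / p2
    out$p1[i] <- p1
    out$p2[i] <- p2
    out$confidence[i] <- conf
    out$call[i] <- if (conf > confidence_cutoff) names(v)[1L] else "ambiguous"
  }
  rownames(out) <- rownames(votes)
  out
}

# Count votes: predictions is a models x samples character matrix.
tally_votes <- function(predictions, classes) {
  t(apply(predictions, 2L, function(p) {
    tabulate(factor(p, levels = classes), nbins = length(classes))
  })) -> counts
  colnames(counts) <- classes
  counts
}

#' Leak-free in-cohort ensemble classification by fourfold cross-fitting
#'
#' Samples are split into stratified folds by consensus class; for each
#' fold, every dictionary entry's linear SVC is trained on the other folds
#' (ambiguous samples never train) and predicts the held-out fold. No
#' sample is ever used for both training and its own classification call.
#' Ambiguous samples are spread across folds and predicted alongside.
#'
#' @param expr Standardized gene-by-sample matrix.
#' @param labels Consensus labels (a `consensus_calls` or named vector);
#'   `"ambiguous"` samples are predicted but never trained on.
#' @param dictionary A (filtered) `model_dictionary`.
#' @param n_folds Number of cross-fitting folds.
#' @param seed Seed for the stratified split.
#' @param cost SVM cost.
#' @return A list of class `etc_calls`: `calls` (data.frame `sample_id`,
#'   `call`, `p1`, `p2`, `confidence`, `n_models_voting`), `votes` (count
#'   matrix), `fold` (named fold assignment, for leak auditing).
#' @export
crossfit_calls <- function(expr, labels, dictionary, n_folds = 4L, seed = 1L,
                           cost = 1) {
  lab <- call_labels(labels)
  # canonical sample order: fold assignment is then independent of the
  # column order of `expr`
  samples <- sort(intersect(colnames(expr), names(lab)))
  lab <- lab[samples]
  labeled <- samples[lab != "ambiguous"]
  ambiguous <- setdiff(samples, labeled)
  classes <- sort(unique(lab[labeled]))
  if (length(classes) < 2L) stop("need at least 2 non-ambiguous classes")
  fold <- setNames(integer(length(samples)), samples)
  fold[labeled] <- stratified_folds(lab[labeled], n_folds, seed)
  if (length(ambiguous)) {
    fold[ambiguous] <- rep_len(seq_len(n_folds), length(ambiguous))
  }
  votes <- matrix(0L, length(samples), length(classes),
                  dimnames = list(samples, classes))
  for (f in seq_len(n_folds)) {
    train <- labeled[fold[labeled] != f]
    test <- samples[fold == f]
    if (length(unique(lab[train])) < length(classes)) {
      stop("a class is absent from the training split; reduce n_folds")
    }
    x_tr <- t(expr[, train, drop = FALSE])
    x_te <- t(expr[, test, drop = FALSE])
    for (genes in dictionary$entries) {
      fit <- lsvc_fit(x_tr[, genes, drop = FALSE], lab[train], cost = cost)
      pred <- predict(fit, x_te[, genes, drop = FALSE])
      votes[cbind(test, pred)] <- votes[cbind(test, pred)] + 1L
    }
  }
  pc <- plurality_confidence(votes)
  calls <- data.frame(sample_id = samples, pc, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(calls = calls, votes = votes, fold = fold,
                 classes = classes),
            class = "etc_calls")
}

#' @export
print.etc_calls <- function(x, ...) {
  tab <- table(x$calls$call)
  cat(sprintf("ETC calls (%d models): %s\n",
              if (nrow(x$calls)) x$calls$n_models_voting[1L] else 0L,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Fit the final ensemble on all labeled samples
#'
#' Trains every dictionary entry's linear SVC on all non-ambiguous samples,
#' producing a serializable ensemble for classifying external cohorts.
#'
#' @param expr Standardized gene-by-sample matrix.
#' @param labels Consensus labels; ambiguous samples are excluded.
#' @param dictionary A (filtered) `model_dictionary`.
#' @param seed Stored as metadata.
#' @param cost SVM cost.
#' @return A list of class `etc_model`: `entries` (each with `genes`,
#'   `weights`, `intercepts`), `classes`, `signature_genes`, `meta`.
#' @export
fit_final <- function(expr, labels, dictionary, seed = 1L, cost = 1) {
  lab <- call_labels(labels)
  lab <- lab[lab != "ambiguous"]
  train <- intersect(colnames(expr), names(lab))
  lab <- lab[train]
  x <- t(expr[, train, drop = FALSE])
  classes <- sort(unique(lab))
  entries <- lapply(dictionary$entries, function(genes) {
    fit <- lsvc_fit(x[, genes, drop = FALSE], lab, cost = cost)
    list(genes = genes, weights = fit$weights, intercepts = fit$intercepts)
  })
  structure(list(entries = entries, classes = classes,
                 signature_genes = unique(unlist(dictionary$entries)),
                 meta = list(seed = as.integer(seed), cost = cost,
                             n_training_samples = length(train))),
            class = "etc_model")
}

#' @export
print.etc_model <- function(x, ...) {
  cat(sprintf("ETC ensemble: %d linear SVCs over %d signature genes, classes %s\n",
              length(x$entries), length(x$signature_genes),
              paste(x$classes, collapse = "/")))
  invisible(x)
}

# Predict all samples of `x` (samples x genes) with one serialized entry.
predict_entry <- function(entry, x, classes) {
  scores <- x[, entry$genes, drop = FALSE] %*% entry$weights +
    matrix(entry$intercepts, nrow(x), length(entry$intercepts), byrow = TRUE)
  classes[max.col(scores, ties.method = "first")]
}

#' Classify samples with a fitted ensemble
#'
#' @param object An [fit_final()] ensemble.
#' @param newdata Standardized gene-by-sample matrix containing every
#'   signature gene (use [predict_external()] when genes are missing).
#' @param ... Unused.
#' @return An `etc_calls` list (without fold bookkeeping).
#' @export
predict.etc_model <- function(object, newdata, ...) {
  miss <- setdiff(object$signature_genes, rownames(newdata))
  if (length(miss)) {
    stop(length(miss), " signature gene(s) missing; use predict_external()")
  }
  x <- t(newdata[object$signature_genes, , drop = FALSE])
  preds <- vapply(object$entries, predict_entry, character(nrow(x)),
                  x = x, classes = object$classes)
  votes <- tally_votes(t(preds), object$classes)
  rownames(votes) <- rownames(x)
  pc <- plurality_confidence(votes)
  calls <- data.frame(sample_id = rownames(x), pc, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(calls = calls, votes = votes, fold = NULL,
                 classes = object$classes),
            class = "etc_calls")
}

#' Classify an external cohort, tolerating missing signature genes
#'
#' Cross-platform validation scenario: some signature genes may be absent
#' from the new platform. Missing genes are dropped from every affected
#' entry, and those entries are refit on the training cohort restricted to
#' the surviving genes — refitting preserves each entry's decision geometry
#' on the available genes, whereas zero-filling standardized features would
#' bias the linear scores. Entries left with fewer than 2 genes are
#' excluded from voting (the vote denominator is the number of voting
#' entries).
#'
#' @param model An [fit_final()] ensemble.
#' @param expr_new Standardized (within its own dataset) gene-by-sample
#'   matrix of the external cohort.
#' @param refit_expr,refit_labels The training cohort and labels used to
#'   refit gene-reduced entries.
#' @param cost SVM cost for refits.
#' @return An `etc_calls`; attributes `n_refit`, `n_excluded`, and
#'   `mean_confidence_by_class` (mean p1 of confident calls per class).
#' @export
predict_external <- function(model, expr_new, refit_expr, refit_labels,
                             cost = 1) {
  present <- intersect(model$signature_genes, rownames(expr_new))
  if (length(present) < 0.5 * length(model$signature_genes)) {
    stop("fewer than 50% of signature genes present; platform too divergent")
  }
  lab <- call_labels(refit_labels)
  lab <- lab[lab != "ambiguous"]
  train <- intersect(colnames(refit_expr), names(lab))
  lab <- lab[train]
  x_tr <- t(refit_expr[, train, drop = FALSE])
  x_new <- t(expr_new[present, , drop = FALSE])
  n_refit <- 0L
  n_excluded <- 0L
  preds <- list()
  for (entry in model$entries) {
    genes <- intersect(entry$genes, present)
    if (length(genes) < 2L) {
      n_excluded <- n_excluded + 1L
      next
    }
    if (length(genes) < length(entry$genes)) {
      fit <- lsvc_fit(x_tr[, genes, drop = FALSE], lab, cost = cost)
      entry <- list(genes = genes, weights = fit$weights,
                    intercepts = fit$intercepts)
      n_refit <- n_refit + 1L
    }
    preds[[length(preds) + 1L]] <- predict_entry(entry, x_new, model$classes)
  }
  if (!length(preds)) stop("no entries left to vote")
  pred_mat <- do.call(rbind, preds)  # models x samples
  votes <- tally_votes(pred_mat, model$classes)
  rownames(votes) <- rownames(x_new)
  pc <- plurality_confidence(votes)
  calls <- data.frame(sample_id = rownames(x_new), pc,
                      stringsAsFactors = FALSE, row.names = NULL)
  confident <- pc$call != "ambiguous"
  mean_conf <- tapply(pc$p1[confident], pc$call[confident], mean)
  out <- structure(list(calls = calls, votes = votes, fold = NULL,
                        classes = model$classes),
                   class = "etc_calls")
  attr(out, "n_refit") <- n_refit
  attr(out, "n_excluded") <- n_excluded
  attr(out, "mean_confidence_by_class") <- mean_conf
  out
}

#' Serialize an ensemble model to JSON
#'
#' Plain-text model exchange: gene lists, per-class weight vectors and
#' intercepts, class labels and metadata. [etc_model_from_json()] restores
#' a model that predicts identically.
#'
#' @param model An `etc_model`.
#' @param path Output path.
#' @export
etc_model_to_json <- function(model, path) {
  obj <- list(
    classes = model$classes,
    signature_genes = model$signature_genes,
    meta = model$meta,
    entries = lapply(model$entries, function(e) {
      list(genes = e$genes,
           weights = unname(as.list(as.data.frame(e$weights))),
           intercepts = unname(e$intercepts))
    }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname etc_model_to_json
#' @param path Path to a JSON file written by [etc_model_to_json()].
#' @export
etc_model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  classes <- unlist(obj$classes)
  entries <- lapply(obj$entries, function(e) {
    genes <- unlist(e$genes)
    w <- vapply(e$weights, function(col) unlist(col), numeric(length(genes)))
    dimnames(w) <- list(genes, classes)
    list(genes = genes, weights = w,
         intercepts = setNames(unlist(e$intercepts), classes))
  })
  structure(list(entries = entries, classes = classes,
                 signature_genes = unlist(obj$signature_genes),
                 meta = lapply(obj$meta, unlist)),
            class = "etc_model")
}
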