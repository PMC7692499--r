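#' One-vs-rest mutation enrichment per subtype
#'
#' For every mutated gene and every subtype, a 2x2 chi-squared test
#' (mutated/wild-type x in-group/rest, no continuity correction) measures
#' enrichment; p-values are Benjamini-Hochberg adjusted across all
#' gene-by-group tests. Genes with no mutation in any sample are removed
#' before testing. Ambiguous samples are excluded by default.
#'
#' @param mutations Binary gene-by-sample matrix ("1" = mutated).
#' @param calls Subtype labels (a `consensus_calls`, `etc_calls`,
#'   data.frame, or named vector).
#' @param include_ambiguous Keep ambiguous samples as their own group?
#' @return data.frame with `gene`, `group`, the 2x2 counts
#'   (`mut_in_group`, `wt_in_group`, `mut_rest`, `wt_rest`), `statistic`,
#'   `p`, `p_adj`, and `small_expected` (TRUE when any expected cell < 5).
#' @export
mutation_enrichment <- function(mutations, calls, include_ambiguous = FALSE) {
  stopifnot(is.matrix(mutations), all(mutations %in% c(0, 1)))
  lab <- call_labels(calls)
  if (!include_ambiguous) lab <- lab[lab != "ambiguous"]
  common <- intersect(colnames(mutations), names(lab))
  if (!length(common)) stop("no samples shared between mutations and calls")
  mutations <- mutations[, common, drop = FALSE]
  lab <- lab[common]
  zero <- rowSums(mutations) == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with no mutation removed")
    mutations <- mutations[!zero, , drop = FALSE]
  }
  groups <- sort(unique(lab))
  res <- list()
  for (g in groups) {
    in_g <- lab == g
    for (gene in rownames(mutations)) {
      mut <- mutations[gene, ] == 1
      tab <- matrix(c(sum(mut & in_g), sum(!mut & in_g),
                      sum(mut & !in_g), sum(!mut & !in_g)), 2L)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      test <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(test$statistic)
      if (is.nan(stat)) { stat <- 0; pval <- 1 } else pval <- test$p.value
      res[[length(res) + 1L]] <- data.frame(
        gene = gene, group = g,
        mut_in_group = tab[1, 1], wt_in_group = tab[2, 1],
        mut_rest = tab[1, 2], wt_rest = tab[2, 2],
        statistic = stat, p = pval,
        small_expected = any(expected < 5),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves, log-rank test, and per-group Cox hazard ratios
#'
#' Product-limit survival estimates per subtype, an overall log-rank test,
#' and univariate Cox proportional-hazards ratios (Efron tie handling) of
#' each group against a reference, with 95% confidence intervals and median
#' survival ("not reached" when the curve never crosses 0.5). Ambiguous
#' samples are excluded by default.
#'
#' @param clinical data.frame with `sample_id`, `survival_time`, `event`.
#' @param calls Subtype labels.
#' @param reference Reference group for hazard ratios (default: first
#'   group alphabetically).
#' @param include_ambiguous Keep ambiguous samples as their own group?
#' @return A list of class `survival_summary`: `km` (data.frame of per-group
#'   curves: `group`, `time`, `surv`, `n_risk`, `n_event`, `n_censor`),
#'   `logrank` (`chisq`, `df`, `p`), `hazard_ratios` (per non-reference
#'   group: `hr`, `lower`, `upper`, `p`; NA with a warning for groups with
#'   no events), `medians`, `reference`.
#' @export
km_logrank <- function(clinical, calls, reference = NULL,
                       include_ambiguous = FALSE) {
  clinical <- validate_clinical(clinical)
  lab <- call_labels(calls)
  if (!include_ambiguous) lab <- lab[lab != "ambiguous"]
  common <- intersect(clinical$sample_id, names(lab))
  if (length(common) < 2L) stop("too few samples with both survival and calls")
  d <- clinical[match(common, clinical$sample_id), ]
  d$group <- factor(lab[common])
  if (nlevels(d$group) < 2L) stop("need at least 2 groups for survival comparison")
  if (is.null(reference)) reference <- levels(d$group)[1L]
  d$group <- stats::relevel(d$group, ref = as.character(reference))

  fit <- survival::survfit(survival::Surv(survival_time, event) ~ group,
                           data = d)
  km <- data.frame(
    group = rep(sub("^group=", "", names(fit$strata)), fit$strata),
    time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor,
    stringsAsFactors = FALSE)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", rownames(summary(fit)$table))

  sd_test <- survival::survdiff(survival::Surv(survival_time, event) ~ group,
                                data = d)
  df <- length(sd_test$n) - 1L
  logrank <- list(chisq = unname(sd_test$chisq), df = df,
                  p = stats::pchisq(sd_test$chisq, df, lower.tail = FALSE))

  events_per_group <- tapply(d$event, d$group, sum)
  if (any(events_per_group == 0)) {
    warning("group(s) with zero events: ",
            paste(names(events_per_group)[events_per_group == 0],
                  collapse = ", "), "; hazard ratios not estimable")
  }
  # monotone-likelihood warnings (zero-event or perfectly separated groups)
  # are re-reported below as non-estimable HRs
  cox <- withCallingHandlers(
    survival::coxph(survival::Surv(survival_time, event) ~ group,
                    data = d, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("coefficient may be infinite|Loglik converged",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cs <- summary(cox)
  hr <- data.frame(group = sub("^group", "", rownames(cs$conf.int)),
                   hr = cs$conf.int[, "exp(coef)"],
                   lower = cs$conf.int[, "lower .95"],
                   upper = cs$conf.int[, "upper .95"],
                   log_hr = cs$coefficients[, "coef"],
                   se_log_hr = cs$coefficients[, "se(coef)"],
                   p = cs$coefficients[, "Pr(>|z|)"],
                   stringsAsFactors = FALSE, row.names = NULL)
  bad <- names(events_per_group)[events_per_group == 0]
  hr[hr$group %in% bad, c("hr", "lower", "upper", "log_hr", "p")] <- NA
  structure(list(km = km, logrank = logrank, hazard_ratios = hr,
                 medians = med, reference = as.character(reference)),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf("log-rank chisq = %.3g (df %d), p = %.3g; reference %s\n",
              x$logrank$chisq, x$logrank$df, x$logrank$p, x$reference))
  meds <- ifelse(is.na(x$medians), "not reached", signif(x$medians, 4))
  cat("median survival:", paste(names(x$medians), meds, sep = "=",
                                collapse = ", "), "\n")
  invisible(x)
}

#' Tumor purity by subtype: median [IQR] and one-way ANOVA
#'
#' Ambiguous samples are kept as their own group (their purity is of
#' interest: hard-to-classify samples tend to be dilute). Groups with fewer
#' than 2 samples are summarized but excluded from the ANOVA.
#'
#' @param purity Named numeric vector of per-sample purity in `[0, 1]`.
#' @param calls Subtype labels.
#' @return A list: `summary` (data.frame `group`, `n`, `median`, `q1`,
#'   `q3`), `anova_f`, `anova_p`.
#' @export
purity_by_group <- function(purity, calls) {
  stopifnot(all(purity >= 0 & purity <= 1, na.rm = TRUE))
  lab <- call_labels(calls)
  common <- intersect(names(purity), names(lab))
  if (!length(common)) stop("no samples shared between purity and calls")
  p <- purity[common]
  g <- lab[common]
  summ <- do.call(rbind, lapply(sort(unique(g)), function(gr) {
    q <- quantile(p[g == gr], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = gr, n = sum(g == gr), median = q[2L],
               q1 = q[1L], q3 = q[3L], stringsAsFactors = FALSE)
  }))
  big <- names(table(g))[table(g) >= 2L]
  if (length(big) >= 2L) {
    keep <- g %in% big
    av <- summary(aov(p[keep] ~ factor(g[keep])))[[1L]]
    anova_f <- av$`F value`[1L]
    anova_p <- av$`Pr(>F)`[1L]
  } else {
    anova_f <- NA_real_
    anova_p <- NA_real_
  }
  list(summary = summ, anova_f = anova_f, anova_p = anova_p)
}

#' Concordance between two classifications
#'
#' Cross-tabulates two label vectors over their shared samples and reports
#' percent agreement under an optimal one-to-one matching of class labels
#' (Hungarian assignment on the contingency table), making the statistic
#' invariant to class naming and symmetric in its arguments. A semantic
#' mapping (e.g. subtype -> mutation class) can be supplied to override the
#' automatic matching. Per-class composition lines report how each class of
#' the first labeling distributes over the second.
#'
#' @param calls_a,calls_b Label vectors (or call objects).
#' @param ambiguous Either `"exclude"` (drop samples ambiguous in either
#'   labeling) or `"own"` (treat ambiguous as a class).
#' @param mapping Optional named character vector mapping classes of `a` to
#'   classes of `b`.
#' @return A list of class `subtype_concordance`: `table` (contingency),
#'   `percent_agreement`, `matching` (named character), `n`, `composition`
#'   (data.frame).
#' @export
concordance <- function(calls_a, calls_b, ambiguous = c("exclude", "own"),
                        mapping = NULL) {
  ambiguous <- match.arg(ambiguous)
  a <- call_labels(calls_a)
  b <- call_labels(calls_b)
  common <- intersect(names(a), names(b))
  if (!length(common)) stop("no shared samples between the two labelings")
  a <- a[common]
  b <- b[common]
  if (ambiguous == "exclude") {
    keep <- a != "ambiguous" & b != "ambiguous"
    a <- a[keep]
    b <- b[keep]
    if (!length(a)) stop("no samples left after excluding ambiguous calls")
  }
  tab <- table(a, b)
  if (is.null(mapping)) {
    k <- max(dim(tab))
    padded <- matrix(0, k, k)
    padded[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    sol <- as.integer(clue::solve_LSAP(padded, maximum = TRUE))
    matching <- setNames(rep(NA_character_, nrow(tab)), rownames(tab))
    for (i in seq_len(nrow(tab))) {
      if (sol[i] <= ncol(tab)) matching[i] <- colnames(tab)[sol[i]]
    }
  } else {
    matching <- mapping
  }
  matched <- 0L
  for (cls in names(matching)) {
    if (!is.na(matching[cls]) && cls %in% rownames(tab) &&
        matching[cls] %in% colnames(tab)) {
      matched <- matched + tab[cls, matching[cls]]
    }
  }
  comp <- do.call(rbind, lapply(rownames(tab), function(cls) {
    n_cls <- sum(tab[cls, ])
    data.frame(class_a = cls, class_b = colnames(tab),
               n = as.integer(tab[cls, ]), n_class_a = n_cls,
               fraction = as.numeric(tab[cls, ]) / n_cls,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, percent_agreement = 100 * matched / sum(tab),
                 matching = matching, n = sum(tab), composition = comp),
            class = "subtype_concordance")
}

#' @export
print.subtype_concordance <- function(x, ...) {
  cat(sprintf("%.1f%% agreement over %d samples (optimal class matching)\n",
              x$percent_agreement, x$n))
  print(x$table)
  invisible(x)
}
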