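test_that("one-vs-rest DE: null genes, planted signal, and BH behave", {
  co <- default_cohort()
  de <- one_vs_rest_de(co$expression, co$true_subtype)
  expect_setequal(unique(de$group), paste0("S", 1:4))

  # planted informative genes are found in at least one contrast
  sig_genes <- unique(de$gene[de$p_adj < 0.05])
  found <- mean(co$informative_gene_ids %in% sig_genes)
  expect_gt(found, 0.9)

  # a gene identical in group and rest: statistic 0, p = 1
  x <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:20)))
  lab <- setNames(rep(c("A", "B"), each = 10), colnames(x))
  x[1, ] <- 7  # constant everywhere: exactly identical in group and rest
  de2 <- one_vs_rest_de(x, lab)
  flat <- de2[de2$gene == "g1", ]
  expect_true(all(flat$statistic == 0))
  expect_true(all(flat$p == 1))

  # BH adjustment matches the hand computation (independent cummin oracle)
  bh_hand <- function(p) {
    n <- length(p)
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  expect_equal(bh_hand(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  one <- de2[de2$group == "A", ]
  expect_equal(one$p_adj, bh_hand(one$p))
})

test_that("gene pattern groups recover planted archetypes", {
  # 6 archetype profiles over 4 subtypes, 10 genes each, tiny noise
  set.seed(51)
  arch <- matrix(rnorm(6 * 4, sd = 3), 6, 4)
  genes <- sprintf("g%02d", 1:60)
  truth <- rep(1:6, each = 10)
  n_per <- 15
  lab <- setNames(rep(paste0("S", 1:4), each = n_per),
                  sprintf("s%02d", 1:(4 * n_per)))
  x <- arch[truth, rep(1:4, each = n_per)] +
    matrix(rnorm(60 * 4 * n_per, sd = 0.05), 60)
  dimnames(x) <- list(genes, names(lab))
  grp <- partition_gene_groups(x, lab, genes, n_groups = 6, seed = 8)
  expect_equal(adjusted_rand(grp, truth), 1)

  # adding a constant to one gene's values leaves its group unchanged
  x2 <- x
  x2["g01", ] <- x2["g01", ] + 100
  grp2 <- partition_gene_groups(x2, lab, genes, n_groups = 6, seed = 8)
  expect_equal(adjusted_rand(grp2, grp), 1)
  expect_true(all(grp[truth == 1] == grp["g01"]))

  expect_error(partition_gene_groups(x, lab, genes[1:4], n_groups = 6),
               "fewer genes")
})

test_that("RFE keeps planted informative genes and follows the schedule", {
  set.seed(53)
  n <- 160
  lab <- setNames(rep(c("A", "B", "C", "D"), each = n / 4),
                  sprintf("s%03d", 1:n))
  genes <- sprintf("g%02d", 1:20)
  mu <- matrix(0, 20, 4)
  mu[1, ] <- c(6, 0, 0, 0); mu[2, ] <- c(0, 6, 0, 0); mu[3, ] <- c(0, 0, 6, 6)
  x <- mu[, rep(1:4, each = n / 4)] + matrix(rnorm(20 * n), 20)
  dimnames(x) <- list(genes, names(lab))
  sel <- rfe_select(x, lab, genes, step = 5, seed = 2)
  expect_true(all(c("g01", "g02", "g03") %in% sel))
  tr <- attr(sel, "trace")
  expect_equal(tr$size, seq(20, 5, by = -5))
  # smallest size attaining the maximum accuracy is returned
  best <- max(tr$cv_accuracy)
  expect_equal(length(sel), min(tr$size[tr$cv_accuracy == best]))
})

test_that("RFE with step 1 matches exhaustive best-subset on a toy problem", {
  set.seed(57)
  n <- 120
  lab <- setNames(rep(c("A", "B"), each = n / 2), sprintf("s%03d", 1:n))
  genes <- paste0("g", 1:6)
  mu <- matrix(0, 6, 2)
  mu[1, ] <- c(5, -5); mu[2, ] <- c(-5, 5)
  x <- mu[, rep(1:2, each = n / 2)] + matrix(rnorm(6 * n, sd = 0.5), 6)
  dimnames(x) <- list(genes, names(lab))
  sel <- rfe_select(x, lab, genes, step = 1, seed = 2)
  # exhaustive search over singletons: either informative gene separates
  # perfectly, so RFE must end on a single informative gene
  expect_equal(length(sel), 1L)
  expect_true(sel %in% c("g1", "g2"))
})

test_that("the signature combines curated and RFE genes with full groups", {
  co <- default_cohort()
  sig <- default_signature()
  expect_s3_class(sig, "signature")
  expect_setequal(sig$gene_ids,
                  union(sig$curated_gene_ids, sig$selected_gene_ids))
  expect_length(intersect(sig$curated_gene_ids, sig$selected_gene_ids), 0L)
  expect_identical(sig$curated_gene_ids, co$informative_gene_ids[1:10])
  expect_equal(length(sig$selected_gene_ids), 60L)
  expect_setequal(names(sig$group_assignment), sig$gene_ids)
  expect_equal(sort(unique(unname(sig$group_assignment))), 1:6)
})

test_that("the model dictionary half-samples groups and is reproducible", {
  co <- default_cohort()
  sig <- default_signature()
  dic <- default_dictionary()
  expect_length(dic$entries, 200L)
  pool_max <- sum(floor(table(sig$group_assignment) / 2))
  sz <- lengths(dic$entries)
  expect_true(all(sz >= 1 & sz <= pool_max))
  expect_gt(length(unique(sz)), 1L)
  expect_true(all(unlist(dic$entries) %in% sig$gene_ids))
  # democratized gene usage: the union of entries covers most of the
  # signature
  expect_gt(length(unique(unlist(dic$entries))) / length(sig$gene_ids), 0.9)

  d1 <- build_model_dictionary(co$expression, default_dbu()$consensus, sig,
                               n_models = 4, seed = 99)
  d2 <- build_model_dictionary(co$expression, default_dbu()$consensus, sig,
                               n_models = 4, seed = 99)
  expect_identical(d1$entries, d2$entries)
})

test_that("accuracy filtering applies the floor and is monotone", {
  co <- default_cohort()
  dic <- default_dictionary()
  filt95 <- default_filtered_dictionary()
  acc_all <- suppressMessages(cv_filter_models(
    dic, co$expression, default_dbu()$consensus, floor = 0, seed = 5))
  expect_true(all(filt95$cv_accuracy >= 0.95))
  expect_equal(length(filt95$entries),
               sum(acc_all$cv_accuracy >= 0.95))
  # raising the floor never adds entries
  filt99 <- suppressMessages(cv_filter_models(
    dic, co$expression, default_dbu()$consensus, floor = 0.99, seed = 5))
  expect_lte(length(filt99$entries), length(filt95$entries))
  key95 <- vapply(filt95$entries, paste, "", collapse = ",")
  key99 <- vapply(filt99$entries, paste, "", collapse = ",")
  expect_true(all(key99 %in% key95))
})
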