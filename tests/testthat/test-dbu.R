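test_that("a DBU iteration recovers two synthetic blobs without noise", {
  tb <- two_blob_expr()
  p <- dbu_params(genes_per_iteration = 100L, min_points = 20L, eps = 1,
                  n_neighbors = 5L)
  it <- run_dbu_iteration(tb$expr, p, iteration_seed = 71, iteration_id = 1)
  expect_s3_class(it, "dbu_iteration")
  expect_equal(it$n_clusters, 2L)
  expect_equal(sum(it$labels == 0), 0L)
  expect_equal(adjusted_rand(it$labels, tb$labels), 1)

  # determinism under a fixed seed
  it2 <- run_dbu_iteration(tb$expr, p, iteration_seed = 71, iteration_id = 1)
  expect_identical(it$labels, it2$labels)
  expect_identical(it$sampled_gene_ids, it2$sampled_gene_ids)

  expect_error(
    run_dbu_iteration(tb$expr, dbu_params(genes_per_iteration = 10000L), 1),
    "exceeds")
  unstd <- matrix(rnorm(100), 10)
  expect_error(run_dbu_iteration(unstd, p, 1), "standardized")
})

test_that("iteration filtering counts and resolves the modal cluster number", {
  make_it <- function(k) {
    structure(list(iteration_id = k, labels = setNames(rep(1L, 10),
                                                       paste0("s", 1:10)),
                   n_clusters = k), class = "dbu_iteration")
  }
  its <- lapply(c(3, 3, 3, 3, 3, 3, 3, 3, 2, 2), make_it)
  kept <- suppressMessages(filter_iterations(its, expected_groups = 3))
  expect_length(kept, 8L)
  expect_equal(attr(kept, "n_removed"), 2L)
  auto <- suppressMessages(filter_iterations(its, expected_groups = "auto"))
  expect_equal(attr(auto, "expected_groups"), 3L)
  expect_error(filter_iterations(lapply(c(2, 2), make_it), 4), "no iteration")
})

test_that("label alignment inverts a known permutation exactly", {
  its <- fake_iterations(n_iter = 5, flip = 0, noise = 0)
  ref <- its[[1L]]
  permuted <- its[[2L]]  # same partition, different cluster ids
  aligned <- align_iteration_labels(list(ref, permuted), reference = ref)
  expect_identical(aligned[[1L]]$labels, aligned[[2L]]$labels)
  # identity case
  aligned2 <- align_iteration_labels(list(ref, ref), reference = ref)
  expect_identical(aligned2[[2L]]$labels, aligned2[[1L]]$labels)
})

test_that("alignment excludes iterations with mismatched cluster counts", {
  its <- fake_iterations(n_iter = 3, flip = 0, noise = 0)
  bad <- its[[3L]]
  bad$labels[bad$labels == 3L] <- 2L
  bad$n_clusters <- 2L
  expect_warning(
    out <- align_iteration_labels(list(its[[1L]], its[[2L]], bad),
                                  reference = its[[1L]]),
    "excluded")
  expect_length(out, 2L)
})

test_that("consensus voting applies the plurality and ambiguity rules", {
  n_it <- 10L
  samples <- c("a", "b", "c")
  # sample a: 7/10 vote cluster 1 (exactly 70%) -> confident call
  # sample b: noise is the most common label -> ambiguous
  # sample c: unanimous cluster 2
  lab_a <- c(rep(1L, 7), rep(2L, 3))
  lab_b <- c(rep(0L, 6), rep(1L, 4))
  lab_c <- rep(2L, 10)
  its <- lapply(seq_len(n_it), function(m) {
    structure(list(iteration_id = m,
                   labels = setNames(c(lab_a[m], lab_b[m], lab_c[m]), samples),
                   n_clusters = 2L),
              class = "dbu_iteration")
  })
  cc <- consensus_call(its, threshold = 0.70)
  calls <- setNames(cc$calls$consensus_class, cc$calls$sample_id)
  expect_identical(unname(calls["a"]), "1")   # exactly 70% passes
  expect_identical(unname(calls["b"]), "ambiguous")
  expect_identical(unname(calls["c"]), "2")
  expect_equal(cc$calls$vote_fraction[cc$calls$sample_id == "c"], 1)
  # vote matrix rows plus noise fraction sum to one
  expect_lt(max(abs(rowSums(cc$votes) + cc$noise_fraction - 1)), 1e-12)
  # 69% would be ambiguous: drop one agreeing vote
  its2 <- its
  its2[[7L]]$labels["a"] <- 2L
  cc2 <- consensus_call(its2, threshold = 0.70)
  expect_identical(cc2$calls$consensus_class[cc2$calls$sample_id == "a"],
                   "ambiguous")
  expect_error(consensus_call(list(), 0.7), "no iterations")
})

test_that("full DBU recovers planted two-group structure end to end", {
  tb <- two_blob_expr()
  p <- dbu_params(n_iterations = 8L, genes_per_iteration = 60L,
                  min_points = 20L, eps = 1, expected_groups = "auto",
                  seed = 5)
  res <- suppressMessages(run_dbu(tb$expr, p))
  expect_s3_class(res, "dbu_result")
  expect_equal(res$expected_groups, 2L)
  lab <- setNames(res$consensus$calls$consensus_class,
                  res$consensus$calls$sample_id)
  ok <- lab != "ambiguous"
  expect_gt(mean(ok), 0.95)
  expect_equal(adjusted_rand(lab[ok], tb$labels[ok]), 1)
})

test_that("subclustering resolves a merged diluted group", {
  # emulate a top-level run that fused the diluted subtype with the
  # subtype whose tumor profile it shares: S2 and S4 share one label and
  # only the purity dilution can separate them on re-clustering
  co <- default_cohort()
  truth <- co$true_subtype
  merged <- setNames(ifelse(truth %in% c("S2", "S4"), "2", as.character(truth)),
                     names(truth))
  p <- default_dbu_params(n_iterations = 10L)
  sub_cc <- suppressMessages(
    subcluster_group(co$expression, merged, "2", p))
  sl <- setNames(sub_cc$calls$consensus_class, sub_cc$calls$sample_id)
  expect_setequal(names(sl), names(truth)[truth %in% c("S2", "S4")])
  ok <- sl != "ambiguous"
  expect_equal(attr(sub_cc, "n_subgroups"), 2L)
  expect_gt(adjusted_rand(sl[ok], truth[names(sl)[ok]]), 0.8)
  expect_true(all(startsWith(unique(sl[ok]), "2")))
})

test_that("subclustering a homogeneous group reports a single subgroup", {
  co <- default_cohort()
  truth <- co$true_subtype
  p <- default_dbu_params(n_iterations = 10L)
  sub_cc <- suppressMessages(
    subcluster_group(co$expression, truth, "S1", p))
  expect_equal(attr(sub_cc, "n_subgroups"), 1L)
  expect_true(all(sub_cc$calls$consensus_class == "S1"))
  # a too-small group is refused
  expect_error(subcluster_group(co$expression, truth, "nosuch", p),
               "too small")
})
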