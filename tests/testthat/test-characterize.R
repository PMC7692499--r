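test_that("mutation enrichment reproduces the hand chi-squared and drops
           all-wild-type genes", {
  # build a mutation matrix realizing the 2x2 table [[30,20],[10,40]]
  # for gene mgA in group G1 (mut/wt x in-group/rest)
  samples <- sprintf("s%03d", 1:100)
  lab <- setNames(rep(c("G1", "G2"), each = 50), samples)
  mut <- matrix(0L, 2, 100, dimnames = list(c("mgA", "mgB"), samples))
  mut["mgA", 1:30] <- 1L            # 30 mutated in group, 20 wt in group
  mut["mgA", 51:60] <- 1L           # 10 mutated in rest, 40 wt in rest
  out <- suppressMessages(mutation_enrichment(mut, lab))
  row <- out[out$gene == "mgA" & out$group == "G1", ]
  expect_equal(row$mut_in_group, 30)
  expect_equal(row$wt_in_group, 20)
  expect_equal(row$mut_rest, 10)
  expect_equal(row$wt_rest, 40)
  # textbook formula: N (ad - bc)^2 / (r1 r2 c1 c2)
  hand <- 100 * (30 * 40 - 20 * 10)^2 / (40 * 60 * 50 * 50)
  expect_equal(row$statistic, hand, tolerance = 1e-10)
  expect_true(all(out$p_adj >= out$p))
  # mgB is never mutated: absent from the output
  expect_false("mgB" %in% out$gene)
})

test_that("mutation enrichment has nominal size under the null", {
  set.seed(71)
  n <- 400
  samples <- sprintf("s%03d", 1:n)
  lab <- setNames(sample(c("A", "B"), n, replace = TRUE), samples)
  mut <- matrix(rbinom(200 * n, 1, 0.3), 200, n,
                dimnames = list(sprintf("mg%03d", 1:200), samples))
  out <- suppressMessages(mutation_enrichment(mut, lab))
  rate <- mean(out$p < 0.05)
  expect_lt(abs(rate - 0.05), 0.03)
})

test_that("KM medians and log-rank match hand computation on toy data", {
  cl <- data.frame(sample_id = sprintf("s%d", 1:6),
                   survival_time = c(1, 2, 3, 10, 20, 30),
                   event = 1)
  lab <- setNames(rep(c("A", "B"), each = 3), cl$sample_id)
  s <- km_logrank(cl, lab, reference = "A")
  expect_equal(unname(s$medians["A"]), 2)
  expect_equal(unname(s$medians["B"]), 20)
  # product-limit by hand for group A: 2/3, 1/3, 0
  km_a <- s$km[s$km$group == "A", ]
  expect_equal(km_a$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # hand log-rank: at each event time, O - E for group A under the
  # hypergeometric model
  times <- sort(unique(cl$survival_time))
  o_minus_e <- 0; v <- 0
  for (t in times) {
    at_risk <- cl$survival_time >= t
    d <- sum(cl$survival_time == t)          # all events here
    n_t <- sum(at_risk)
    n_a <- sum(at_risk & lab[cl$sample_id] == "A")
    d_a <- sum(cl$survival_time == t & lab[cl$sample_id] == "A")
    o_minus_e <- o_minus_e + d_a - d * n_a / n_t
    if (n_t > 1) {
      v <- v + d * (n_a / n_t) * (1 - n_a / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  hand_chisq <- o_minus_e^2 / v
  expect_equal(s$logrank$chisq, hand_chisq, tolerance = 1e-8)
  expect_lt(s$logrank$p, 0.05)  # as strong as 6 samples allow
})

test_that("identical survival in two groups gives null log-rank and unit HR", {
  cl <- data.frame(sample_id = sprintf("s%d", 1:40),
                   survival_time = rep(c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19), 4),
                   event = rep(c(1, 1, 0, 1), 10))
  lab <- setNames(rep(c("A", "B"), each = 20), cl$sample_id)
  cl$survival_time[21:40] <- cl$survival_time[1:20]
  cl$event[21:40] <- cl$event[1:20]
  s <- km_logrank(cl, lab, reference = "A")
  expect_equal(s$logrank$chisq, 0, tolerance = 1e-10)
  expect_equal(s$logrank$p, 1, tolerance = 1e-10)
  expect_equal(s$hazard_ratios$hr, 1, tolerance = 1e-6)
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(73)
  cl <- data.frame(sample_id = sprintf("s%d", 1:60),
                   survival_time = rexp(60, 0.1), event = 1)
  lab <- setNames(rep(c("A", "B"), each = 30), cl$sample_id)
  s <- km_logrank(cl, lab, reference = "A")
  for (g in c("A", "B")) {
    km_g <- s$km[s$km$group == g, ]
    tg <- cl$survival_time[lab[cl$sample_id] == g]
    emp <- vapply(km_g$time, function(t) mean(tg > t), numeric(1))
    expect_equal(km_g$surv, emp, tolerance = 1e-12)
  }
})

test_that("groups with zero events yield non-estimable hazard ratios", {
  cl <- data.frame(sample_id = sprintf("s%d", 1:20),
                   survival_time = rep(c(2, 4, 6, 8, 10), 4),
                   event = rep(c(1, 0), c(10, 10)))
  lab <- setNames(rep(c("A", "B"), each = 10), cl$sample_id)
  expect_warning(s <- km_logrank(cl, lab, reference = "A"), "zero events")
  expect_true(is.na(s$hazard_ratios$hr[s$hazard_ratios$group == "B"]))
})

test_that("purity summaries flag the diluted subtype and ANOVA reacts", {
  co <- default_cohort()
  res <- purity_by_group(co$purity, co$true_subtype)
  expect_setequal(res$summary$group, paste0("S", 1:4))
  dil <- paste0("S", co$config$diluted_subtype)
  expect_equal(res$summary$group[which.min(res$summary$median)], dil)
  expect_lt(res$anova_p, 0.01)

  # single group: ANOVA skipped, summary still produced
  one <- purity_by_group(co$purity, setNames(rep("G", length(co$purity)),
                                             names(co$purity)))
  expect_true(is.na(one$anova_p))
  expect_equal(nrow(one$summary), 1L)
})

test_that("concordance is permutation-invariant, symmetric, and calibrated", {
  ids <- sprintf("s%03d", 1:300)
  a <- setNames(rep(c("1", "2"), each = 150), ids)
  expect_equal(concordance(a, a)$percent_agreement, 100)

  b <- setNames(ifelse(a == "1", "2", "1"), ids)
  expect_equal(concordance(a, b)$percent_agreement, 100)

  # symmetry and label renaming
  set.seed(81)
  x <- setNames(sample(c("p", "q", "r"), 300, replace = TRUE), ids)
  y <- setNames(sample(c("u", "v", "w"), 300, replace = TRUE), ids)
  expect_equal(concordance(x, y)$percent_agreement,
               concordance(y, x)$percent_agreement)
  y2 <- setNames(c(u = "Z1", v = "Z2", w = "Z3")[y], ids)
  expect_equal(concordance(x, y2)$percent_agreement,
               concordance(x, y)$percent_agreement)

  # independent labels: agreement near the best random matching baseline
  reps <- vapply(1:30, function(i) {
    xi <- sample(c("p", "q", "r"), 300, replace = TRUE)
    yi <- sample(c("u", "v", "w"), 300, replace = TRUE)
    names(xi) <- names(yi) <- ids
    concordance(xi, yi)$percent_agreement
  }, numeric(1))
  expect_lt(abs(mean(reps) / 100 - 1 / 3), 0.05)

  # semantic mapping override
  m <- concordance(a, b, mapping = c("1" = "1", "2" = "2"))
  expect_equal(m$percent_agreement, 0)
  expect_error(concordance(a, setNames(a, paste0("x", ids))), "shared")
})
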