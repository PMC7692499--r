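test_that("plurality voting and the confidence rule follow the definitions", {
  pc <- plurality_confidence(c(A = 800, B = 150, C = 50))
  expect_equal(pc$p1, 0.80)
  expect_equal(pc$p2, 0.15)
  expect_equal(pc$confidence, 0.80 / 0.15)
  expect_identical(pc$call, "A")

  # confidence exactly 3 is ambiguous ("greater than 3" is strict)
  pc3 <- plurality_confidence(c(A = 600, B = 200, C = 200))
  expect_equal(pc3$confidence, 3)
  expect_identical(pc3$call, "ambiguous")

  # unanimity: p2 = 0, confidence infinite, confident call
  pcu <- plurality_confidence(c(A = 1000, B = 0))
  expect_equal(pcu$confidence, Inf)
  expect_identical(pcu$call, "A")

  # exact top tie: confidence 1, ambiguous
  pct <- plurality_confidence(c(A = 500, B = 500))
  expect_equal(pct$confidence, 1)
  expect_identical(pct$call, "ambiguous")

  # scale-free in the counts
  a <- plurality_confidence(c(A = 8, B = 3, C = 1))
  b <- plurality_confidence(c(A = 800, B = 300, C = 100))
  expect_identical(a$call, b$call)
  expect_equal(a$confidence, b$confidence)

  expect_error(plurality_confidence(c(A = 0, B = 0)), "at least one vote")
})

test_that("plurality voting matches a brute-force oracle on random votes", {
  brute <- function(v, cutoff = 3) {
    tot <- sum(v)
    s <- sort(v, decreasing = TRUE)
    p1 <- unname(s[1] / tot)
    p2 <- if (length(s) > 1) unname(s[2] / tot) else 0
    conf <- if (p2 == 0) Inf else p1 / p2
    list(call = if (conf > cutoff) names(s)[1] else "ambiguous",
         p1 = p1, p2 = p2, conf = conf)
  }
  set.seed(61)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    v <- setNames(rpois(k, lambda = sample(c(1, 5, 50), 1)), LETTERS[1:k])
    if (i %% 7 == 0) v[2] <- v[1]       # force exact top ties
    if (i %% 11 == 0) v[-1] <- 0        # force p2 = 0
    if (sum(v) == 0) v[1] <- 1
    got <- plurality_confidence(v)
    want <- brute(v)
    expect_identical(got$call, want$call)
    expect_equal(got$p1, want$p1)
    expect_equal(got$p2, want$p2)
    expect_equal(got$confidence, want$conf)
  }
})

test_that("cross-fitting never trains on the predicted fold and stays stratified", {
  co <- default_cohort()
  etc <- default_crossfit()
  dbu_lab <- call_labels(default_dbu()$consensus)
  expect_setequal(etc$calls$sample_id, colnames(co$expression))
  # every sample has a fold, folds partition the cohort
  expect_true(all(etc$fold %in% 1:4))
  # stratification: every class appears in every fold's training complement
  labeled <- names(dbu_lab)[dbu_lab != "ambiguous"]
  for (f in 1:4) {
    train_classes <- unique(dbu_lab[labeled[etc$fold[labeled] != f]])
    expect_setequal(train_classes, sort(unique(dbu_lab[labeled])))
  }
  # every sample receives one vote per dictionary entry
  expect_true(all(etc$calls$n_models_voting ==
                    length(default_filtered_dictionary()$entries)))
})

test_that("cross-fitting is invariant to sample order under a fixed seed", {
  tb <- two_blob_expr(n_per = 40, n_genes = 60)
  lab <- setNames(as.character(tb$labels), colnames(tb$expr))
  dic <- structure(list(entries = list(rownames(tb$expr)[1:20],
                                       rownames(tb$expr)[41:60]),
                        cv_accuracy = c(1, 1)),
                   class = "model_dictionary")
  a <- crossfit_calls(tb$expr, lab, dic, seed = 3)
  perm <- sample(ncol(tb$expr))
  b <- crossfit_calls(tb$expr[, perm], lab, dic, seed = 3)
  bb <- b$calls[match(a$calls$sample_id, b$calls$sample_id), ]
  expect_identical(a$calls$call, bb$call)
  expect_equal(a$calls$p1, bb$p1)
})

test_that("the final ensemble round-trips through JSON and predicts sanely", {
  co <- default_cohort()
  dic <- default_filtered_dictionary()
  dbu_lab <- default_dbu()$consensus
  model <- fit_final(co$expression, dbu_lab, dic, seed = 7)
  expect_length(model$entries, length(dic$entries))
  for (i in c(1L, length(model$entries))) {
    expect_identical(model$entries[[i]]$genes, dic$entries[[i]])
  }
  pred <- predict(model, co$expression)
  # training-cohort accuracy at least mean CV accuracy - 0.02
  lab <- call_labels(dbu_lab)
  ok <- pred$calls$call != "ambiguous" & lab[pred$calls$sample_id] != "ambiguous"
  acc <- mean(pred$calls$call[ok] == lab[pred$calls$sample_id][ok])
  expect_gte(acc, mean(dic$cv_accuracy) - 0.02)

  path <- withr::local_tempfile(fileext = ".json")
  etc_model_to_json(model, path)
  model2 <- etc_model_from_json(path)
  pred2 <- predict(model2, co$expression)
  expect_identical(pred$calls, pred2$calls)
})

test_that("a single-entry ensemble reduces to its one classifier", {
  tb <- two_blob_expr(n_per = 30, n_genes = 40)
  lab <- setNames(as.character(tb$labels), colnames(tb$expr))
  dic <- structure(list(entries = list(rownames(tb$expr)),
                        cv_accuracy = 1),
                   class = "model_dictionary")
  model <- fit_final(tb$expr, lab, dic)
  pred <- predict(model, tb$expr)
  expect_true(all(pred$calls$confidence == Inf))
  expect_true(all(pred$calls$call != "ambiguous"))
})

test_that("external prediction with all genes present equals plain prediction", {
  co <- default_cohort()
  dic <- default_filtered_dictionary()
  model <- fit_final(co$expression, default_dbu()$consensus, dic, seed = 7)
  pe <- predict_external(model, co$expression, co$expression,
                         default_dbu()$consensus)
  expect_equal(attr(pe, "n_refit"), 0L)
  expect_equal(attr(pe, "n_excluded"), 0L)
  pp <- predict(model, co$expression)
  expect_identical(pe$calls$call, pp$calls$call)
  expect_false(is.null(attr(pe, "mean_confidence_by_class")))

  # too-divergent platform: fewer than half the signature genes
  tiny <- co$expression[model$signature_genes[1:3], , drop = FALSE]
  attr(tiny, "standardized") <- TRUE
  expect_error(predict_external(model, tiny, co$expression,
                                default_dbu()$consensus), "50%")
})
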