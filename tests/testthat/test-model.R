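# Shared synthetic modeling fixture: planted complexes -> pulldowns -> WMM
# features -> leak-free labels.
model_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    tr <- make_planted_complexes(20, c(3, 8), 0.1, seed = 101)
    obs <- simulate_pulldowns(tr, 6, 0.8, 0.01, 25, seed = 102)
    feats <- compute_wmm(obs, min_pair_count = 0L)
    names(feats)[3:4] <- c("wmm_paircount", "wmm_negln")
    red <- reduce_redundancy(tr$complexes)
    sp <- split_benchmark(red, seed = 103)
    cache <<- list(truth = tr, feats = feats, split = sp)
    cache
  }
})

test_that("assemble_training keeps positives and subsamples negatives deterministically", {
  fx <- model_fixture()
  gold <- fx$split$train
  lab <- assemble_training(fx$feats, gold, n_negatives = 50, seed = 1)
  expect_identical(nrow(lab), nrow(gold$positives) + 50L)
  expect_identical(sum(lab$label == 1), nrow(gold$positives))
  lab2 <- assemble_training(fx$feats, gold, n_negatives = 50, seed = 1)
  expect_identical(lab, lab2)
  lab3 <- assemble_training(fx$feats, gold, n_negatives = 50, seed = 2)
  expect_false(identical(lab, lab3))
  # requesting more negatives than exist: all used, with a warning
  expect_warning(
    all_neg <- assemble_training(fx$feats, gold, n_negatives = 10000000, seed = 1),
    "negatives available")
  expect_identical(nrow(all_neg), nrow(gold$positives) + nrow(gold$negatives))
  expect_error(assemble_training(fx$feats, list(positives = gold$positives[0, ],
                                                negatives = gold$negatives)),
               "no positive")
})

test_that("imputation zero-fills with observed indicators", {
  tab <- data.frame(id_a = c("A", "A"), id_b = c("B", "C"),
                    f1 = c(1.5, NA))
  out <- impute_missing(tab)
  expect_identical(out$f1, c(1.5, 0))
  expect_identical(out$obs_f1, c(1, 0))
})

test_that("a separable problem trains to perfect training AUPRC; single class errors", {
  fx <- model_fixture()
  lab <- assemble_training(fx$feats, fx$split$train, n_negatives = 200, seed = 5)
  model <- train_classifier(lab, backend = "glmnet", seed = 5)
  scores <- score_all_pairs(model, lab)
  pr <- precision_recall(scores, fx$split$train)
  expect_gte(auprc(pr), 0.99)
  expect_true(all(scores$score >= 0 & scores$score <= 1))
  lab1 <- lab[lab$label == 1, ]
  expect_error(train_classifier(lab1), "both classes")
})

test_that("frozen models give identical scores after save/load and reject bad schemas", {
  fx <- model_fixture()
  lab <- assemble_training(fx$feats, fx$split$train, n_negatives = 100, seed = 7)
  model <- train_classifier(lab, seed = 7)
  s1 <- score_all_pairs(model, lab)
  d <- withr::local_tempdir()
  save_model(model, file.path(d, "m"))
  thawed <- load_model(file.path(d, "m"))
  s2 <- score_all_pairs(thawed, lab)
  expect_identical(s1, s2)
  s3 <- score_all_pairs(model, lab)
  expect_identical(s1, s3)
  bad <- lab; bad$wmm_negln <- NULL
  expect_error(score_all_pairs(model, bad), "schema mismatch")
})

test_that("PR analysis matches exhaustive threshold-by-threshold hand computation", {
  # 10-pair worked example, scores with ties
  truth <- list(
    positives = data.frame(id_a = c("a", "b", "c", "d"),
                           id_b = c("p", "p", "p", "p")),
    negatives = data.frame(id_a = c("e", "f", "g", "h", "i", "j"),
                           id_b = c("p", "p", "p", "p", "p", "p")))
  scores <- data.frame(id_a = letters[1:10], id_b = rep("p", 10),
                       score = c(0.9, 0.8, 0.8, 0.4, 0.85, 0.6, 0.4, 0.3,
                                 0.2, 0.1))
  pr <- precision_recall(scores, truth)
  # hand enumeration over distinct thresholds {0.9,0.85,0.8,0.6,0.4,0.3,0.2,0.1}
  lab <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  sc <- scores$score
  expected <- t(vapply(sort(unique(sc), decreasing = TRUE), function(t) {
    sel <- sc >= t
    c(precision = sum(lab[sel]) / sum(sel), recall = sum(lab[sel]) / sum(lab))
  }, c(precision = 0, recall = 0)))
  expect_equal(pr$precision, unname(expected[, "precision"]))
  expect_equal(pr$recall, unname(expected[, "recall"]))
  expect_true(all(diff(pr$recall) >= 0))
  auprc_hand <- sum(diff(c(0, expected[, "recall"])) * expected[, "precision"])
  expect_equal(auprc(pr), auprc_hand, tolerance = 1e-12)
})

test_that("PR endpoints behave analytically", {
  truth <- list(positives = data.frame(id_a = c("a", "b"), id_b = c("x", "y")),
                negatives = data.frame(id_a = c("c", "d", "e", "f"),
                                       id_b = c("x", "y", "x", "y")))
  perfect <- data.frame(id_a = c("a", "b", "c", "d", "e", "f"),
                        id_b = c("x", "y", "x", "y", "x", "y"),
                        score = c(1, 1, 0, 0, 0, 0))
  expect_equal(auprc(precision_recall(perfect, truth)), 1.0)
  constant <- perfect; constant$score <- 0.5
  pr <- precision_recall(constant, truth)
  expect_equal(auprc(pr), 2 / 6, tolerance = 1e-12)
  expect_equal(pr$recall[nrow(pr)], 1)
  # unscored truth pairs enter at score zero and are counted
  partial <- perfect[1:4, ]
  pr2 <- precision_recall(partial, truth)
  expect_identical(attr(pr2, "n_unscored"), 2L)
})

test_that("score-bin precision table flags empty bins and nails pure bins", {
  truth <- list(positives = data.frame(id_a = c("a", "b"), id_b = c("x", "x")),
                negatives = data.frame(id_a = c("c", "d"), id_b = c("x", "x")))
  scores <- data.frame(id_a = c("a", "b", "c", "d"), id_b = rep("x", 4),
                       score = c(0.95, 0.92, 0.05, 0.08))
  tab <- score_vs_precision_table(scores, truth, bins = seq(0, 1, 0.1))
  expect_equal(tab$precision[tab$bin_lo == 0.9], 1)
  expect_equal(tab$precision[tab$bin_lo == 0.0], 0)
  mid <- tab[tab$bin_lo == 0.5, ]
  expect_true(mid$empty)
  expect_true(is.na(mid$precision))
})

test_that("permutation importance separates signal from noise and is seeded", {
  fx <- model_fixture()
  lab <- assemble_training(fx$feats, fx$split$train, n_negatives = 150, seed = 9)
  set.seed(11)
  lab$noise <- rnorm(nrow(lab))
  model <- train_classifier(lab, seed = 9)
  imp <- permutation_importance(model, lab, fx$split$train, n_repeats = 5,
                                seed = 13)
  noise_row <- imp[imp$feature == "noise", ]
  signal_row <- imp[imp$feature == "wmm_negln", ]
  expect_lt(abs(noise_row$importance), 0.02)
  expect_gt(signal_row$importance, noise_row$importance)
  imp2 <- permutation_importance(model, lab, fx$split$train, n_repeats = 5,
                                 seed = 13)
  expect_identical(imp, imp2)
})

test_that("duplicated informative features share importance away", {
  fx <- model_fixture()
  lab <- assemble_training(fx$feats, fx$split$train, n_negatives = 150, seed = 15)
  lab$wmm_negln_copy <- lab$wmm_negln
  model <- train_classifier(lab, seed = 15)
  imp <- permutation_importance(model, lab, fx$split$train, n_repeats = 5,
                                seed = 15)
  # with a redundant copy present, shuffling either column individually
  # costs little: the twin still carries the signal
  expect_lt(imp$importance[imp$feature == "wmm_negln"], 0.05)
  expect_lt(imp$importance[imp$feature == "wmm_negln_copy"], 0.05)
})

test_that("feature-group ablation zeroes exactly the named columns", {
  tab <- data.frame(id_a = "A", id_b = "B", f1 = 3, f2 = 4)
  expect_identical(ablate_feature_groups(tab, list()), tab)
  out <- ablate_feature_groups(tab, list(grp = "f1"))
  expect_identical(out$f1, 0)
  expect_identical(out$f2, 4)
  all_zero <- ablate_feature_groups(tab, list(g = c("f1", "f2")))
  expect_true(all(all_zero$f1 == 0, all_zero$f2 == 0))
  expect_error(ablate_feature_groups(tab, list(g = "nope")), "unknown feature")
})

test_that("ablating the only informative group collapses held-out performance", {
  fx <- model_fixture()
  lab <- assemble_training(fx$feats, fx$split$train, n_negatives = 200, seed = 17)
  model <- train_classifier(lab, seed = 17)
  test_tab <- impute_missing(fx$feats)
  intact <- auprc(precision_recall(score_all_pairs(model, test_tab),
                                   fx$split$test))
  ablated_tab <- ablate_feature_groups(test_tab,
                                       list(wmm = c("wmm_negln", "wmm_paircount")))
  ablated <- auprc(precision_recall(score_all_pairs(model, ablated_tab),
                                    fx$split$test))
  expect_gt(intact, ablated)
})
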