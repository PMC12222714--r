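test_that("bicor hits the exact limits and is affine-invariant and symmetric", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(bicor(x, 2 * x + 1), 1)
  expect_equal(bicor(x, -x), -1)
  set.seed(3)
  a <- rnorm(60); b <- a + rnorm(60, sd = 0.4)
  expect_equal(as.numeric(bicor(a, b)), as.numeric(bicor(b, a)))
  expect_equal(as.numeric(bicor(3 * a + 2, 0.5 * b - 7)),
               as.numeric(bicor(a, b)), tolerance = 1e-12)
  expect_true(abs(bicor(a, b)) <= 1)
  expect_true(is.na(bicor(c(1, 2), c(3, 4))))
})

test_that("bicor tracks Pearson on clean Gaussians but resists one outlier", {
  set.seed(17)
  gaps <- replicate(20, {
    z <- matrix(rnorm(1000), ncol = 2) %*% chol(matrix(c(1, 0.6, 0.6, 1), 2))
    abs(as.numeric(bicor(z[, 1], z[, 2])) - cor(z[, 1], z[, 2]))
  })
  expect_lt(max(gaps), 0.05)
  # one extreme outlier swings Pearson but barely moves bicor
  set.seed(19)
  x <- rnorm(30); y <- x + rnorm(30, sd = 0.3)
  r0 <- cor(x, y); b0 <- as.numeric(bicor(x, y))
  xo <- c(x, 30); yo <- c(y, -30)
  expect_gt(abs(cor(xo, yo) - r0), 0.3)
  expect_lt(abs(as.numeric(bicor(xo, yo)) - b0), 0.1)
})

test_that("bicor falls back to Pearson on zero-MAD input, flagged", {
  x <- c(rep(1, 9), 2)   # MAD 0
  y <- seq_len(10)
  r <- bicor(x, y)
  expect_identical(attr(r, "fallback"), "pearson")
  expect_equal(as.numeric(r), cor(x, y))
})

expr_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tr <- make_planted_complexes(40, c(4, 8), 0, seed = 201,
                                   n_me_pairs = 12, n_sc_pairs = 12)
      ex <- simulate_expression(tr, 8, 15, "anticorrelated", noise_sd = 0.3,
                                seed = 202)
      cache <<- list(truth = tr, expr = ex)
    }
    cache
  }
})

test_that("sub-score 1 follows the generator's planted correlations", {
  fx <- expr_fixture()
  me <- fx$truth$me_pairs[1, ]
  expect_lte(allin_sub1(fx$expr, c(me$id_a, me$id_b)), -0.9)
  sc <- fx$truth$sc_pairs[1, ]
  expect_gte(allin_sub1(fx$expr, c(sc$id_a, sc$id_b)), 0.9)
  # identical profiles: exactly 1
  m <- matrix(rep(rnorm(20, sd = 2), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("p", "q"), sprintf("c%02d", 1:20)))
  em <- as_expression_matrix(m, setNames(rep(c("L1", "L2"), each = 10),
                                         colnames(m)))
  expect_equal(allin_sub1(em, c("p", "q")), 1)
  # fewer than 3 shared lines: missing
  m2 <- m; m2["q", 3:20] <- NA
  em2 <- as_expression_matrix(m2, attr(em, "lineage"))
  expect_true(is.na(allin_sub1(em2, c("p", "q"))))
})

test_that("sub-score 2 matches hand-averaged lineage means on a toy", {
  vals_p <- c(1, 3, 10, 14, 5, 7)   # lineage means: 2, 12, 6
  vals_q <- c(2, 2, 8, 8, 4, 4)     # lineage means: 2, 8, 4
  m <- rbind(p = vals_p, q = vals_q)
  colnames(m) <- sprintf("c%d", 1:6)
  em <- as_expression_matrix(m, setNames(rep(c("L1", "L2", "L3"), each = 2),
                                         colnames(m)))
  got <- allin_sub2(em, c("p", "q"))
  expected <- as.numeric(bicor(c(2, 12, 6), c(2, 8, 4)))
  expect_equal(got, expected)
  # a lineage with < 2 detected lines for a protein yields a missing mean
  m3 <- m; m3["p", 5] <- NA
  em3 <- as_expression_matrix(m3, attr(em, "lineage"))
  expect_true(is.finite(allin_sub2(em3, c("p", "q"))) ||
                is.na(allin_sub2(em3, c("p", "q"))))
})

test_that("sub-score 3 is directional, seeded, and guards its preconditions", {
  fx <- expr_fixture()
  cx <- fx$truth$complexes[[which(vapply(fx$truth$complexes, function(c)
    !any(c %in% c(fx$truth$me_pairs$id_a, fx$truth$me_pairs$id_b)), TRUE))[1]]]
  pair_same <- c(cx[1], cx[1])
  # a protein against itself: top-vs-bottom difference must be large positive
  v <- allin_sub3(fx$expr, pair_same, seed = 7)
  expect_gt(v, 0)
  v2 <- allin_sub3(fx$expr, pair_same, seed = 7)
  expect_identical(v, v2)
  # lineage-exclusive ME pairs: A's abundance is low (imputed) exactly where
  # B is high, so the difference score is strongly negative
  trx <- make_planted_complexes(20, c(4, 6), 0, seed = 211, n_me_pairs = 6)
  exl <- simulate_expression(trx, 8, 15, "lineage_exclusive", noise_sd = 0.2,
                             seed = 212)
  me_vals <- vapply(seq_len(nrow(trx$me_pairs)), function(r) {
    allin_sub3(exl, c(trx$me_pairs$id_a[r], trx$me_pairs$id_b[r]), seed = 5)
  }, 0)
  expect_lt(mean(me_vals), 0)
  # detection floor: protein observed in < min_detect lines is missing
  sparse <- exl
  expect_true(is.na(allin_sub3(sparse, c(trx$me_pairs$id_a[1],
                                         trx$me_pairs$id_b[1]),
                               min_detect = 1000, seed = 1)))
  expect_error(allin_sub3(fx$expr, pair_same, n_extreme = 10000), "n_extreme")
})

test_that("sub-score 4 contrasts lineage-coherent and lineage-swapped pairs", {
  fx <- expr_fixture()
  cx <- fx$truth$complexes[[which(vapply(fx$truth$complexes, function(c)
    length(c) >= 6 && !any(c %in% c(fx$truth$me_pairs$id_a,
                                    fx$truth$me_pairs$id_b)), TRUE))[1]]]
  coherent <- allin_sub4(fx$expr, cx[1:2], cx)
  expect_gt(coherent, 0.5)
  # ME pair inside its complex: anti-correlated member flips the vector
  me_cx_idx <- which(vapply(fx$truth$complexes, function(c)
    fx$truth$me_pairs$id_a[1] %in% c && length(c) >= 5, TRUE))
  if (length(me_cx_idx) > 0) {
    me_cx <- fx$truth$complexes[[me_cx_idx[1]]]
    v <- allin_sub4(fx$expr, c(fx$truth$me_pairs$id_a[1],
                               fx$truth$me_pairs$id_b[1]), me_cx)
    expect_lt(v, 0)
  }
  expect_true(is.na(allin_sub4(fx$expr, cx[1:2], cx[1:4])))  # < 3 others
})

test_that("allin_combine z-scores, negates, and enforces the two-sub-score rule", {
  rec <- data.frame(id_a = sprintf("a%d", 1:5), id_b = sprintf("b%d", 1:5),
                    sub1 = c(-1, -0.5, 0, 0.5, 1),
                    sub2 = c(-0.8, -0.4, 0, 0.4, 0.8),
                    sub3 = c(NA, NA, NA, NA, NA),
                    sub4 = c(NA, 0.2, NA, 0.2, NA))
  out <- allin_combine(rec)
  expect_true(all(out$n_subscores >= 2))
  # the pair at the mean of every available sub-score lands at allin ~ 0
  mid <- out[out$id_a == "a3", ]
  expect_equal(mid$allin, 0, tolerance = 1e-12)
  # most-anticorrelated pair gets the highest score (reversal)
  expect_identical(out$id_a[which.max(out$allin)], "a1")
  # adding a constant to one sub-score leaves the ranking unchanged
  rec2 <- rec; rec2$sub2 <- rec2$sub2 + 100
  out2 <- allin_combine(rec2)
  expect_identical(order(out$allin), order(out2$allin))
  # permuting rows permutes, not changes, the scores
  rec3 <- rec[c(3, 1, 5, 2, 4), ]
  out3 <- allin_combine(rec3)
  expect_equal(sort(out3$allin), sort(out$allin))
})

test_that("ALL-IN separates planted ME from SC pairs", {
  fx <- expr_fixture()
  tab <- allin_scores(fx$expr, fx$truth$complexes, seed = 7)
  key <- paste(tab$id_a, tab$id_b)
  me_key <- paste(fx$truth$me_pairs$id_a, fx$truth$me_pairs$id_b)
  sc_key <- paste(fx$truth$sc_pairs$id_a, fx$truth$sc_pairs$id_b)
  me <- tab$allin[key %in% me_key]
  sc <- tab$allin[key %in% sc_key]
  expect_gte(length(me), 10)
  expect_gt(mean(me), mean(sc))
  auroc <- mean(outer(me, sc, ">")) + 0.5 * mean(outer(me, sc, "=="))
  expect_gte(auroc, 0.9)
})

test_that("Jaccard Interactome score follows its set arithmetic", {
  net <- data.frame(
    id_a = c("A", "A", "A", "B", "B", "B", "B", "A"),
    id_b = c("P1", "P2", "P3", "P2", "P3", "P4", "A", "Q1"),
    score = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9, 0.95, 0.5))
  # A's partners at >= 0.8 (excluding B): P1 P2 P3; B's: P2 P3 P4 -> 2/4
  expect_equal(jaccard_interactome(net, c("A", "B")), 0.5)
  ident <- data.frame(id_a = rep(c("A", "B"), each = 3),
                      id_b = rep(c("P1", "P2", "P3"), 2), score = 0.9)
  expect_equal(jaccard_interactome(ident, c("A", "B")), 1)
  disjoint <- data.frame(id_a = rep(c("A", "B"), each = 3),
                         id_b = c("P1", "P2", "P3", "Q1", "Q2", "Q3"),
                         score = 0.9)
  expect_equal(jaccard_interactome(disjoint, c("A", "B")), 0)
  expect_true(is.na(jaccard_interactome(net, c("A", "B"), min_partners = 5)))
})

test_that("complex covariation summaries apply the published filters", {
  map <- as_map(list(c("A", "B", "C", "D"), c("X", "Y", "Z"),
                     c("E", "F", "G", "H")), tier = c(1L, 1L, 5L))
  prs <- t(combn(c("A", "B", "C", "D"), 2))
  cov <- data.frame(id_a = prs[, 1], id_b = prs[, 2],
                    score = c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7))
  out <- complex_covariation_summary(map, cov, min_size = 4, max_tier = 4)
  # the 3-complex is too small, the tier-5 complex too low, no coverage for EFGH
  expect_identical(out$cluster_id, "C001")
  expect_equal(out$median_covariation, 0.7)
  cov2 <- cov; cov2$score <- c(0.1, 0.2, 0.3, 0.8, 0.9, 0.55)
  out2 <- complex_covariation_summary(map, cov2, min_size = 4)
  expect_equal(out2$median_covariation[out2$cluster_id == "C001"],
               median(cov2$score))
})

test_that("thresholded Pearson matches a hand-filtered computation", {
  a <- c(0.9, 0.8, 0.1, 0.5, 0.05, 0.7, 0.3, 0.25, 0.6, 0.15)
  b <- c(0.85, 0.6, 0.9, 0.4, 0.02, 0.65, 0.1, 0.3, 0.55, 0.05)
  keep <- a >= 0.2 & b >= 0.2
  expect_equal(thresholded_pearson(a, b), cor(a[keep], b[keep]))
  expect_equal(thresholded_pearson(a, a), 1)
  low <- rep(0.05, 10)
  r <- thresholded_pearson(low, low)
  expect_true(is.na(r))
  expect_identical(attr(r, "flag"), "no_pairs_above_floor")
})
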