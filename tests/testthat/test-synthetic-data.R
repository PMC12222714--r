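test_that("planted complexes respect size bounds, counts, and determinism", {
  one <- make_planted_complexes(1, c(3, 3), 0, seed = 7)
  expect_length(one$complexes, 1L)
  expect_length(one$complexes[[1L]], 3L)

  tr <- make_planted_complexes(20, c(3, 8), 0.2, seed = 1)
  expect_length(tr$complexes, 20L)
  expect_true(all(lengths(tr$complexes) >= 3 & lengths(tr$complexes) <= 8))

  tr2 <- make_planted_complexes(20, c(3, 8), 0.2, seed = 1)
  expect_identical(tr, tr2)

  expect_error(make_planted_complexes(0, c(3, 8)), "n_complexes")
  expect_error(make_planted_complexes(3, c(1, 4)), "size_range")
})

test_that("overlap_fraction plants shared subunits", {
  tr <- make_planted_complexes(40, c(3, 6), 0.5, seed = 9)
  counts <- table(unlist(tr$complexes))
  expect_gt(sum(counts > 1), 0)
  none <- make_planted_complexes(40, c(3, 6), 0, seed = 9)
  expect_true(all(table(unlist(none$complexes)) == 1))
})

test_that("ME/SC pair flags are within-complex and protein-disjoint", {
  tr <- make_planted_complexes(40, c(4, 8), 0, seed = 3,
                               n_me_pairs = 10, n_sc_pairs = 10)
  flagged <- rbind(tr$me_pairs, tr$sc_pairs)
  ids <- c(flagged$id_a, flagged$id_b)
  expect_false(any(duplicated(ids)))
  co_complex <- function(a, b) any(vapply(tr$complexes,
                                          function(cx) a %in% cx && b %in% cx,
                                          TRUE))
  expect_true(all(mapply(co_complex, flagged$id_a, flagged$id_b)))
})

test_that("pulldown edge cases follow detection parameters exactly", {
  tr <- make_planted_complexes(5, c(3, 5), 0, seed = 2)
  # perfect detection, no background: each experiment is its bait's complex
  obs <- simulate_pulldowns(tr, 2, detect_prob = 1, background_rate = 0,
                            n_background_proteins = 10, seed = 4)
  expect_true(is.logical(obs$presence))
  for (j in seq_len(ncol(obs$presence))) {
    present <- rownames(obs$presence)[obs$presence[, j]]
    matches <- vapply(tr$complexes, function(cx) setequal(present, cx), TRUE)
    expect_true(any(matches))
  }
  # zero detection: only the bait is present
  solo <- simulate_pulldowns(tr, 2, detect_prob = 0, background_rate = 0,
                             n_background_proteins = 0, seed = 4)
  expect_true(all(colSums(solo$presence) == 1))
  expect_error(simulate_pulldowns(tr, 2, detect_prob = 1.2), "detect_prob")
})

test_that("within-complex co-occurrence rate matches the binomial expectation", {
  # bait present always, each prey detected at 0.8: across many experiments
  # the observed prey-detection rate concentrates at detect_prob
  tr <- make_planted_complexes(25, c(4, 6), 0, seed = 5)
  obs <- simulate_pulldowns(tr, 40, detect_prob = 0.8, background_rate = 0.01,
                            n_background_proteins = 30, seed = 6)
  expect_gte(ncol(obs$presence), 1000L)
  member_of <- rep(seq_along(tr$complexes), lengths(tr$complexes))
  names(member_of) <- unlist(tr$complexes)
  rates <- numeric(0)
  for (j in seq_len(ncol(obs$presence))) {
    present <- rownames(obs$presence)[obs$presence[, j]]
    cx_members <- names(member_of)[member_of == member_of[[present[
      present %in% names(member_of)][1L]]]]
    rates <- c(rates, (sum(cx_members %in% present) - 1L) /
                 (length(cx_members) - 1L))
  }
  expect_lt(abs(mean(rates) - 0.8), 0.03)
})

test_that("expression generator gives exact correlations in the noiseless limit", {
  tr <- make_planted_complexes(10, c(4, 6), 0, seed = 11,
                               n_me_pairs = 3, n_sc_pairs = 3)
  ex <- simulate_expression(tr, 6, 10, "anticorrelated", noise_sd = 0, seed = 12)
  cx <- setdiff(tr$complexes[[which(vapply(tr$complexes, function(c)
    !any(c %in% c(tr$me_pairs$id_a, tr$me_pairs$id_b)), TRUE))[1L]]], character(0))
  expect_equal(cor(ex[cx[1L], ], ex[cx[2L], ]), 1.0, tolerance = 1e-12)
  me <- tr$me_pairs[1L, ]
  expect_equal(cor(ex[me$id_a, ], ex[me$id_b, ]), -1.0, tolerance = 1e-12)
  expect_error(simulate_expression(tr, 6, 10, "bogus"), "arg")
})

test_that("lineage-exclusive ME pairs share no observed cell line", {
  tr <- make_planted_complexes(10, c(4, 6), 0, seed = 21, n_me_pairs = 4)
  ex <- simulate_expression(tr, 8, 10, "lineage_exclusive", noise_sd = 0.2,
                            seed = 22)
  for (r in seq_len(nrow(tr$me_pairs))) {
    a <- ex[tr$me_pairs$id_a[r], ]
    b <- ex[tr$me_pairs$id_b[r], ]
    expect_identical(sum(is.finite(a) & is.finite(b)), 0L)
  }
  # missingness only where the lineage-support rule dictates: non-ME
  # proteins are fully observed
  flagged <- c(tr$me_pairs$id_a, tr$me_pairs$id_b)
  others <- setdiff(rownames(ex), flagged)
  expect_true(all(is.finite(ex[others, ])))
})

test_that("toy trimer geometry is as constructed, independent of the classifier", {
  # overlap: common-chain interface sets intersect in > 10 residues
  tri <- make_toy_trimer(TRUE, 32, seed = 5)
  sup <- superpose_on_common(tri)
  i1 <- interface_residues(sup$trimer$dimer_1)$chain_a
  i2 <- interface_residues(sup$trimer$dimer_2)$chain_a
  expect_gt(length(intersect(i1, i2)), 10)
  # disjoint faces: intersection exactly zero
  tri0 <- make_toy_trimer(FALSE, 32, seed = 6)
  sup0 <- superpose_on_common(tri0)
  j1 <- interface_residues(sup0$trimer$dimer_1)$chain_a
  j2 <- interface_residues(sup0$trimer$dimer_2)$chain_a
  expect_length(intersect(j1, j2), 0L)
  # the emitted rigid transform is recovered by superposition
  expect_lt(sup$rmsd, 1e-6)
  expect_lt(sup0$rmsd, 1e-6)
  # too short a common chain for two disjoint interfaces
  expect_error(make_toy_trimer(FALSE, 20), "too small")
  expect_silent(make_toy_trimer(TRUE, 20, seed = 1))
})

test_that("generators are byte-identical across repeated runs and leave RNG alone", {
  tr <- make_planted_complexes(6, c(3, 5), 0.1, seed = 8)
  set.seed(123)
  before <- runif(1)
  obs1 <- simulate_pulldowns(tr, 3, 0.7, 0.02, 15, seed = 9)
  set.seed(123)
  expect_identical(runif(1), before)
  obs2 <- simulate_pulldowns(tr, 3, 0.7, 0.02, 15, seed = 9)
  expect_identical(obs1, obs2)
  ex1 <- simulate_expression(tr, 4, 8, "anticorrelated", 0.3, seed = 10)
  ex2 <- simulate_expression(tr, 4, 8, "anticorrelated", 0.3, seed = 10)
  expect_identical(ex1, ex2)
  n1 <- simulate_scored_network(tr, seed = 13)
  n2 <- simulate_scored_network(tr, seed = 13)
  expect_identical(n1, n2)
})

test_that("fixture writers round-trip through their plain-text formats", {
  tr <- make_planted_complexes(5, c(3, 5), 0.2, seed = 31,
                               n_me_pairs = 2, n_sc_pairs = 1)
  d <- withr::local_tempdir()
  write_truth(tr, file.path(d, "truth.json"))
  tr2 <- read_truth(file.path(d, "truth.json"))
  expect_identical(lapply(tr$complexes, sort), lapply(tr2$complexes, identity))
  expect_identical(tr$me_pairs, tr2$me_pairs)

  obs <- simulate_pulldowns(tr, 3, 0.8, 0.05, 10, seed = 32)
  write_observations(obs, file.path(d, "obs.tsv"))
  obs2 <- read_observations(file.path(d, "obs.tsv"))
  expect_identical(obs$presence, obs2$presence)

  ex <- simulate_expression(tr, 4, 8, "lineage_exclusive", 0.2, seed = 33)
  write_expression(ex, file.path(d, "e.tsv"), file.path(d, "l.tsv"))
  ex2 <- read_expression(file.path(d, "e.tsv"), file.path(d, "l.tsv"))
  expect_equal(unclass(ex)[, ], unclass(ex2)[, ], tolerance = 1e-9)
  expect_identical(attr(ex, "lineage"), attr(ex2, "lineage"))
})
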