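# Shared fixtures and independent oracles used across test files.

# Exhaustive subset-pair enumeration oracle for the hypergeometric tail:
# draws every pair (A, B) of subsets of {1..N} with |A| = n, |B| = m and
# counts how often |A intersect B| >= k. Only feasible for N <= ~10.
enumerate_tail_prob <- function(k, n, m, N) {
  A_sets <- combn(N, n, simplify = FALSE)
  B_sets <- combn(N, m, simplify = FALSE)
  hits <- 0L
  for (A in A_sets) for (B in B_sets)
    if (length(intersect(A, B)) >= k) hits <- hits + 1L
  hits / (length(A_sets) * length(B_sets))
}

# Brute-force clique enumeration oracle for k-clique precision/recall on
# tiny instances: enumerates every unique s-subset on each side.
brute_kclique <- function(predicted, gold, weighting = "asymmetric") {
  contained <- function(members, sets)
    any(vapply(sets, function(s) all(members %in% s), TRUE))
  max_size <- max(c(lengths(predicted), lengths(gold)))
  per <- lapply(2:max_size, function(s) {
    cliques_of <- function(sets) {
      cl <- list()
      for (set in sets) {
        if (length(set) < s) next
        cb <- combn(sort(set), s, simplify = FALSE)
        cl <- c(cl, cb)
      }
      unique(lapply(cl, identity))
    }
    pc <- cliques_of(predicted)
    gc <- cliques_of(gold)
    data.frame(
      size = s,
      precision = if (length(pc)) mean(vapply(pc, contained, TRUE, gold)) else NA,
      recall = if (length(gc)) mean(vapply(gc, contained, TRUE, predicted)) else NA,
      w_pred = sum(lengths(predicted) >= s),
      w_gold = sum(lengths(gold) >= s))
  })
  per <- do.call(rbind, per)
  okp <- !is.na(per$precision) & per$w_pred > 0
  okr <- !is.na(per$recall) & per$w_gold > 0
  list(per_size = per,
       precision = sum(per$precision[okp] * per$w_pred[okp]) / sum(per$w_pred[okp]),
       recall = sum(per$recall[okr] * per$w_gold[okr]) / sum(per$w_gold[okr]))
}

# Tiny deterministic observation matrix used by several WMM tests.
toy_obs <- function() {
  m <- matrix(FALSE, 5, 6,
              dimnames = list(paste0("P", 1:5), paste0("E", 1:6)))
  m["P1", c(1, 2, 3)] <- TRUE
  m["P2", c(1, 2, 4)] <- TRUE
  m["P3", c(2, 3, 5, 6)] <- TRUE
  m["P4", c(4, 5)] <- TRUE
  m["P5", 6] <- TRUE
  as_obs_matrix(m)
}

# A complex map wrapper for plain cluster lists.
as_map <- function(clusters, tier = rep(1L, length(clusters))) {
  structure(list(clusters = lapply(clusters, sort), tier = tier,
                 cluster_id = sprintf("C%03d", seq_along(clusters)),
                 provenance = list()),
            class = "complex_map")
}
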