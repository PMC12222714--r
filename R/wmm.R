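# Weighted matrix model (WMM) co-occurrence features. Two proteins seen in n
# and m of N experiments, sharing k, are scored by the upper tail of the
# hypergeometric distribution:
#
#   p(#shared >= k | n, m, N) = sum_{i=k}^{min(n,m)} C(n,i) C(N-n, m-i) / C(N,m)
#
# evaluated in log space (log-gamma binomials, shifted exponentiation of the
# tail terms) so that N in the tens of thousands never overflows. The feature
# pair emitted per protein pair is -ln(p) and the raw co-occurrence count.

log_choose <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

#' Hypergeometric upper-tail probability
#'
#' Probability that two random subsets of sizes `n` and `m` drawn from `N`
#' experiments share at least `k` experiments.
#'
#' @param k Observed shared-experiment count, `0 <= k <= min(n, m)`.
#' @param n,m Per-protein experiment counts, each `<= N`.
#' @param N Total number of experiments (>= 1).
#' @return The tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(k, n, m, N) {
  for (v in list(k = k, n = n, m = m, N = N))
    assert_that(is.numeric(v) && length(v) == 1L && is.finite(v) && v == floor(v),
                "k, n, m, N must be single integers")
  if (N < 1) stop("N must be >= 1", call. = FALSE)
  if (n < 0 || m < 0 || n > N || m > N)
    stop(sprintf("n (%d) and m (%d) must lie in [0, N = %d]", n, m, N),
         call. = FALSE)
  if (k < 0 || k > min(n, m))
    stop(sprintf("k (%d) must lie in [0, min(n, m) = %d]", k, min(n, m)),
         call. = FALSE)
  if (k == 0) return(1)
  i <- seq.int(k, min(n, m))
  log_terms <- log_choose(n, i) + log_choose(N - n, m - i) - log_choose(N, m)
  mx <- max(log_terms)
  p <- exp(mx) * sum(exp(log_terms - mx))
  min(max(p, 0), 1)
}

#' Compute WMM co-occurrence features for all observed pairs
#'
#' For every unordered protein pair co-observed in at least `min_pair_count`
#' experiments, reports the pair count `k` and `-ln p(#shared >= k | n, m, N)`.
#' Pairs below the floor are omitted (their features are treated as missing
#' downstream); `min_pair_count = 0` enumerates all pairs, including never
#' co-observed ones at `-ln(1) = 0`.
#'
#' @param obs An `obs_matrix`.
#' @param min_pair_count Enumeration floor on the shared-experiment count.
#' @return Data frame `id_a`, `id_b`, `pair_count`, `neg_ln_pval`.
#' @export
compute_wmm <- function(obs, min_pair_count = 1L) {
  assert_that(inherits(obs, "obs_matrix"), "`obs` must be an obs_matrix")
  assert_count(min_pair_count, "min_pair_count")
  pres <- obs$presence
  assert_that(nrow(pres) >= 2L, "need at least two proteins")
  N <- ncol(pres)
  storage.mode(pres) <- "integer"
  counts <- rowSums(pres)
  shared <- tcrossprod(pres)          # k for every pair
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  k <- shared[idx]
  keep <- k >= min_pair_count
  idx <- idx[keep, , drop = FALSE]
  k <- k[keep]
  n <- counts[idx[, 1L]]
  m <- counts[idx[, 2L]]
  neg_ln <- vapply(seq_along(k), function(j) {
    p <- hypergeom_tail(k[j], n[j], m[j], N)
    if (p <= 0) 745 else -log(p)      # cap at ~ -log(.Machine$double.xmin)
  }, 0)
  ids <- rownames(pres)
  out <- canonicalize_pairs(data.frame(ids[idx[, 1L]], ids[idx[, 2L]]))
  out$pair_count <- as.integer(k)
  out$neg_ln_pval <- pmax(neg_ln, 0)
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gate observation presence on an auxiliary per-entry score
#'
#' Retains a presence call only where its auxiliary score (e.g., an abundance
#' Z-score) exceeds `score_cutoff`, so WMM feature variants can be computed at
#' several stringencies from one observation table.
#'
#' @param obs An `obs_matrix`. The score matrix defaults to the one attached
#'   at load time.
#' @param per_experiment_score Optional numeric matrix aligned with
#'   `obs$presence`; must cover every present entry.
#' @param score_cutoff Strict lower cutoff.
#' @return A new `obs_matrix` (pruned of now-absent proteins).
#' @export
threshold_observations <- function(obs, per_experiment_score = NULL,
                                   score_cutoff = 0) {
  assert_that(inherits(obs, "obs_matrix"), "`obs` must be an obs_matrix")
  score <- if (is.null(per_experiment_score)) obs$score else per_experiment_score
  assert_that(!is.null(score), "no per-entry score available for thresholding")
  missing_at <- obs$presence & is.na(score)
  if (any(missing_at)) {
    w <- which(missing_at, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing score for present entry (%s, %s)",
                 rownames(obs$presence)[w[1L]], colnames(obs$presence)[w[2L]]),
         call. = FALSE)
  }
  pres <- obs$presence & !is.na(score) & score > score_cutoff
  as_obs_matrix(pres, score = score)
}

#' Compute a multi-stringency WMM feature table
#'
#' Runs [compute_wmm()] at each score cutoff (plus the unthresholded matrix
#' when `include_raw`), naming columns `wmm_negln_<tag>` / `wmm_paircount_<tag>`
#' so several stringencies coexist in one feature table.
#'
#' @param obs An `obs_matrix` with attached scores (unless only raw requested).
#' @param cutoffs Numeric score cutoffs.
#' @param dataset_tag Tag embedded in feature names.
#' @param include_raw Also emit features from the unthresholded matrix.
#' @param min_pair_count Passed to [compute_wmm()].
#' @return Data frame `id_a`, `id_b`, feature columns; `NA` where a pair was
#'   not enumerated at a given stringency.
#' @export
wmm_feature_table <- function(obs, cutoffs = numeric(0), dataset_tag = "obs",
                              include_raw = TRUE, min_pair_count = 1L) {
  variants <- list()
  if (include_raw) variants[["raw"]] <- obs
  for (ct in cutoffs)
    variants[[paste0("z", gsub("[^0-9a-zA-Z]", "_", format(ct)))]] <-
      threshold_observations(obs, score_cutoff = ct)
  assert_that(length(variants) > 0L, "no WMM variant requested")
  tabs <- lapply(names(variants), function(tag) {
    w <- compute_wmm(variants[[tag]], min_pair_count = min_pair_count)
    names(w)[names(w) == "pair_count"] <-
      sprintf("wmm_paircount_%s_%s", dataset_tag, tag)
    names(w)[names(w) == "neg_ln_pval"] <-
      sprintf("wmm_negln_%s_%s", dataset_tag, tag)
    w
  })
  out <- Reduce(function(a, b) merge(a, b, by = c("id_a", "id_b"), all = TRUE),
                tabs)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}
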