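# Expression-based interpretation of complex maps. The ALL-IN score (Average
# celL Lineage co-expressIoN) combines four sub-scores computed over
# z-scored relative protein abundances across cell lines grouped into cancer
# lineages; high ALL-IN indicates likely mutual exclusivity. Robust
# correlation throughout is the biweight midcorrelation (bicor), which
# down-weights outliers with a bisquare kernel around the median.

#' Biweight midcorrelation
#'
#' Robust correlation with the standard tuning constant 9 on the
#' median-absolute-deviation scale; missing values are handled
#' pairwise-complete. A zero MAD in either vector (no spread around the
#' median) makes the bisquare weights degenerate, in which case the function
#' falls back to Pearson and flags it via the `"fallback"` attribute.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation in [-1, 1] (`NA` if fewer than 3 complete pairs).
#' @export
bicor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  weights_for <- function(v) {
    med <- median(v)
    m <- mad(v, constant = 1)
    if (m == 0) return(NULL)
    u <- (v - med) / (9 * m)
    w <- (1 - u^2)^2
    w[abs(u) >= 1] <- 0
    (v - med) * w
  }
  a <- weights_for(x); b <- weights_for(y)
  if (is.null(a) || is.null(b)) {
    r <- suppressWarnings(stats::cor(x, y))
    return(structure(r, fallback = "pearson"))
  }
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) return(NA_real_)
  max(-1, min(1, sum(a * b) / den))
}

expr_lineages <- function(expr) attr(expr, "lineage")

get_profile <- function(expr, protein) {
  assert_that(protein %in% rownames(expr),
              sprintf("protein %s absent from expression matrix", protein))
  as.numeric(expr[protein, ])
}

#' ALL-IN sub-score 1: robust correlation across all cell lines
#'
#' @param expr An `expression_matrix`.
#' @param pair Length-2 character vector of protein identifiers.
#' @return bicor over cell lines where both proteins are observed (`NA` if
#'   fewer than 3).
#' @export
allin_sub1 <- function(expr, pair) {
  as.numeric(bicor(get_profile(expr, pair[1L]), get_profile(expr, pair[2L])))
}

lineage_means <- function(expr, protein) {
  v <- get_profile(expr, protein)
  lin <- expr_lineages(expr)
  out <- tapply(v, lin, function(z) {
    z <- z[is.finite(z)]
    if (length(z) < 2L) NA_real_ else mean(z)   # <2 detected lines: missing
  })
  as.numeric(out[sort(unique(lin))])
}

#' ALL-IN sub-score 2: robust correlation of lineage-mean profiles
#'
#' Averaging within lineages removes the bias from lineages contributing
#' different numbers of cell lines.
#'
#' @inheritParams allin_sub1
#' @return bicor of the two lineage-mean vectors (`NA` with < 3 shared
#'   lineages or a single lineage).
#' @export
allin_sub2 <- function(expr, pair) {
  lin <- expr_lineages(expr)
  if (length(unique(lin)) < 2L) return(NA_real_)
  as.numeric(bicor(lineage_means(expr, pair[1L]), lineage_means(expr, pair[2L])))
}

#' ALL-IN sub-score 3: differential expression across detection extremes
#'
#' Captures very large abundance differences that correlations miss when one
#' protein drops below detection. Missing values (for proteins detected in at
#' least `min_detect` cell lines) are imputed from N(`impute_mean`,
#' `impute_sd`), reflecting that non-detection usually means low abundance.
#' For each direction, the score is the mean abundance of one protein in the
#' other's top `n_extreme` cell lines minus its mean in the bottom
#' `n_extreme` (ranking includes imputed values); the two directions are
#' averaged.
#'
#' @inheritParams allin_sub1
#' @param min_detect Minimum detected cell lines per protein.
#' @param impute_mean,impute_sd Imputation distribution (published: -4, 0.3).
#' @param n_extreme Cell lines per extreme (published: 50).
#' @param seed Integer seed for the imputation draw.
#' @return The averaged difference score (`NA` when either protein fails the
#'   detection floor).
#' @export
allin_sub3 <- function(expr, pair, min_detect = 50L, impute_mean = -4,
                       impute_sd = 0.3, n_extreme = 50L, seed = 1L) {
  n_lines <- ncol(expr)
  if (n_lines < n_extreme)
    stop(sprintf("only %d cell lines but n_extreme = %d", n_lines, n_extreme),
         call. = FALSE)
  a <- get_profile(expr, pair[1L]); b <- get_profile(expr, pair[2L])
  if (sum(is.finite(a)) < min_detect || sum(is.finite(b)) < min_detect)
    return(NA_real_)
  with_seed(seed, {
    fill <- function(v) {
      miss <- !is.finite(v)
      v[miss] <- rnorm(sum(miss), impute_mean, impute_sd)
      v
    }
    a <- fill(a); b <- fill(b)
    one_direction <- function(u, v) {
      # mean of u in v's top n_extreme lines minus its bottom n_extreme
      ord <- order(v, decreasing = TRUE)
      mean(u[ord[seq_len(n_extreme)]]) -
        mean(u[rev(ord)[seq_len(n_extreme)]])
    }
    (one_direction(a, b) + one_direction(b, a)) / 2
  })
}

#' ALL-IN sub-score 4: lineage-specific coherence with the rest of the complex
#'
#' For each protein of the pair, computes per-lineage the mean robust
#' correlation to the other complex subunits, then correlates the two
#' proteins' lineage vectors. Mutually exclusive subunits expressed
#' lineage-specifically correlate with the complex in different lineages,
#' driving this score negative.
#'
#' @inheritParams allin_sub1
#' @param complex_members All members of the complex containing the pair.
#' @param outer `"bicor"` (default) or `"pearson"` for the outer correlation.
#' @return Correlation of the two lineage-coherence vectors (`NA` with < 3
#'   informative lineages or < 3 other subunits... see details).
#' @export
allin_sub4 <- function(expr, pair, complex_members,
                       outer = c("bicor", "pearson")) {
  outer <- match.arg(outer)
  others <- setdiff(complex_members, pair)
  others <- others[others %in% rownames(expr)]
  if (length(others) < 3L) return(NA_real_)
  lin <- expr_lineages(expr)
  lineages <- sort(unique(lin))
  if (length(lineages) < 3L) return(NA_real_)
  coherence <- function(protein) {
    v <- get_profile(expr, protein)
    vapply(lineages, function(L) {
      sel <- lin == L
      cs <- vapply(others, function(o) {
        as.numeric(bicor(v[sel], get_profile(expr, o)[sel]))
      }, 0)
      cs <- cs[is.finite(cs)]
      if (length(cs) == 0L) NA_real_ else mean(cs)
    }, 0)
  }
  va <- coherence(pair[1L]); vb <- coherence(pair[2L])
  ok <- is.finite(va) & is.finite(vb)
  if (sum(ok) < 3L) return(NA_real_)
  if (outer == "bicor") as.numeric(bicor(va[ok], vb[ok]))
  else suppressWarnings(stats::cor(va[ok], vb[ok]))
}

#' Compute ALL-IN records for all within-complex pairs
#'
#' Evaluates the four sub-scores for every within-complex pair of the map
#' that has expression data, z-scores each sub-score across pairs, and
#' reports `allin` as the negated mean of the available z-scored sub-scores.
#' Pairs with fewer than two sub-scores are excluded.
#'
#' @param expr An `expression_matrix`.
#' @param map A `complex_map`, `complex_list`, or plain list of complexes.
#' @param seed Integer seed (sub-score 3 imputation).
#' @param sub3_args Optional overrides for [allin_sub3()] parameters.
#' @return Data frame `id_a`, `id_b`, `sub1..sub4`, `n_subscores`, `allin`.
#' @export
allin_scores <- function(expr, map, seed = 1L, sub3_args = list()) {
  complexes <- if (inherits(map, "complex_map")) map$clusters else map
  pairs <- list(); ctx <- list()
  seen <- character(0)
  for (cx in complexes) {
    members <- intersect(cx, rownames(expr))
    if (length(members) < 2L) next
    prs <- utils::combn(sort(members), 2L)
    for (j in seq_len(ncol(prs))) {
      key <- paste(prs[, j], collapse = "\t")
      if (key %in% seen) next
      seen <- c(seen, key)
      pairs[[length(pairs) + 1L]] <- prs[, j]
      ctx[[length(ctx) + 1L]] <- cx
    }
  }
  assert_that(length(pairs) > 0L, "no within-complex pairs with expression data")
  sub3_fun <- function(pair) {
    do.call(allin_sub3, c(list(expr = expr, pair = pair, seed = seed), sub3_args))
  }
  recs <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(id_a = p[1L], id_b = p[2L],
               sub1 = allin_sub1(expr, p),
               sub2 = allin_sub2(expr, p),
               sub3 = sub3_fun(p),
               sub4 = allin_sub4(expr, p, ctx[[i]]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  allin_combine(tab)
}

#' Combine sub-scores into the ALL-IN score
#'
#' Z-scores each sub-score column over the supplied pair population
#' (missing values ignored) and sets `allin` to the negated mean of the
#' available z-scored sub-scores; pairs with fewer than two available
#' sub-scores are dropped.
#'
#' @param records Data frame with `id_a`, `id_b`, `sub1`..`sub4`.
#' @return The records with `n_subscores` and `allin` columns, filtered to
#'   `n_subscores >= 2`.
#' @export
allin_combine <- function(records) {
  subs <- c("sub1", "sub2", "sub3", "sub4")
  subs <- subs[subs %in% names(records)]
  z <- sapply(subs, function(cl) {
    v <- records[[cl]]
    mu <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(ifelse(is.na(v), NA_real_, 0))
    (v - mu) / s
  })
  z <- matrix(z, nrow = nrow(records))
  records$n_subscores <- rowSums(!is.na(z))
  records$allin <- -rowMeans(z, na.rm = TRUE)
  out <- records[records$n_subscores >= 2L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Jaccard Interactome score of a protein pair
#'
#' Jaccard similarity of the two proteins' high-confidence partner sets in
#' the scored network (partners at score >= `conf_min`, excluding the pair
#' members themselves). Distinguishes genuine mutual exclusivity (shared
#' interactome, competing subunits) from spurious co-membership.
#'
#' @param net Scored network data frame.
#' @param pair Length-2 character vector.
#' @param min_partners Minimum qualifying partners per protein.
#' @param conf_min Partner confidence floor (published: 0.8, non-strict).
#' @return Jaccard in [0, 1], or `NA` when either partner set is too small.
#' @export
jaccard_interactome <- function(net, pair, min_partners = 3L, conf_min = 0.8) {
  hi <- net[net$score >= conf_min, , drop = FALSE]
  partners <- function(p) {
    setdiff(unique(c(hi$id_b[hi$id_a == p], hi$id_a[hi$id_b == p])), pair)
  }
  pa <- partners(pair[1L]); pb <- partners(pair[2L])
  if (length(pa) < min_partners || length(pb) < min_partners) return(NA_real_)
  jaccard(pa, pb)
}

#' Per-complex median covariation summary
#'
#' Median of the within-complex pairwise covariation scores among covered
#' subunits, after the published Fig.-style filters: complexes smaller than
#' `min_size`, in a worse tier than `max_tier`, or with less than
#' `min_coverage` of members covered by the covariation table are omitted.
#'
#' @param map A `complex_map`.
#' @param cov Pairwise covariation data frame `id_a`, `id_b`, `score`.
#' @param min_size Minimum complex size.
#' @param max_tier Worst (largest) confidence tier admitted.
#' @param min_coverage Minimum fraction of members with covariation data.
#' @return Data frame `cluster_id`, `tier`, `size`, `coverage`,
#'   `median_covariation`, `n_pairs`.
#' @export
complex_covariation_summary <- function(map, cov, min_size = 4L,
                                        max_tier = Inf, min_coverage = 0.5) {
  cov_key <- pair_key(cov$id_a, cov$id_b)
  cov_score <- setNames(cov$score, cov_key)
  covered <- unique(c(cov$id_a, cov$id_b))
  rows <- lapply(seq_along(map$clusters), function(i) {
    cx <- map$clusters[[i]]
    if (length(cx) < min_size || map$tier[i] > max_tier) return(NULL)
    in_cov <- intersect(cx, covered)
    coverage <- length(in_cov) / length(cx)
    if (coverage < min_coverage) return(NULL)
    if (length(in_cov) < 2L) return(NULL)
    prs <- utils::combn(sort(in_cov), 2L)
    scores <- cov_score[pair_key(prs[1L, ], prs[2L, ])]
    scores <- scores[!is.na(scores)]
    if (length(scores) == 0L) return(NULL)
    data.frame(cluster_id = map$cluster_id[i], tier = map$tier[i],
               size = length(cx), coverage = coverage,
               median_covariation = median(scores),
               n_pairs = length(scores), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(cluster_id = character(0), tier = integer(0),
                      size = integer(0), coverage = numeric(0),
                      median_covariation = numeric(0), n_pairs = integer(0))
  rownames(out) <- NULL
  out
}

#' Pearson correlation above a joint score floor
#'
#' Correlates two per-pair score vectors over the pairs where both scores
#' are at least `floor`, correcting for the mass of non-interacting,
#' non-covarying pairs near zero.
#'
#' @param scores_a,scores_b Numeric vectors, aligned by pair.
#' @param floor Joint threshold (published: 0.2).
#' @return Pearson correlation, or `NA` with attribute `flag =
#'   "no_pairs_above_floor"` when nothing survives.
#' @export
thresholded_pearson <- function(scores_a, scores_b, floor = 0.2) {
  keep <- is.finite(scores_a) & is.finite(scores_b) &
    scores_a >= floor & scores_b >= floor
  if (sum(keep) < 3L)
    return(structure(NA_real_, flag = "no_pairs_above_floor"))
  stats::cor(scores_a[keep], scores_b[keep])
}
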