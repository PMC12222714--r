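# Annotation enrichment of complexes against a background (hypergeometric
# upper tail, the same machinery as the WMM), an empirical shuffled-complex
# null, and guilt-by-association transfer of enriched terms to
# uncharacterized complex members.

#' Hypergeometric annotation enrichment for one complex
#'
#' For each term, tests overlap >= observed between the complex and the
#' term's members within the background universe, then applies
#' Benjamini-Hochberg correction within the annotation set. Terms annotating
#' exactly one complex member are excluded (a single protein cannot support
#' complex-level enrichment), as are terms on the `blocklist` (e.g. ontology
#' root terms).
#'
#' @param complex Character vector of member identifiers.
#' @param annotations An `annotation_set`.
#' @param background Character vector: the annotation universe (e.g. all
#'   proteins observed across the underlying experiments). Complex members
#'   outside it are logged and intersected away.
#' @param blocklist Term ids or term names never tested.
#' @return Data frame `term`, `term_name`, `k` (annotated members), `n`
#'   (term size in background), `p`, `q` (BH), ordered by `p`.
#' @export
enrich_complex <- function(complex, annotations, background,
                           blocklist = c("CORUM root", "REACTOME root term",
                                         "KEGG root term")) {
  complex <- unique(complex)
  outside <- setdiff(complex, background)
  if (length(outside) > 0L) {
    message(sprintf("%d complex member(s) outside background dropped: %s",
                    length(outside), paste(outside, collapse = ", ")))
    complex <- intersect(complex, background)
  }
  assert_that(length(complex) >= 1L, "no complex members inside background")
  N <- length(background)
  m <- length(complex)
  term_names <- attr(annotations, "term_name")
  rows <- lapply(names(annotations), function(tid) {
    if (tid %in% blocklist || term_names[[tid]] %in% blocklist) return(NULL)
    members <- intersect(annotations[[tid]], background)
    n <- length(members)
    if (n == 0L) return(NULL)
    k <- length(intersect(members, complex))
    if (k <= 1L) return(NULL)   # single annotated protein: excluded
    data.frame(term = tid, term_name = term_names[[tid]], k = k, n = n,
               p = hypergeom_tail(k, n, m, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(term = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), p = numeric(0),
                      q = numeric(0)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrich every complex of a map
#'
#' @param map A `complex_map`.
#' @inheritParams enrich_complex
#' @return Data frame with a `cluster_id` column prepended.
#' @export
enrich_map <- function(map, annotations, background,
                       blocklist = c("CORUM root", "REACTOME root term",
                                     "KEGG root term")) {
  rows <- lapply(seq_along(map$clusters), function(i) {
    e <- suppressMessages(enrich_complex(intersect(map$clusters[[i]], background),
                                         annotations, background, blocklist))
    if (nrow(e) == 0L) return(NULL)
    cbind(cluster_id = map$cluster_id[i], e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(cluster_id = character(0), term = character(0),
                      term_name = character(0), k = integer(0), n = integer(0),
                      p = numeric(0), q = numeric(0))
  rownames(out) <- NULL
  out
}

#' Shuffle a complex map preserving size and membership multisets
#'
#' Randomly reassigns protein ids to cluster ids while keeping the exact
#' cluster-size multiset and the exact per-protein membership counts, giving
#' the empirical null for enrichment calibration. Duplicate assignments
#' within a cluster are repaired by deterministic seeded swaps.
#'
#' @param map A `complex_map`.
#' @param seed Integer seed.
#' @return A shuffled `complex_map`.
#' @export
shuffle_complexes <- function(map, seed = 1L) {
  sizes <- lengths(map$clusters)
  slots <- rep(seq_along(sizes), sizes)
  proteins <- unlist(map$clusters, use.names = FALSE)
  with_seed(seed, {
    perm <- proteins[sample.int(length(proteins))]
    # repair duplicates within a cluster by swapping with another slot
    guard <- 0L
    repeat {
      dup <- which(duplicated(paste(slots, perm, sep = "\r")))
      if (length(dup) == 0L) break
      guard <- guard + 1L
      assert_that(guard < 10000L, "shuffle could not resolve duplicate memberships")
      i <- dup[1L]
      repeat {
        j <- sample.int(length(perm), 1L)
        if (slots[j] == slots[i]) next
        if (!(perm[j] %in% perm[slots == slots[i]]) &&
            !(perm[i] %in% perm[slots == slots[j]])) {
          tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
          break
        }
      }
    }
    clusters <- lapply(split(perm, slots), sort)
    names(clusters) <- NULL
    structure(list(clusters = clusters, tier = map$tier,
                   cluster_id = map$cluster_id, provenance = map$provenance),
              class = "complex_map")
  })
}

#' Guilt-by-association annotation transfer
#'
#' Transfers an enriched term to an uncharacterized complex member when all
#' three published rules hold: at least `share_min` of the complex members
#' carry the term, the term's corrected p-value is at most `p_max`, and the
#' receiving protein's annotation score is below `score_max` (UniProt-style
#' 1-5 scale, < 4 = understudied). The receiving protein counts in the
#' share denominator.
#'
#' @param map A `complex_map`.
#' @param enrichments Output of [enrich_map()] (or compatible data frame).
#' @param annotations The `annotation_set` used for enrichment.
#' @param annotation_scores Named integer vector (protein -> 1..5); proteins
#'   without a score are treated as unscored and never receive transfers.
#' @param p_max,share_min,score_max The three rule thresholds.
#' @return Data frame `protein`, `cluster_id`, `term`, `term_name`, `q`,
#'   `share`, `annotation_score`.
#' @export
transfer_annotations <- function(map, enrichments, annotations,
                                 annotation_scores, p_max = 0.01,
                                 share_min = 0.5, score_max = 4L) {
  rows <- list()
  for (i in seq_along(map$clusters)) {
    cid <- map$cluster_id[i]
    members <- map$clusters[[i]]
    enr <- enrichments[enrichments$cluster_id == cid & enrichments$q <= p_max, ,
                       drop = FALSE]
    if (nrow(enr) == 0L) next
    targets <- members[!is.na(annotation_scores[members]) &
                         annotation_scores[members] < score_max]
    if (length(targets) == 0L) next
    for (r in seq_len(nrow(enr))) {
      term_members <- annotations[[enr$term[r]]]
      share <- length(intersect(members, term_members)) / length(members)
      if (share < share_min) next
      for (tg in setdiff(targets, term_members)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein = tg, cluster_id = cid, term = enr$term[r],
          term_name = enr$term_name[r], q = enr$q[r], share = share,
          annotation_score = unname(annotation_scores[tg]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein = character(0), cluster_id = character(0),
                      term = character(0), term_name = character(0),
                      q = numeric(0), share = numeric(0),
                      annotation_score = integer(0))
  rownames(out) <- NULL
  out
}
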