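# Gold-standard construction: redundancy reduction of curated complex lists
# and a leak-free 50:50 train/test split with positive/negative pair labels.
# Leak-freedom means no protein pair may appear in more than one of the six
# output sets (train/test x positive/negative, plus the two complex lists
# sharing no pair).

#' Reduce redundancy of a benchmark complex list
#'
#' First removes complexes larger than `size_threshold` subunits (and any
#' complex fully contained in a removed large complex, so e.g. ribosomal
#' subcomplexes go with the ribosome), then iteratively removes the larger of
#' any pair of complexes with Jaccard coefficient `>= merge_threshold` until
#' no such pair remains. Processing order is descending size then
#' lexicographic, and ties on size remove the lexicographically later
#' complex, so the result is deterministic.
#'
#' @param complexes A `complex_list`.
#' @param merge_threshold Jaccard threshold in (0, 1].
#' @param size_threshold Maximum complex size retained.
#' @param remove_largest Remove the larger of a redundant pair (the published
#'   behavior). `FALSE` removes the smaller instead.
#' @param remove_large_subcomplexes Also drop complexes strictly contained in
#'   a removed oversize complex.
#' @return A reduced `complex_list`.
#' @export
reduce_redundancy <- function(complexes, merge_threshold = 0.6,
                              size_threshold = 30L, remove_largest = TRUE,
                              remove_large_subcomplexes = TRUE) {
  assert_that(merge_threshold > 0 && merge_threshold <= 1,
              "`merge_threshold` must be in (0, 1]")
  cxs <- lapply(complexes, unique)
  big <- lengths(cxs) > size_threshold
  if (any(big) && remove_large_subcomplexes) {
    large_sets <- cxs[big]
    sub_of_big <- vapply(cxs, function(x)
      any(vapply(large_sets, function(L) all(x %in% L), TRUE)), TRUE)
    big <- big | sub_of_big
  }
  cxs <- cxs[!big]
  repeat {
    if (length(cxs) < 2L) break
    ord <- order_complexes(cxs)
    cxs <- cxs[ord]
    removed <- logical(length(cxs))
    changed <- FALSE
    for (i in seq_len(length(cxs) - 1L)) {
      if (removed[i]) next
      for (j in seq.int(i + 1L, length(cxs))) {
        if (removed[j] || removed[i]) next
        if (jaccard(cxs[[i]], cxs[[j]]) >= merge_threshold) {
          # i precedes j in (desc size, lex) order: i is the larger, or the
          # lexicographically earlier on a size tie -- the tie removes j.
          si <- length(cxs[[i]]); sj <- length(cxs[[j]])
          victim <- if (si == sj) j else if (xor(si > sj, !remove_largest)) i else j
          removed[victim] <- TRUE
          changed <- TRUE
        }
      }
    }
    cxs <- cxs[!removed]
    if (!changed) break
  }
  as_complex_list(cxs, source_tag = paste0(attr(complexes, "source_tag"), ":reduced"))
}

# Fast unordered-pair machinery on integer-coded proteins: a pair (i < j) is
# encoded as the double i * K + j, which is exact for K * K < 2^53.
encode_pairs <- function(i, j, K) {
  pmin(i, j) * K + pmax(i, j)
}

all_pairs_idx <- function(v) {
  # all unordered pairs of the integer vector v (assumed sorted unique)
  n <- length(v)
  if (n < 2L) return(cbind(integer(0), integer(0)))
  a <- rep.int(v[-n], (n - 1L):1L)
  b <- v[sequence((n - 1L):1L, from = 2:n)]
  cbind(a, b)
}

within_complex_pair_codes <- function(cxs_idx, K) {
  codes <- lapply(cxs_idx, function(v) {
    p <- all_pairs_idx(sort(v))
    encode_pairs(p[, 1L], p[, 2L], K)
  })
  unique(unlist(codes, use.names = FALSE))
}

#' Split benchmark complexes into leak-free train and test sets
#'
#' Shuffles complexes under `seed`, assigns them 50:50 to train/test, resolves
#' any train/test complex pair sharing a protein pair by randomly removing one
#' of the two, then derives labeled pairs per split: positives are
#' within-complex pairs; negatives are pairs of proteins from separate
#' complexes of that split that are never co-complexed in either split.
#' Negative pairs arising in both splits are assigned to one split uniformly
#' at random.
#'
#' @param complexes A `complex_list` with at least two complexes.
#' @param seed Integer seed.
#' @return A `benchmark_split`: list with `train` and `test`, each holding
#'   `complexes` (a `complex_list`) and `positives` / `negatives` pair data
#'   frames, plus a `log` of removals.
#' @export
split_benchmark <- function(complexes, seed = 1L) {
  assert_that(length(complexes) >= 2L, "need at least two complexes to split")
  proteins <- sort(unique(unlist(complexes)))
  K <- length(proteins) + 1
  cxs_idx <- lapply(complexes, function(x) match(x, proteins))
  with_seed(seed, {
    n <- length(cxs_idx)
    ord <- sample.int(n)
    train_sel <- ord[seq_len(ceiling(n / 2))]
    test_sel <- setdiff(ord, train_sel)
    log <- character(0)
    # resolve cross-split complexes sharing >= 1 protein pair
    repeat {
      tr_codes <- lapply(cxs_idx[train_sel], function(v) {
        p <- all_pairs_idx(sort(v)); encode_pairs(p[, 1L], p[, 2L], K)
      })
      te_codes <- lapply(cxs_idx[test_sel], function(v) {
        p <- all_pairs_idx(sort(v)); encode_pairs(p[, 1L], p[, 2L], K)
      })
      te_all <- unlist(te_codes, use.names = FALSE)
      offender <- NULL
      for (ti in seq_along(train_sel)) {
        hit <- tr_codes[[ti]] %in% te_all
        if (any(hit)) {
          code <- tr_codes[[ti]][which(hit)[1L]]
          tj <- which(vapply(te_codes, function(cc) code %in% cc, TRUE))[1L]
          offender <- c(ti, tj)
          break
        }
      }
      if (is.null(offender)) break
      if (runif(1L) < 0.5) {
        log <- c(log, sprintf("removed train complex %d (pair overlap with test)",
                              train_sel[offender[1L]]))
        train_sel <- train_sel[-offender[1L]]
      } else {
        log <- c(log, sprintf("removed test complex %d (pair overlap with train)",
                              test_sel[offender[2L]]))
        test_sel <- test_sel[-offender[2L]]
      }
    }
    make_side <- function(sel) {
      idx <- cxs_idx[sel]
      pos <- within_complex_pair_codes(idx, K)
      prots <- sort(unique(unlist(idx)))
      list(idx = idx, pos = pos, prots = prots)
    }
    tr <- make_side(train_sel)
    te <- make_side(test_sel)
    co_any <- unique(c(tr$pos, te$pos))
    make_neg <- function(side) {
      p <- all_pairs_idx(side$prots)
      codes <- encode_pairs(p[, 1L], p[, 2L], K)
      codes[!(codes %in% co_any)]
    }
    neg_tr <- make_neg(tr)
    neg_te <- make_neg(te)
    both <- intersect(neg_tr, neg_te)
    if (length(both) > 0L) {
      to_train <- runif(length(both)) < 0.5
      drop_from_train <- both[!to_train]
      drop_from_test <- both[to_train]
      neg_tr <- neg_tr[!(neg_tr %in% drop_from_train)]
      neg_te <- neg_te[!(neg_te %in% drop_from_test)]
      log <- c(log, sprintf("resolved %d cross-split negative pairs at random",
                            length(both)))
    }
    decode <- function(codes) {
      if (length(codes) == 0L)
        return(data.frame(id_a = character(0), id_b = character(0)))
      codes <- sort(codes)    # proteins is sorted, so code order == id order
      i <- floor(codes / K)
      j <- codes - i * K
      data.frame(id_a = proteins[i], id_b = proteins[j],
                 stringsAsFactors = FALSE)
    }
    side_out <- function(sel, side, neg) {
      list(complexes = as_complex_list(lapply(sel, function(i) complexes[[i]]),
                                       source_tag = attr(complexes, "source_tag")),
           positives = decode(side$pos), negatives = decode(neg))
    }
    structure(list(train = side_out(train_sel, tr, neg_tr),
                   test = side_out(test_sel, te, neg_te),
                   seed = seed, log = log),
              class = "benchmark_split")
  })
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat(sprintf(paste0("<benchmark_split> train: %d complexes, %d pos, %d neg; ",
                     "test: %d complexes, %d pos, %d neg (seed %d)\n"),
              length(x$train$complexes), nrow(x$train$positives),
              nrow(x$train$negatives), length(x$test$complexes),
              nrow(x$test$positives), nrow(x$test$negatives), x$seed))
  invisible(x)
}

#' Check the six leak-freedom invariants of a benchmark split
#'
#' @param split A `benchmark_split`.
#' @return `TRUE` invisibly; stops with the violated invariant otherwise.
#' @export
check_split_invariants <- function(split) {
  ids <- unique(c(split$train$positives$id_a, split$train$positives$id_b,
                  split$train$negatives$id_a, split$train$negatives$id_b,
                  split$test$positives$id_a, split$test$positives$id_b,
                  split$test$negatives$id_a, split$test$negatives$id_b))
  K <- length(ids) + 1
  key <- function(df) {
    if (nrow(df) == 0L) return(numeric(0))
    encode_pairs(match(df$id_a, ids), match(df$id_b, ids), K)
  }
  tp <- key(split$train$positives); tn <- key(split$train$negatives)
  sp <- key(split$test$positives);  sn <- key(split$test$negatives)
  assert_that(!any(tp %in% tn), "train positives intersect train negatives")
  assert_that(!any(sp %in% sn), "test positives intersect test negatives")
  assert_that(!any(tp %in% sp), "train positives intersect test positives")
  assert_that(!any(tn %in% sn), "train negatives intersect test negatives")
  assert_that(!any(tp %in% sn), "train positives intersect test negatives")
  assert_that(!any(sp %in% tn), "test positives intersect train negatives")
  invisible(TRUE)
}

#' Write the six benchmark split outputs
#'
#' Emits `<prefix>.train.txt`, `<prefix>.test.txt` (complex lists) and the
#' four labeled pair files `<prefix>.{train,test}_ppis.txt`,
#' `<prefix>.neg_{train,test}_ppis.txt`.
#'
#' @param split A `benchmark_split`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The directory, invisibly.
#' @export
write_benchmark_split <- function(split, dir, prefix = "benchmark") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(prefix, ...))
  with_label <- function(df, l) { df$label <- rep(l, nrow(df)); df }
  write_complexes(split$train$complexes, p(".train.txt"))
  write_complexes(split$test$complexes, p(".test.txt"))
  write_pairs(with_label(split$train$positives, 1L), p(".train_ppis.txt"))
  write_pairs(with_label(split$test$positives, 1L), p(".test_ppis.txt"))
  write_pairs(with_label(split$train$negatives, 0L), p(".neg_train_ppis.txt"))
  write_pairs(with_label(split$test$negatives, 0L), p(".neg_test_ppis.txt"))
  invisible(dir)
}
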