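# Weighted k-clique precision/recall between a predicted cluster set and
# gold-standard complexes. Complexes are treated as fully connected, so the
# size-s cliques of a cluster are simply its s-subsets. For each size s from
# 2 to the largest complex or cluster:
#   precision_s = fraction of predicted s-cliques contained in a gold complex
#   recall_s    = fraction of gold s-cliques contained in a predicted cluster
# Per-size values are averaged with weights = number of predicted clusters
# (for precision) or gold complexes (for recall) of size >= s, damping the
# influence of the largest complexes.

# Index: protein -> integer ids of containing complexes, for O(s) containment.
membership_index <- function(complexes) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(complexes)) {
    for (p in complexes[[i]]) {
      env[[p]] <- c(env[[p]], i)
    }
  }
  env
}

count_containing <- function(members, index) {
  hit <- index[[members[1L]]]
  if (is.null(hit)) return(0L)
  for (p in members[-1L]) {
    nxt <- index[[p]]
    if (is.null(nxt)) return(0L)
    hit <- hit[hit %in% nxt]
    if (length(hit) == 0L) return(0L)
  }
  length(hit)
}

clique_contained <- function(members, index) {
  count_containing(members, index) > 0L
}

# Exact per-size fraction of s-cliques (unique across source sets) contained
# on the other side.
exact_clique_fraction <- function(source_sets, s, index) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  n_tot <- 0L; n_hit <- 0L
  for (set in source_sets) {
    if (length(set) < s) next
    combos <- utils::combn(sort(set), s)
    for (j in seq_len(ncol(combos))) {
      members <- combos[, j]
      key <- paste(members, collapse = "\t")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      n_tot <- n_tot + 1L
      if (clique_contained(members, index)) n_hit <- n_hit + 1L
    }
  }
  if (n_tot == 0L) return(c(frac = NA_real_, n = 0))
  c(frac = n_hit / n_tot, n = n_tot)
}

# Monte-Carlo per-size fraction: source set sampled proportional to its
# s-clique count, then a uniform s-subset. That draws cliques uniformly over
# the clique *multiset*; a clique shared by m source sets is drawn with
# probability proportional to m, so each draw is weighted 1/m
# (Horvitz-Thompson) to make the ratio estimate the unique-clique fraction
# that exact enumeration computes.
sampled_clique_fraction <- function(source_sets, s, index, n_samples,
                                    source_index) {
  sizes <- lengths(source_sets)
  counts <- ifelse(sizes >= s, choose(sizes, s), 0)
  total <- sum(counts)
  if (total == 0) return(c(frac = NA_real_, n = 0))
  picks <- sample.int(length(source_sets), n_samples, replace = TRUE,
                      prob = counts / total)
  num <- 0; den <- 0
  for (i in picks) {
    members <- sample(source_sets[[i]], s)
    w <- 1 / count_containing(members, source_index)
    den <- den + w
    if (clique_contained(members, index)) num <- num + w
  }
  c(frac = num / den, n = n_samples)
}

#' Weighted k-clique precision/recall of predicted complexes
#'
#' @param predicted,gold `complex_list` objects (or plain lists of member
#'   vectors); both non-empty.
#' @param max_exact_size Largest clique size enumerated exhaustively when the
#'   per-size clique count is within `exact_cap`; larger sizes (or counts)
#'   fall back to uniform sampling.
#' @param n_samples Monte-Carlo sample size per sampled clique size.
#' @param seed Integer seed for sampling.
#' @param exact_cap Clique-count ceiling for exact enumeration.
#' @param mode `"auto"` chooses exact vs sampled per size; `"exact"` /
#'   `"sample"` force one route.
#' @param weighting `"asymmetric"` (default: precision weighted by predicted
#'   cluster counts, recall by gold complex counts) or `"symmetric"` (both
#'   weighted by the summed counts).
#' @return A `clique_eval`: per-size table plus `weighted_precision`,
#'   `weighted_recall`, `weighted_f1` and sampling metadata. An empty
#'   predicted set reports precision 0 with `empty_predicted = TRUE`.
#' @export
kclique_eval <- function(predicted, gold, max_exact_size = 6L,
                         n_samples = 10000L, seed = 1L, exact_cap = 20000L,
                         mode = c("auto", "exact", "sample"),
                         weighting = c("asymmetric", "symmetric")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  assert_that(length(gold) >= 1L, "empty gold standard")
  empty_predicted <- length(predicted) == 0L
  pred_sets <- lapply(predicted, unique)
  gold_sets <- lapply(gold, unique)
  pred_index <- membership_index(pred_sets)
  gold_index <- membership_index(gold_sets)
  max_size <- max(c(lengths(pred_sets), lengths(gold_sets), 2L))
  with_seed(seed, {
    rows <- list()
    for (s in 2:max_size) {
      one_side <- function(source_sets, index, source_index) {
        counts <- sum(ifelse(lengths(source_sets) >= s,
                             choose(lengths(source_sets), s), 0))
        use_exact <- switch(mode,
                            exact = TRUE,
                            sample = FALSE,
                            auto = counts <= exact_cap ||
                              (s <= max_exact_size && counts <= 10 * exact_cap))
        if (counts == 0) return(c(frac = NA_real_, n = 0, exact = NA))
        if (use_exact) c(exact_clique_fraction(source_sets, s, index), exact = 1)
        else c(sampled_clique_fraction(source_sets, s, index, n_samples,
                                       source_index), exact = 0)
      }
      pr <- if (empty_predicted) c(frac = NA_real_, n = 0, exact = NA)
            else one_side(pred_sets, gold_index, pred_index)
      rc <- one_side(gold_sets, pred_index, gold_index)
      # a gold size with no predicted clique that large still has recall,
      # computed by containment of gold cliques in predicted clusters
      w_pred <- sum(lengths(pred_sets) >= s)
      w_gold <- sum(lengths(gold_sets) >= s)
      rows[[length(rows) + 1L]] <- data.frame(
        size = s,
        precision = unname(pr["frac"]), recall = unname(rc["frac"]),
        n_pred_cliques = unname(pr["n"]), n_gold_cliques = unname(rc["n"]),
        w_pred = w_pred, w_gold = w_gold,
        exact_pred = unname(pr["exact"]), exact_gold = unname(rc["exact"]))
    }
    per_size <- do.call(rbind, rows)
    wp <- if (weighting == "asymmetric") per_size$w_pred
          else per_size$w_pred + per_size$w_gold
    wr <- if (weighting == "asymmetric") per_size$w_gold
          else per_size$w_pred + per_size$w_gold
    ok_p <- !is.na(per_size$precision) & wp > 0
    ok_r <- !is.na(per_size$recall) & wr > 0
    weighted_precision <- if (any(ok_p))
      sum(per_size$precision[ok_p] * wp[ok_p]) / sum(wp[ok_p]) else 0
    weighted_recall <- if (any(ok_r))
      sum(per_size$recall[ok_r] * wr[ok_r]) / sum(wr[ok_r]) else 0
    weighted_f1 <- if (weighted_precision + weighted_recall > 0)
      2 * weighted_precision * weighted_recall /
        (weighted_precision + weighted_recall) else 0
    structure(list(per_size = per_size,
                   weighted_precision = weighted_precision,
                   weighted_recall = weighted_recall,
                   weighted_f1 = weighted_f1,
                   empty_predicted = empty_predicted,
                   seed = seed, weighting = weighting),
              class = "clique_eval")
  })
}

#' @export
print.clique_eval <- function(x, ...) {
  cat(sprintf("<clique_eval> weighted precision %.3f, recall %.3f, F1 %.3f%s\n",
              x$weighted_precision, x$weighted_recall, x$weighted_f1,
              if (x$empty_predicted) " (empty predicted set)" else ""))
  invisible(x)
}
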