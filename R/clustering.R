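# Two-stage clustering of the scored interaction network: cohesiveness-based
# dense-region growth (ClusterOne-style greedy seeds with overlap merging)
# followed by Markov clustering (MCL) inside each region, then the
# edge-weight post-filter and the 2..100 size gate. A parameter sweep over
# (score threshold, density, max overlap, inflation) is evaluated by weighted
# k-clique precision/recall, ranked sets are assembled into confidence tiers,
# and a Jaccard-based reduction yields the non-redundant map.

#' Clustering parameter set
#'
#' @param score_threshold Confidence cutoff applied to the network.
#' @param c1_density Minimum weighted density of a dense region.
#' @param c1_overlap Overlap score at or above which regions merge.
#' @param mcl_inflation MCL inflation exponent (>= 1).
#' @return A named list of class `cluster_params`.
#' @export
cluster_params <- function(score_threshold, c1_density = 0.3,
                           c1_overlap = 0.7, mcl_inflation = 2) {
  assert_that(score_threshold >= 0 && score_threshold <= 1,
              "`score_threshold` must be in [0, 1]")
  assert_that(mcl_inflation >= 1, "`mcl_inflation` must be >= 1")
  structure(list(score_threshold = score_threshold, c1_density = c1_density,
                 c1_overlap = c1_overlap, mcl_inflation = mcl_inflation),
            class = "cluster_params")
}

#' The published parameter sweep grids
#'
#' @return Named list of the four parameter grids used for cluster-set
#'   selection (14 score thresholds x 2 overlaps x 4 densities x 9 inflations).
#' @export
paper_sweep_grids <- function() {
  list(score_threshold = c(0.95, 0.9, 0.85, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3,
                           0.2, 0.1, 0.05, 0.04, 0.03),
       c1_overlap = c(0.6, 0.7),
       c1_density = c(0.1, 0.2, 0.3, 0.4),
       mcl_inflation = c(1, 2, 3, 4, 5, 7, 9, 11, 15))
}

#' Threshold a scored network into a weighted graph
#'
#' Retains edges with score strictly greater than `cutoff` (the published
#' filter wording is "greater than"); isolated nodes are dropped.
#'
#' @param net Scored network data frame (`id_a`, `id_b`, `score`).
#' @param cutoff Confidence cutoff.
#' @return An `igraph` weighted undirected graph.
#' @export
threshold_network <- function(net, cutoff) {
  keep <- net$score > cutoff
  edges <- net[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$id_a, to = edges$id_b, weight = edges$score),
    directed = FALSE)
  g
}

# Weighted cohesiveness of node set S: W_in / (W_in + W_bound + penalty*|S|).
cohesiveness <- function(w_in, w_bound, size, penalty) {
  w_in / (w_in + w_bound + penalty * size)
}

#' Grow dense regions by greedy cohesiveness optimization
#'
#' ClusterOne-style procedure: seeds are taken in descending weighted-degree
#' order among nodes not yet covered; each seed group greedily adds boundary
#' nodes or removes members while cohesiveness
#' `W_in / (W_in + W_bound + penalty * |V|)` improves. Grown groups with
#' overlap score `omega(A,B) = |A ∩ B|^2 / (|A| |B|) >=` `max_overlap`
#' are merged, then groups with weighted density below `density` or fewer
#' than 3 members are discarded.
#'
#' @param graph Weighted `igraph` graph.
#' @param density Minimum weighted density `2 W_in / (|V| (|V|-1))`.
#' @param max_overlap Merge threshold on the overlap score.
#' @param penalty Cohesiveness size penalty (default 2, the original
#'   algorithm's default).
#' @return List of character vectors (node-name sets), deterministic order.
#' @export
grow_dense_regions <- function(graph, density = 0.3, max_overlap = 0.7,
                               penalty = 2) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(list())
  W <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  nodes <- igraph::V(graph)$name
  strength <- rowSums(W)
  seed_order <- order(-strength, nodes)
  covered <- logical(n)
  groups <- list()
  for (seed in seed_order) {
    if (covered[seed]) next
    S <- seed
    in_S <- logical(n); in_S[seed] <- TRUE
    w_to_S <- W[seed, ]        # weight from each node into S, kept incremental
    w_in <- 0
    repeat {
      w_bound <- sum(w_to_S[!in_S])
      h <- cohesiveness(w_in, w_bound, length(S), penalty)
      # candidate additions: boundary nodes
      cand_add <- which(!in_S & w_to_S > 0)
      best_h <- h; best_action <- NULL
      if (length(cand_add) > 0L) {
        add_in <- w_in + w_to_S[cand_add]
        add_bound <- w_bound - w_to_S[cand_add] +
          (strength[cand_add] - w_to_S[cand_add])
        add_h <- cohesiveness(add_in, add_bound, length(S) + 1L, penalty)
        bi <- which.max(add_h)
        if (add_h[bi] > best_h + 1e-12) {
          best_h <- add_h[bi]; best_action <- c("add", cand_add[bi])
        }
      }
      if (length(S) > 1L) {
        rem_w <- w_to_S[S]                        # u's weight into S
        rem_in <- w_in - rem_w
        rem_bound <- w_bound + rem_w - (strength[S] - rem_w)
        rem_h <- cohesiveness(rem_in, rem_bound, length(S) - 1L, penalty)
        bi <- which.max(rem_h)
        if (rem_h[bi] > best_h + 1e-12) {
          best_h <- rem_h[bi]; best_action <- c("remove", S[bi])
        }
      }
      if (is.null(best_action)) break
      v <- as.integer(best_action[2L])
      if (best_action[1L] == "add") {
        w_in <- w_in + w_to_S[v]
        S <- c(S, v); in_S[v] <- TRUE
        w_to_S <- w_to_S + W[v, ]
      } else {
        S <- setdiff(S, v); in_S[v] <- FALSE
        w_to_S <- w_to_S - W[v, ]
        w_in <- w_in - w_to_S[v]
      }
    }
    covered[S] <- TRUE
    groups[[length(groups) + 1L]] <- sort(S)
  }
  # merge overlapping groups at omega >= max_overlap, to fixed point
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(groups)) {
      j <- i + 1L
      while (j <= length(groups)) {
        ov <- length(intersect(groups[[i]], groups[[j]]))^2 /
          (length(groups[[i]]) * length(groups[[j]]))
        if (ov >= max_overlap) {
          groups[[i]] <- sort(union(groups[[i]], groups[[j]]))
          groups[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  keep <- vapply(groups, function(S) {
    if (length(S) < 3L) return(FALSE)
    w_in <- sum(W[S, S]) / 2
    dens <- 2 * w_in / (length(S) * (length(S) - 1L))
    dens >= density
  }, TRUE)
  lapply(groups[keep], function(S) nodes[S])
}

#' Markov clustering of a weighted subgraph
#'
#' Standard MCL: self-loops are added at each node's maximum incident weight,
#' the matrix is column-normalized, then expansion (matrix squaring) and
#' inflation (element-wise power and renormalization) alternate until the
#' matrix stops changing. Clusters are read from the attractor rows;
#' overlapping attractor systems are merged, so the output is a partition of
#' the subgraph's nodes.
#'
#' @param subgraph Weighted `igraph` graph (connected or not).
#' @param inflation Inflation exponent (>= 1; 1 reduces to a pure random-walk
#'   limit, one cluster per connected component).
#' @param max_iters Iteration cap; non-convergence returns the current
#'   interpretation with a `converged = FALSE` attribute and a warning.
#' @param tol Convergence tolerance on the max entry change.
#' @param prune Entries below this are zeroed each iteration.
#' @return List of character vectors partitioning the nodes; attribute
#'   `converged`.
#' @export
mcl <- function(subgraph, inflation = 2, max_iters = 200L, tol = 1e-6,
                prune = 1e-8) {
  n <- igraph::vcount(subgraph)
  nodes <- igraph::V(subgraph)$name
  if (n == 0L) return(structure(list(), converged = TRUE))
  if (n == 1L) return(structure(list(nodes), converged = TRUE))
  A <- igraph::as_adjacency_matrix(subgraph, attr = "weight", sparse = FALSE)
  mcl_matrix(A, nodes, inflation, max_iters, tol, prune)
}

# Matrix-level MCL used by both mcl() and the sweep's inner loop.
mcl_matrix <- function(A, nodes, inflation = 2, max_iters = 200L, tol = 1e-6,
                       prune = 1e-8) {
  n <- nrow(A)
  if (n == 1L) return(structure(list(nodes), converged = TRUE))
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalize <- function(M) {
    cs <- colSums(M)
    dead <- which(cs == 0)        # column emptied by pruning: restart at self
    if (length(dead) > 0L) {
      M[cbind(dead, dead)] <- 1
      cs[dead] <- 1
    }
    sweep(M, 2L, cs, "/")
  }
  M <- normalize(A)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    M2 <- M %*% M
    M2 <- normalize(M2^inflation)
    M2[M2 < prune] <- 0
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations", max_iters),
            call. = FALSE)
  # attractor rows: rows retaining mass; cluster = supports of those rows,
  # merged when they share nodes so the result is a partition
  eps <- 1e-6
  attract <- which(rowSums(M) > eps)
  clusters <- lapply(attract, function(i) which(M[i, ] > eps))
  assign <- integer(n)
  cl_id <- 0L
  for (cl in clusters) {
    hit <- unique(assign[cl][assign[cl] > 0L])
    if (length(hit) == 0L) {
      cl_id <- cl_id + 1L
      assign[cl] <- cl_id
    } else {
      tgt <- min(hit)
      assign[assign %in% hit] <- tgt
      assign[cl] <- tgt
    }
  }
  for (i in which(assign == 0L)) { cl_id <- cl_id + 1L; assign[i] <- cl_id }
  out <- lapply(split(seq_len(n), assign), function(ix) sort(nodes[ix]))
  names(out) <- NULL
  out <- out[order(-lengths(out), vapply(out, function(x) x[1L], ""))]
  structure(out, converged = converged)
}

#' Two-stage clustering at one parameter set
#'
#' Threshold, grow dense regions, run MCL within each region, then apply the
#' published post-filters: members whose maximum within-cluster edge weight
#' is not strictly greater than the score threshold are removed, and only
#' clusters with 2..100 members are kept.
#'
#' @param net Scored network data frame.
#' @param params A `cluster_params`.
#' @return List of character vectors (clusters), deterministically ordered
#'   and deduplicated.
#' @export
two_stage_cluster <- function(net, params) {
  g <- threshold_network(net, params$score_threshold)
  two_stage_cluster_graph(g, params)
}

# Same as two_stage_cluster but takes the already-thresholded graph, so the
# parameter sweep can reuse graphs, adjacency, and regions across the grid.
two_stage_cluster_graph <- function(g, params, regions = NULL, W = NULL) {
  if (igraph::vcount(g) == 0L) return(list())
  if (is.null(W))
    W <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  if (is.null(regions))
    regions <- grow_dense_regions(g, density = params$c1_density,
                                  max_overlap = params$c1_overlap)
  clusters <- list()
  for (region in regions) {
    idx <- match(region, rownames(W))
    clusters <- c(clusters, suppressWarnings(
      mcl_matrix(W[idx, idx, drop = FALSE], region,
                 inflation = params$mcl_inflation)))
  }
  post_filter_clusters(clusters, W, params$score_threshold)
}

post_filter_clusters <- function(clusters, W, score_threshold,
                                 max_size = 100L) {
  out <- list()
  seen <- character(0)
  nodes <- rownames(W)
  for (cl in clusters) {
    idx <- match(cl, nodes)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 2L) next
    Ws <- W[idx, idx, drop = FALSE]
    keep <- apply(Ws, 1L, max) > score_threshold
    cl2 <- sort(nodes[idx[keep]])
    if (length(cl2) < 2L || length(cl2) > max_size) next
    key <- paste(cl2, collapse = "\t")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- cl2
  }
  out[order(-lengths(out), vapply(out, function(x) x[1L], ""))]
}

#' Sweep clustering parameters and evaluate each set by weighted k-cliques
#'
#' One row per parameter combination, with weighted clique precision, recall,
#' F1 against the training gold standard, plus cluster and protein counts.
#' Results are cached on disk (keyed by the parameter values) when
#' `cache_dir` is given, making interrupted sweeps resumable.
#'
#' @param net Scored network data frame.
#' @param grids Named list of grids (`score_threshold`, `c1_density`,
#'   `c1_overlap`, `mcl_inflation`); see [paper_sweep_grids()].
#' @param gold_train Gold-standard `complex_list` for evaluation.
#' @param cache_dir Optional cache directory.
#' @param kclique_seed,kclique_samples Sampling controls for the evaluator.
#' @return A `sweep_table` data frame, ordered by descending weighted
#'   precision, with a `clusters` attribute holding each row's cluster list.
#' @export
parameter_sweep <- function(net, grids, gold_train, cache_dir = NULL,
                            kclique_seed = 1L, kclique_samples = 2000L) {
  combos <- expand.grid(mcl_inflation = grids$mcl_inflation,
                        c1_density = grids$c1_density,
                        c1_overlap = grids$c1_overlap,
                        score_threshold = grids$score_threshold,
                        KEEP.OUT.ATTRS = FALSE)
  if (!is.null(cache_dir)) dir.create(cache_dir, showWarnings = FALSE,
                                      recursive = TRUE)
  rows <- vector("list", nrow(combos))
  cluster_sets <- vector("list", nrow(combos))
  graph_cache <- list()
  region_cache <- list()
  for (r in seq_len(nrow(combos))) {
    p <- cluster_params(combos$score_threshold[r], combos$c1_density[r],
                        combos$c1_overlap[r], combos$mcl_inflation[r])
    key <- sprintf("t%g_d%g_o%g_i%g", p$score_threshold, p$c1_density,
                   p$c1_overlap, p$mcl_inflation)
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(key, ".rds")) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      res <- readRDS(cache_file)
    } else {
      gkey <- sprintf("%g", p$score_threshold)
      if (is.null(graph_cache[[gkey]])) {
        g0 <- threshold_network(net, p$score_threshold)
        graph_cache[[gkey]] <- list(
          g = g0,
          W = if (igraph::vcount(g0) > 0L)
            igraph::as_adjacency_matrix(g0, attr = "weight", sparse = FALSE)
          else NULL)
      }
      g <- graph_cache[[gkey]]$g
      rkey <- sprintf("%s_%g_%g", gkey, p$c1_density, p$c1_overlap)
      if (is.null(region_cache[[rkey]]))
        region_cache[[rkey]] <- grow_dense_regions(g, p$c1_density, p$c1_overlap)
      clusters <- two_stage_cluster_graph(g, p, regions = region_cache[[rkey]],
                                          W = graph_cache[[gkey]]$W)
      ev <- if (length(clusters) > 0L) {
        kclique_eval(as_complex_list(clusters, "sweep"), gold_train,
                     n_samples = kclique_samples, seed = kclique_seed)
      } else {
        list(weighted_precision = 0, weighted_recall = 0, weighted_f1 = 0)
      }
      res <- list(clusters = clusters,
                  metrics = c(precision = ev$weighted_precision,
                              recall = ev$weighted_recall,
                              f1 = ev$weighted_f1,
                              n_clusters = length(clusters),
                              n_proteins = length(unique(unlist(clusters)))))
      if (!is.null(cache_file)) saveRDS(res, cache_file)
    }
    cluster_sets[[r]] <- res$clusters
    rows[[r]] <- data.frame(score_threshold = p$score_threshold,
                            c1_density = p$c1_density,
                            c1_overlap = p$c1_overlap,
                            mcl_inflation = p$mcl_inflation,
                            precision = res$metrics[["precision"]],
                            recall = res$metrics[["recall"]],
                            f1 = res$metrics[["f1"]],
                            n_clusters = res$metrics[["n_clusters"]],
                            n_proteins = res$metrics[["n_proteins"]])
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$precision, -out$recall, out$score_threshold)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, clusters = cluster_sets[ord],
            class = c("sweep_table", "data.frame"))
}

#' Select sweep rows balancing precision and recall
#'
#' Picks `n_tiers` rows from a sweep table, ranked by descending precision,
#' spacing the picks over the precision range so the resulting tiers span
#' high-precision to high-recall cluster sets (the published maps use six
#' hand-picked sets; this is the automated analogue).
#'
#' @param sweep A `sweep_table`.
#' @param n_tiers Number of cluster sets to select.
#' @param min_clusters Ignore parameter sets yielding fewer clusters.
#' @return List of `list(params, clusters, precision, recall)`, ordered by
#'   descending precision.
#' @export
select_tier_sets <- function(sweep, n_tiers = 6L, min_clusters = 1L) {
  ok <- which(sweep$n_clusters >= min_clusters)
  assert_that(length(ok) > 0L, "no parameter set produced clusters")
  sw <- sweep[ok, , drop = FALSE]
  cl <- attr(sweep, "clusters")[ok]
  # best f1 within each precision stratum; fall back to top rows
  picks <- unique(round(seq(1L, nrow(sw), length.out = min(n_tiers, nrow(sw)))))
  lapply(picks, function(i) {
    list(params = cluster_params(sw$score_threshold[i], sw$c1_density[i],
                                 sw$c1_overlap[i], sw$mcl_inflation[i]),
         clusters = cl[[i]], precision = sw$precision[i], recall = sw$recall[i])
  })
}

#' Assemble selected cluster sets into a confidence-tiered complex map
#'
#' Tier 1 is the highest-precision set. A complex appearing in several tiers
#' is recorded once, at its best (lowest-numbered) tier.
#'
#' @param selected List of `list(params, clusters)` ordered by descending
#'   weighted precision (as from [select_tier_sets()]).
#' @return A `complex_map`: fields `clusters` (list of member vectors),
#'   `tier` (integer per cluster, 1 = highest confidence), `cluster_id`,
#'   `provenance` (params per tier).
#' @export
assemble_tiers <- function(selected) {
  assert_that(length(selected) >= 1L, "no cluster sets to assemble")
  seen <- character(0)
  clusters <- list(); tier <- integer(0)
  provenance <- lapply(selected, `[[`, "params")
  for (t in seq_along(selected)) {
    for (cl in selected[[t]]$clusters) {
      key <- complex_key(cl)
      if (key %in% seen) next
      seen <- c(seen, key)
      clusters[[length(clusters) + 1L]] <- sort(cl)
      tier <- c(tier, t)
    }
  }
  ord <- order(tier, -lengths(clusters),
               vapply(clusters, function(x) x[1L], ""))
  clusters <- clusters[ord]; tier <- tier[ord]
  structure(list(clusters = clusters, tier = tier,
                 cluster_id = sprintf("huC%05d", seq_along(clusters)),
                 provenance = provenance),
            class = "complex_map")
}

#' @export
print.complex_map <- function(x, ...) {
  cat(sprintf("<complex_map> %d complexes over %d tiers, %d proteins\n",
              length(x$clusters), length(unique(x$tier)),
              length(unique(unlist(x$clusters)))))
  invisible(x)
}

#' Reduce a complex map to a non-redundant set
#'
#' Iteratively removes the smaller of any pair of complexes with Jaccard
#' coefficient at or above `jaccard_threshold` (ties remove the
#' lexicographically later complex), to a fixed point.
#'
#' @param map A `complex_map`.
#' @param jaccard_threshold Redundancy threshold (published value 0.7).
#' @return A reduced `complex_map`.
#' @export
reduce_map <- function(map, jaccard_threshold = 0.7) {
  keep <- rep(TRUE, length(map$clusters))
  repeat {
    idx <- which(keep)
    if (length(idx) < 2L) break
    changed <- FALSE
    ord <- idx[order_complexes(map$clusters[idx])]
    for (a in seq_len(length(ord) - 1L)) {
      if (!keep[ord[a]]) next
      for (b in seq.int(a + 1L, length(ord))) {
        if (!keep[ord[b]] || !keep[ord[a]]) next
        if (jaccard(map$clusters[[ord[a]]], map$clusters[[ord[b]]]) >=
              jaccard_threshold) {
          keep[ord[b]] <- FALSE   # ord is (desc size, lex): b is smaller/later
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  structure(list(clusters = map$clusters[keep], tier = map$tier[keep],
                 cluster_id = map$cluster_id[keep],
                 provenance = map$provenance),
            class = "complex_map")
}

#' Write / read a complex map
#'
#' The cluster file holds one complex per line (tab-separated identifiers,
#' preceded by the cluster id and tier); the manifest JSON records tier
#' provenance.
#'
#' @param map A `complex_map`.
#' @param path Cluster file path.
#' @param manifest_path Optional JSON manifest path.
#' @return `path`, invisibly.
#' @export
write_complex_map <- function(map, path, manifest_path = NULL) {
  lines <- vapply(seq_along(map$clusters), function(i) {
    paste(c(map$cluster_id[i], map$tier[i], sort(map$clusters[[i]])),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(
      list(n_clusters = length(map$clusters),
           tiers = lapply(map$provenance, unclass)),
      manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_complex_map
#' @export
read_complex_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  structure(list(clusters = lapply(parts, function(p) sort(p[-(1:2)])),
                 tier = as.integer(vapply(parts, `[[`, "", 2L)),
                 cluster_id = vapply(parts, `[[`, "", 1L),
                 provenance = list()),
            class = "complex_map")
}
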