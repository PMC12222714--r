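# Synthetic fixture generators with planted ground truth. These emulate the
# pipeline's real inputs -- bait-prey pulldowns, scored networks, lineage
# expression, paired dimer structures -- at toy scale, so every downstream
# module can be tested against a known answer without external data.
#
# All generators take an explicit integer seed and run on a pinned
# Mersenne-Twister stream (see with_seed()), so a fixed seed gives
# byte-identical output on any platform. No generator touches global RNG state.

#' Generate planted protein complexes
#'
#' Builds a set of ground-truth complexes with optional shared subunits, and
#' designates disjoint within-complex pairs as mutually exclusive (ME) or
#' structurally consistent (SC) for use by the expression and structure
#' generators.
#'
#' @param n_complexes Number of complexes (>= 1).
#' @param size_range Integer pair `(min, max)` of complex sizes; min >= 2.
#' @param overlap_fraction Fraction of complexes (beyond the first) that share
#'   one member with a previously generated complex, emulating shared subunits.
#' @param seed Integer seed.
#' @param n_me_pairs,n_sc_pairs Number of within-complex pairs to flag as
#'   mutually exclusive / structurally consistent. All flagged pairs are
#'   protein-disjoint.
#' @return A `planted_truth` object with fields `complexes` (a
#'   [as_complex_list()] object), `me_pairs`, `sc_pairs` (data frames
#'   `id_a`, `id_b`), and `seed`.
#' @export
make_planted_complexes <- function(n_complexes, size_range = c(3L, 8L),
                                   overlap_fraction = 0, seed = 1L,
                                   n_me_pairs = 0L, n_sc_pairs = 0L) {
  assert_count(n_complexes, "n_complexes", min = 1L)
  assert_that(length(size_range) == 2L && size_range[1L] >= 2L &&
                size_range[2L] >= size_range[1L],
              "`size_range` must be an increasing integer pair with min >= 2")
  assert_prob(overlap_fraction, "overlap_fraction")
  with_seed(seed, {
    size_choices <- seq.int(size_range[1L], size_range[2L])
    sizes <- size_choices[sample.int(length(size_choices), n_complexes,
                                     replace = TRUE)]
    next_id <- 1L
    fresh <- function(k) {
      ids <- sprintf("P%04d", seq.int(next_id, next_id + k - 1L))
      next_id <<- next_id + k
      ids
    }
    complexes <- vector("list", n_complexes)
    for (i in seq_len(n_complexes)) {
      share <- i > 1L && runif(1L) < overlap_fraction
      if (share) {
        donor <- complexes[[sample.int(i - 1L, 1L)]]
        shared <- sample(donor, 1L)
        complexes[[i]] <- c(shared, fresh(sizes[i] - 1L))
      } else {
        complexes[[i]] <- fresh(sizes[i])
      }
    }
    # flag protein-disjoint within-complex pairs as ME / SC
    pool <- list()
    for (cx in complexes) {
      if (length(cx) >= 2L) {
        prs <- utils::combn(sort(cx), 2L)
        pool <- c(pool, lapply(seq_len(ncol(prs)), function(j) prs[, j]))
      }
    }
    pool <- pool[sample.int(length(pool))]
    used <- character(0)
    take <- function(k) {
      out <- list()
      while (length(out) < k && length(pool) > 0L) {
        p <- pool[[1L]]
        pool <<- pool[-1L]
        if (!any(p %in% used)) {
          used <<- c(used, p)
          out[[length(out) + 1L]] <- p
        }
      }
      assert_that(length(out) == k,
                  "not enough disjoint within-complex pairs for requested ME/SC flags")
      do.call(rbind, lapply(out, function(p)
        data.frame(id_a = p[1L], id_b = p[2L], stringsAsFactors = FALSE)))
    }
    me <- if (n_me_pairs > 0L) take(n_me_pairs) else
      data.frame(id_a = character(0), id_b = character(0))
    sc <- if (n_sc_pairs > 0L) take(n_sc_pairs) else
      data.frame(id_a = character(0), id_b = character(0))
    structure(list(complexes = as_complex_list(complexes, "planted"),
                   me_pairs = me, sc_pairs = sc, seed = seed),
              class = "planted_truth")
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth> %d complexes, %d ME pairs, %d SC pairs (seed %d)\n",
              length(x$complexes), nrow(x$me_pairs), nrow(x$sc_pairs), x$seed))
  invisible(x)
}

#' Simulate bait-prey pulldown experiments
#'
#' One experiment per sampled bait: the bait is always present, each of its
#' co-complex partners is detected with probability `detect_prob`, and each
#' protein from a dedicated background pool (never a complex member) appears
#' with probability `background_rate`.
#'
#' @param truth A `planted_truth`.
#' @param n_baits_per_complex Baits sampled per complex (with replacement when
#'   larger than the complex).
#' @param detect_prob Per-prey detection probability.
#' @param background_rate Per-experiment presence probability for each
#'   background protein.
#' @param n_background_proteins Size of the background pool.
#' @param seed Integer seed.
#' @return An `obs_matrix` of strictly binary presence calls.
#' @export
simulate_pulldowns <- function(truth, n_baits_per_complex = 3L,
                               detect_prob = 0.8, background_rate = 0.01,
                               n_background_proteins = 20L, seed = 1L) {
  assert_that(inherits(truth, "planted_truth") && length(truth$complexes) >= 1L,
              "`truth` must be a non-empty planted_truth")
  assert_prob(detect_prob, "detect_prob")
  assert_prob(background_rate, "background_rate")
  assert_count(n_baits_per_complex, "n_baits_per_complex", min = 1L)
  with_seed(seed, {
    bg <- if (n_background_proteins > 0L)
      sprintf("BG%04d", seq_len(n_background_proteins)) else character(0)
    proteins <- sort(unique(c(unlist(truth$complexes), bg)))
    rows <- list()
    exp_ids <- character(0)
    e <- 0L
    for (ci in seq_along(truth$complexes)) {
      members <- truth$complexes[[ci]]
      baits <- sample(members, n_baits_per_complex,
                      replace = n_baits_per_complex > length(members))
      for (bait in baits) {
        e <- e + 1L
        preys <- setdiff(members, bait)
        hit <- preys[runif(length(preys)) < detect_prob]
        noise <- bg[runif(length(bg)) < background_rate]
        rows[[e]] <- c(bait, hit, noise)
        exp_ids[e] <- sprintf("E%05d", e)
      }
    }
    m <- matrix(FALSE, length(proteins), e, dimnames = list(proteins, exp_ids))
    for (j in seq_len(e)) m[rows[[j]], j] <- TRUE
    as_obs_matrix(m)
  })
}

#' Simulate lineage-structured protein expression
#'
#' Every complex gets a latent lineage profile; member abundances are that
#' profile plus Gaussian noise, emulating z-scored relative protein abundances
#' across cancer cell lines. Mutually exclusive pairs get either sign-flipped
#' profiles (`me_mode = "anticorrelated"`) or disjoint lineage support with
#' missing values outside the support (`me_mode = "lineage_exclusive"`).
#'
#' @param truth A `planted_truth`.
#' @param n_lineages,n_lines_per_lineage Panel layout (both >= 2). The default
#'   8 x 15 = 120 cell lines keeps sub-score 3's top/bottom-50 rule usable at
#'   toy scale.
#' @param me_mode One of `"anticorrelated"`, `"lineage_exclusive"`.
#' @param noise_sd Residual noise standard deviation.
#' @param seed Integer seed.
#' @return An `expression_matrix` (proteins x cell lines, lineage attribute).
#' @export
simulate_expression <- function(truth, n_lineages = 8L, n_lines_per_lineage = 15L,
                                me_mode = c("anticorrelated", "lineage_exclusive"),
                                noise_sd = 0.3, seed = 1L) {
  me_mode <- match.arg(me_mode)
  assert_count(n_lineages, "n_lineages", min = 2L)
  assert_count(n_lines_per_lineage, "n_lines_per_lineage", min = 2L)
  assert_that(is.numeric(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  with_seed(seed, {
    lineages <- sprintf("L%02d", seq_len(n_lineages))
    lines <- sprintf("CL%03d", seq_len(n_lineages * n_lines_per_lineage))
    lineage_of <- setNames(rep(lineages, each = n_lines_per_lineage), lines)
    proteins <- sort(unique(unlist(truth$complexes)))
    # latent lineage profile per complex; each protein inherits its first
    # complex. On top of the lineage mean, cell lines carry a shared
    # line-level effect whose spread varies by lineage, so co-complex members
    # co-vary within lineages too (the signal sub-score 4 reads).
    n_cx <- length(truth$complexes)
    profiles <- matrix(rnorm(n_cx * n_lineages, sd = 1.5), n_cx, n_lineages)
    line_scale <- matrix(runif(n_cx * n_lineages, 0.5, 1.5), n_cx, n_lineages)
    line_effects <- matrix(rnorm(n_cx * n_lineages * n_lines_per_lineage),
                           n_cx, n_lineages * n_lines_per_lineage)
    first_cx <- vapply(proteins, function(p) {
      which(vapply(truth$complexes, function(cx) p %in% cx, TRUE))[1L]
    }, 1L)
    sign_of <- setNames(rep(1, length(proteins)), proteins)
    support <- setNames(vector("list", length(proteins)), proteins)
    if (nrow(truth$me_pairs) > 0L) {
      for (r in seq_len(nrow(truth$me_pairs))) {
        a <- truth$me_pairs$id_a[r]; b <- truth$me_pairs$id_b[r]
        if (me_mode == "anticorrelated") {
          sign_of[b] <- -1
        } else {
          half <- sample(lineages, floor(n_lineages / 2))
          support[[a]] <- half
          support[[b]] <- setdiff(lineages, half)
        }
      }
    }
    m <- matrix(NA_real_, length(proteins), length(lines),
                dimnames = list(proteins, lines))
    for (i in seq_along(proteins)) {
      cx <- first_cx[i]
      lin_idx <- match(lineage_of, lineages)
      latent <- profiles[cx, lin_idx] +
        line_effects[cx, ] * line_scale[cx, lin_idx]
      vals <- sign_of[i] * latent + rnorm(length(lines), sd = noise_sd)
      sup <- support[[proteins[i]]]
      if (!is.null(sup)) vals[!(lineage_of %in% sup)] <- NA_real_
      m[i, ] <- vals
    }
    as_expression_matrix(m, lineage_of)
  })
}

#' Simulate a scored co-complex interaction network
#'
#' Within-complex pairs receive high classifier-like confidences
#' (`within_mean` with Gaussian jitter, clipped to [0,1]); a `background_rate`
#' fraction of all non-co-complex pairs receive low uniform scores, emulating
#' classifier false positives.
#'
#' @param truth A `planted_truth`.
#' @param within_mean,within_sd Mean/sd of within-complex edge confidence.
#' @param background_rate Probability that a non-co-complex pair gets an edge.
#' @param background_range Uniform range for background edge confidences.
#' @param seed Integer seed.
#' @return A scored network data frame `id_a`, `id_b`, `score`.
#' @export
simulate_scored_network <- function(truth, within_mean = 0.9, within_sd = 0.05,
                                    background_rate = 0.05,
                                    background_range = c(0.05, 0.35),
                                    seed = 1L) {
  with_seed(seed, {
    pos <- unique(do.call(rbind, lapply(truth$complexes, function(cx) {
      if (length(cx) < 2L) return(NULL)
      t(utils::combn(sort(cx), 2L))
    })))
    pos_keys <- pair_key(pos[, 1L], pos[, 2L])
    proteins <- sort(unique(unlist(truth$complexes)))
    all_pairs <- t(utils::combn(proteins, 2L))
    all_keys <- pair_key(all_pairs[, 1L], all_pairs[, 2L])
    neg <- all_pairs[!(all_keys %in% pos_keys), , drop = FALSE]
    keep <- runif(nrow(neg)) < background_rate
    neg <- neg[keep, , drop = FALSE]
    scores_pos <- pmin(1, pmax(0, rnorm(nrow(pos), within_mean, within_sd)))
    scores_neg <- runif(nrow(neg), background_range[1L], background_range[2L])
    net <- data.frame(id_a = c(pos[, 1L], neg[, 1L]),
                      id_b = c(pos[, 2L], neg[, 2L]),
                      score = c(scores_pos, scores_neg),
                      stringsAsFactors = FALSE)
    net[order(net$id_a, net$id_b), , drop = FALSE]
  })
}

# Helix-like arc of CA positions: radius 2.3 A, 100 degrees per residue,
# 1.5 A rise. Only inter-residue distances matter downstream.
helix_coords <- function(n) {
  i <- seq_len(n) - 1L
  th <- i * 100 * pi / 180
  cbind(x = 2.3 * cos(th), y = 2.3 * sin(th), z = 1.5 * i)
}

# Unique-chain patch: copies of common-chain residues s..s+len-1 pushed
# radially outward so each sits exactly 3.9 A from its partner residue and
# > 4 A from every other common-chain residue.
patch_coords <- function(common, s, len) {
  seg <- common[seq.int(s, s + len - 1L), , drop = FALSE]
  r <- sqrt(seg[, "x"]^2 + seg[, "y"]^2)
  f <- (r + 3.9) / r
  cbind(x = seg[, "x"] * f, y = seg[, "y"] * f, z = seg[, "z"])
}

random_rigid_transform <- function() {
  m <- matrix(rnorm(9L), 3L)
  qr_ <- qr(m)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  list(R = R, t = runif(3L, -20, 20))
}

apply_rigid <- function(coords, trans) {
  sweep(as.matrix(coords) %*% t(trans$R), 2L, -trans$t)
}

#' Build a toy trimer: two dimer models sharing a common chain
#'
#' Constructs CA-only dimer models of unique proteins U1 and U2 each bound to
#' a common protein C (a rigid helix-like arc). With `overlap = TRUE` both
#' unique chains contact the same 12-residue face of C, so the common-chain
#' interface sets intersect in > 10 residues; with `overlap = FALSE` they bind
#' disjoint faces and the intersection is exactly 0. Dimer 2 is emitted under
#' a random rigid transform, exercising the superposition step.
#'
#' @param overlap Whether the two unique chains compete for the same face.
#' @param n_residues_per_chain Residues in the common chain (>= 12; >= 27
#'   needed for two disjoint interfaces).
#' @param seed Integer seed (controls the rigid transform).
#' @param plddt Per-residue pLDDT written into every residue.
#' @param pdockq Model-level interface confidence metadata.
#' @return A `trimer_candidate` (see [as_trimer_candidate()]).
#' @export
make_toy_trimer <- function(overlap, n_residues_per_chain = 32L, seed = 1L,
                            plddt = 90, pdockq = 0.5) {
  assert_count(n_residues_per_chain, "n_residues_per_chain", min = 12L)
  patch_len <- 12L
  s1 <- 1L
  s2 <- if (overlap) 1L else s1 + patch_len + 3L
  if (s2 + patch_len - 1L > n_residues_per_chain)
    stop(sprintf(paste0("n_residues_per_chain = %d is too small to build two ",
                        "disjoint 4 A interfaces (need >= %d)"),
                 n_residues_per_chain, s2 + patch_len - 1L), call. = FALSE)
  with_seed(seed, {
    common <- helix_coords(n_residues_per_chain)
    u1 <- patch_coords(common, s1, patch_len)
    u2 <- patch_coords(common, s2, patch_len)
    mk_chain <- function(coords, resi) {
      data.frame(resi = resi, x = coords[, 1L], y = coords[, 2L],
                 z = coords[, 3L], plddt = plddt)
    }
    d1 <- new_dimer_model("toy_d1", protein_a = "C", protein_b = "U1",
                          chain_a = mk_chain(common, seq_len(n_residues_per_chain)),
                          chain_b = mk_chain(u1, seq.int(s1, s1 + patch_len - 1L)),
                          pdockq = pdockq)
    trans <- random_rigid_transform()
    d2 <- new_dimer_model("toy_d2", protein_a = "C", protein_b = "U2",
                          chain_a = mk_chain(apply_rigid(common, trans),
                                             seq_len(n_residues_per_chain)),
                          chain_b = mk_chain(apply_rigid(u2, trans),
                                             seq.int(s2, s2 + patch_len - 1L)),
                          pdockq = pdockq)
    as_trimer_candidate(d1, d2, common_protein = "C")
  })
}

#' Write planted truth to JSON
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- list(complexes = lapply(truth$complexes, sort),
              me_pairs = truth$me_pairs, sc_pairs = truth$sc_pairs,
              seed = truth$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read planted truth from JSON
#'
#' @param path JSON path written by [write_truth()].
#' @return A `planted_truth`.
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  me <- as.data.frame(obj$me_pairs, stringsAsFactors = FALSE)
  sc <- as.data.frame(obj$sc_pairs, stringsAsFactors = FALSE)
  if (nrow(me) == 0L) me <- data.frame(id_a = character(0), id_b = character(0))
  if (nrow(sc) == 0L) sc <- data.frame(id_a = character(0), id_b = character(0))
  structure(list(complexes = as_complex_list(as.list(obj$complexes), "planted"),
                 me_pairs = me, sc_pairs = sc, seed = obj$seed),
            class = "planted_truth")
}
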