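# Mutual-exclusivity calling. Two proteins that each bind the same common
# partner are mutually exclusive when their interfaces on that partner
# overlap: after quality gating and rigid superposition of the two dimers on
# the common chain, the intersection of the two common-chain interface
# residue sets decides the verdict (> 10 shared residues = mutually
# exclusive, 0 = structurally consistent, 1..10 = inconclusive). Structurally
# consistent candidates additionally pass a chain-clash pLDDT screen that
# separates genuine steric conflicts from poorly modeled regions.

#' Default thresholds for exclusivity calling
#'
#' All published gates in one place: pDockQ > 0.23, interface pLDDT > 70,
#' <= 5 provider-reported chain clashes, alignment RMSD < 10 A, 4.0 A
#' interface cutoff, > 10 overlapping interface residues for mutual
#' exclusivity, chain-clash pLDDT sum < 500, and the residue-clash distance
#' (3.0 A for CA-only models, 2.5 A full-atom).
#'
#' @return Named list of thresholds.
#' @export
exclusivity_thresholds <- function() {
  list(pdockq_min = 0.23, if_plddt_min = 70, max_chain_clashes = 5,
       rmsd_max = 10, interface_cutoff = 4.0, overlap_min = 10,
       clash_plddt_sum_max = 500, clash_cutoff_ca = 3.0,
       clash_cutoff_fullatom = 2.5)
}

#' Quality-gate a dimer model
#'
#' Passes when pDockQ is strictly above `pdockq_min`, the interface pLDDT
#' (mean per-residue pLDDT over the interface residues of both chains) is
#' strictly above `if_plddt_min`, and -- only when the provider supplied an
#' inter-chain clash count -- that count is at most `max_chain_clashes`.
#'
#' @param model A `dimer_model`.
#' @param pdockq_min,if_plddt_min,max_chain_clashes Gates (published values).
#' @param interface_cutoff Interface distance cutoff in Angstrom.
#' @return List `pass` (logical), `reasons` (character), `if_plddt`.
#' @export
quality_filter <- function(model, pdockq_min = 0.23, if_plddt_min = 70,
                           max_chain_clashes = 5, interface_cutoff = 4.0) {
  reasons <- character(0)
  if (!is.finite(model$pdockq) || model$pdockq <= pdockq_min)
    reasons <- c(reasons, "pdockq")
  iface <- interface_residues(model, cutoff = interface_cutoff)
  if_vals <- c(model$chain_a$plddt[model$chain_a$resi %in% iface$chain_a],
               model$chain_b$plddt[model$chain_b$resi %in% iface$chain_b])
  if_plddt <- if (length(if_vals) > 0L) mean(if_vals) else NA_real_
  if (!is.finite(if_plddt) || if_plddt <= if_plddt_min)
    reasons <- c(reasons, "if_plddt")
  if (!is.null(model$clash_count) && model$clash_count > max_chain_clashes)
    reasons <- c(reasons, "chain_clashes")
  list(pass = length(reasons) == 0L, reasons = reasons, if_plddt = if_plddt)
}

#' Count overlapping common-chain interface residues of an aligned trimer
#'
#' The interface residue set of the common chain is identified independently
#' in each dimer (residues within `cutoff` of the unique chain); the overlap
#' is the residue-number intersection of the two sets.
#'
#' @param trimer A superposed `trimer_candidate`.
#' @param cutoff Interface distance cutoff in Angstrom.
#' @return List `n_overlap`, `interface_1`, `interface_2`, `overlap`.
#' @export
count_interface_overlap <- function(trimer, cutoff = 4.0) {
  i1 <- interface_residues(trimer$dimer_1, cutoff = cutoff)$chain_a
  i2 <- interface_residues(trimer$dimer_2, cutoff = cutoff)$chain_a
  ov <- intersect(i1, i2)
  list(n_overlap = length(ov), interface_1 = i1, interface_2 = i2, overlap = ov)
}

#' Chain-clash pLDDT screen for structurally consistent candidates
#'
#' Finds residue clashes between the two unique chains of an aligned trimer
#' (any inter-atom distance below `clash_cutoff`), identifies the chain with
#' the lower mean pLDDT over its clashing residues, and sums that chain's
#' clashing-residue pLDDT. Structurally consistent calls fail when the sum
#' reaches `plddt_sum_max`.
#'
#' @param trimer A superposed `trimer_candidate`.
#' @param plddt_sum_max Gate on the summed clash pLDDT (published value 500).
#' @param clash_cutoff Clash distance in Angstrom; defaults to 3.0 for
#'   CA-only models and 2.5 when side-chain atoms are present.
#' @return List `clash_plddt_sum`, `pass`, `n_clash_1`, `n_clash_2`.
#' @export
chain_clash_screen <- function(trimer, plddt_sum_max = 500,
                               clash_cutoff = NULL) {
  u1 <- trimer$dimer_1$chain_b
  u2 <- trimer$dimer_2$chain_b
  if (is.null(clash_cutoff)) {
    ca_only <- all(u1$atom == "CA") && all(u2$atom == "CA")
    th <- exclusivity_thresholds()
    clash_cutoff <- if (ca_only) th$clash_cutoff_ca else th$clash_cutoff_fullatom
  }
  m <- min_residue_distances(u1, u2)
  clash_1 <- as.integer(rownames(m)[apply(m, 1L, min) < clash_cutoff])
  clash_2 <- as.integer(colnames(m)[apply(m, 2L, min) < clash_cutoff])
  if (length(clash_1) == 0L && length(clash_2) == 0L)
    return(list(clash_plddt_sum = 0, pass = TRUE, n_clash_1 = 0L, n_clash_2 = 0L))
  plddt_of <- function(ch, resis) {
    vapply(resis, function(r) mean(ch$plddt[ch$resi == r]), 0)
  }
  p1 <- plddt_of(u1, clash_1); p2 <- plddt_of(u2, clash_2)
  m1 <- if (length(p1)) mean(p1) else Inf
  m2 <- if (length(p2)) mean(p2) else Inf
  s <- if (m1 <= m2) sum(p1) else sum(p2)
  list(clash_plddt_sum = s, pass = s < plddt_sum_max,
       n_clash_1 = length(clash_1), n_clash_2 = length(clash_2))
}

#' Classify a trimer candidate as mutually exclusive or structurally consistent
#'
#' Full pipeline: quality-gate both dimers, superpose on the common chain
#' (discard at RMSD >= 10 A), count the common-chain interface overlap, and
#' apply the chain-clash pLDDT screen to structurally consistent candidates.
#'
#' @param trimer A `trimer_candidate`.
#' @param thresholds Threshold list, see [exclusivity_thresholds()].
#' @return An `exclusivity_call`: one-row data frame with `unique_1`,
#'   `unique_2`, `common_protein`, `verdict` (`mutually_exclusive`,
#'   `structurally_consistent`, `inconclusive`, or `filtered`), `rmsd_align`,
#'   `n_overlap_interface`, `clash_plddt_sum`, `filter_reasons`.
#' @export
classify_trimer <- function(trimer, thresholds = exclusivity_thresholds()) {
  th <- modifyList(exclusivity_thresholds(), thresholds)
  out <- data.frame(unique_1 = trimer$unique_1, unique_2 = trimer$unique_2,
                    common_protein = trimer$common_protein,
                    verdict = NA_character_, rmsd_align = NA_real_,
                    n_overlap_interface = NA_integer_,
                    clash_plddt_sum = NA_real_, filter_reasons = "",
                    stringsAsFactors = FALSE)
  q1 <- quality_filter(trimer$dimer_1, th$pdockq_min, th$if_plddt_min,
                       th$max_chain_clashes, th$interface_cutoff)
  q2 <- quality_filter(trimer$dimer_2, th$pdockq_min, th$if_plddt_min,
                       th$max_chain_clashes, th$interface_cutoff)
  if (!q1$pass || !q2$pass) {
    out$verdict <- "filtered"
    out$filter_reasons <- paste(unique(c(q1$reasons, q2$reasons)), collapse = ",")
    return(structure(out, class = c("exclusivity_call", "data.frame")))
  }
  sup <- superpose_on_common(trimer)
  out$rmsd_align <- sup$rmsd
  if (sup$rmsd >= th$rmsd_max) {
    out$verdict <- "filtered"
    out$filter_reasons <- "rmsd"
    return(structure(out, class = c("exclusivity_call", "data.frame")))
  }
  ov <- count_interface_overlap(sup$trimer, cutoff = th$interface_cutoff)
  out$n_overlap_interface <- ov$n_overlap
  if (ov$n_overlap > th$overlap_min) {
    out$verdict <- "mutually_exclusive"
  } else if (ov$n_overlap == 0L) {
    cs <- chain_clash_screen(sup$trimer, plddt_sum_max = th$clash_plddt_sum_max)
    out$clash_plddt_sum <- cs$clash_plddt_sum
    if (cs$pass) {
      out$verdict <- "structurally_consistent"
    } else {
      out$verdict <- "filtered"
      out$filter_reasons <- "chain_clash_plddt"
    }
  } else {
    out$verdict <- "inconclusive"
  }
  structure(out, class = c("exclusivity_call", "data.frame"))
}

#' Consolidate exclusivity calls across common subunits
#'
#' Drops calls whose common protein is a known homomultimer (it may present
#' identical interfaces twice), then, per unique protein pair, keeps the
#' consensus verdict across common proteins and drops pairs whose verdicts
#' conflict (mutually exclusive via one common subunit, structurally
#' consistent via another).
#'
#' @param calls A list of `exclusivity_call` rows or a data frame of them.
#' @param homomultimer_ids Identifiers of common proteins known to
#'   homomultimerize.
#' @return Data frame: one row per retained pair with `verdict`,
#'   `n_support`, `common_proteins` (comma-joined).
#' @export
resolve_pair_calls <- function(calls, homomultimer_ids = character(0)) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- do.call(rbind, calls)
  calls <- calls[!(calls$common_protein %in% homomultimer_ids), , drop = FALSE]
  calls <- calls[calls$verdict %in% c("mutually_exclusive",
                                      "structurally_consistent"), , drop = FALSE]
  if (nrow(calls) == 0L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      verdict = character(0), n_support = integer(0),
                      common_proteins = character(0)))
  key <- pair_key(calls$unique_1, calls$unique_2)
  out <- lapply(split(seq_len(nrow(calls)), key), function(ix) {
    verdicts <- unique(calls$verdict[ix])
    if (length(verdicts) > 1L) return(NULL)   # conflicting across commons
    parts <- strsplit(key[ix[1L]], "\t", fixed = TRUE)[[1L]]
    data.frame(id_a = parts[1L], id_b = parts[2L], verdict = verdicts,
               n_support = length(ix),
               common_proteins = paste(sort(unique(calls$common_protein[ix])),
                                       collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(id_a = character(0), id_b = character(0),
                      verdict = character(0), n_support = integer(0),
                      common_proteins = character(0)))
  rownames(out) <- NULL
  out
}
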