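# Structural containers and geometry: dimer models (two chains with
# per-residue coordinates and pLDDT), minimal PDB ATOM-record I/O, and
# least-squares rigid superposition (Kabsch with proper-rotation
# enforcement). Models may be CA-only or full-atom; all distance operations
# run over whatever atoms are present.

#' Construct a dimer model
#'
#' @param model_id Model identifier.
#' @param protein_a,protein_b Protein identifiers for chains A and B.
#' @param chain_a,chain_b Data frames with columns `resi`, `x`, `y`, `z`,
#'   `plddt` (one row per atom; CA-only models have one row per residue). An
#'   optional `atom` column names the atom.
#' @param pdockq Model-level interface confidence in [0, 1].
#' @param clash_count Optional precomputed inter-chain residue clash count
#'   from the model provider (used by [quality_filter()] when present).
#' @param source_tag Free-text provenance.
#' @return A `dimer_model`.
#' @export
new_dimer_model <- function(model_id, protein_a, protein_b, chain_a, chain_b,
                            pdockq = NA_real_, clash_count = NULL,
                            source_tag = "unspecified") {
  check_chain <- function(ch, nm) {
    assert_that(is.data.frame(ch) && nrow(ch) >= 1L &&
                  all(c("resi", "x", "y", "z", "plddt") %in% names(ch)),
                sprintf("chain %s needs >= 1 residue with resi/x/y/z/plddt", nm))
    assert_that(all(is.finite(ch$x)) && all(is.finite(ch$y)) && all(is.finite(ch$z)),
                sprintf("chain %s has non-finite coordinates", nm))
    assert_that(all(ch$plddt >= 0 & ch$plddt <= 100),
                sprintf("chain %s pLDDT outside [0, 100]", nm))
    if (!"atom" %in% names(ch)) ch$atom <- "CA"
    ch
  }
  structure(list(model_id = model_id,
                 proteins = c(a = protein_a, b = protein_b),
                 chain_a = check_chain(chain_a, "A"),
                 chain_b = check_chain(chain_b, "B"),
                 pdockq = pdockq, clash_count = clash_count,
                 source_tag = source_tag),
            class = "dimer_model")
}

#' @export
print.dimer_model <- function(x, ...) {
  cat(sprintf("<dimer_model> %s: %s (%d atoms) / %s (%d atoms), pDockQ %.3g\n",
              x$model_id, x$proteins[["a"]], nrow(x$chain_a),
              x$proteins[["b"]], nrow(x$chain_b), x$pdockq))
  invisible(x)
}

#' Pair two dimers sharing a common protein into a trimer candidate
#'
#' @param dimer_1,dimer_2 `dimer_model` objects; each must contain
#'   `common_protein` as one of its chains.
#' @param common_protein Identifier of the shared subunit.
#' @return A `trimer_candidate` with fields `dimer_1`, `dimer_2`,
#'   `common_protein`, `unique_1`, `unique_2`. Chains are reordered so chain
#'   A of both dimers is the common protein.
#' @export
as_trimer_candidate <- function(dimer_1, dimer_2, common_protein) {
  orient <- function(d) {
    if (d$proteins[["a"]] == common_protein) return(d)
    assert_that(d$proteins[["b"]] == common_protein,
                sprintf("dimer %s does not contain common protein %s",
                        d$model_id, common_protein))
    tmp <- d$chain_a; d$chain_a <- d$chain_b; d$chain_b <- tmp
    d$proteins <- c(a = unname(d$proteins[["b"]]), b = unname(d$proteins[["a"]]))
    d
  }
  d1 <- orient(dimer_1); d2 <- orient(dimer_2)
  u1 <- d1$proteins[["b"]]; u2 <- d2$proteins[["b"]]
  assert_that(u1 != u2, "the two dimers must contribute distinct unique proteins")
  structure(list(dimer_1 = d1, dimer_2 = d2, common_protein = common_protein,
                 unique_1 = u1, unique_2 = u2),
            class = "trimer_candidate")
}

#' Read a minimal PDB file into a dimer model
#'
#' Parses ATOM records from a two-chain PDB file: chain id column 22, residue
#' number 23-26, coordinates 31-54, pLDDT from the B-factor columns 61-66.
#'
#' @param path PDB file path.
#' @param model_id Model identifier (defaults to the file name).
#' @param proteins Length-2 character vector naming the proteins of the
#'   first and second chain encountered.
#' @param pdockq,clash_count,source_tag Metadata attached to the model.
#' @return A `dimer_model`.
#' @export
read_pdb_dimer <- function(path, model_id = basename(path), proteins = NULL,
                           pdockq = NA_real_, clash_count = NULL,
                           source_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  atoms <- lines[startsWith(lines, "ATOM")]
  assert_that(length(atoms) > 0L, sprintf("no ATOM records in %s", path))
  fld <- function(a, b) trimws(substring(atoms, a, b))
  df <- data.frame(atom = fld(13, 16), chain = fld(22, 22),
                   resi = as.integer(fld(23, 26)),
                   x = as.numeric(fld(31, 38)), y = as.numeric(fld(39, 46)),
                   z = as.numeric(fld(47, 54)),
                   plddt = as.numeric(fld(61, 66)),
                   stringsAsFactors = FALSE)
  chains <- unique(df$chain)
  assert_that(length(chains) == 2L,
              sprintf("%s must contain exactly two chains, found %d",
                      path, length(chains)))
  if (is.null(proteins)) proteins <- chains
  pick <- function(ch) df[df$chain == ch, c("resi", "atom", "x", "y", "z", "plddt")]
  new_dimer_model(model_id, proteins[1L], proteins[2L],
                  pick(chains[1L]), pick(chains[2L]),
                  pdockq = pdockq, clash_count = clash_count,
                  source_tag = source_tag)
}

#' Write a dimer model as a minimal PDB file
#'
#' @param dimer A `dimer_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb_dimer <- function(dimer, path) {
  serial <- 0L
  fmt_chain <- function(ch, chain_id) {
    vapply(seq_len(nrow(ch)), function(i) {
      serial <<- serial + 1L
      sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
              serial, substr(ch$atom[i], 1, 4), "ALA", chain_id, ch$resi[i],
              ch$x[i], ch$y[i], ch$z[i], 1.0, ch$plddt[i])
    }, "")
  }
  lines <- c(fmt_chain(dimer$chain_a, "A"), "TER",
             fmt_chain(dimer$chain_b, "B"), "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

chain_coords <- function(ch) as.matrix(ch[, c("x", "y", "z")])

# Minimum inter-atom distance matrix between residues of two chains, returned
# as the per-residue-pair minimum. Chains are small (<= a few thousand
# atoms); an all-vs-all distance is fine.
min_residue_distances <- function(chain_x, chain_y) {
  cx <- chain_coords(chain_x); cy <- chain_coords(chain_y)
  d2 <- outer(rowSums(cx^2), rowSums(cy^2), "+") - 2 * tcrossprod(cx, cy)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  rx <- chain_x$resi; ry <- chain_y$resi
  ux <- sort(unique(rx)); uy <- sort(unique(ry))
  m <- matrix(Inf, length(ux), length(uy), dimnames = list(ux, uy))
  for (i in seq_along(ux)) {
    rows <- rx == ux[i]
    mins <- apply(d[rows, , drop = FALSE], 2L, min)
    m[i, ] <- vapply(seq_along(uy), function(j) min(mins[ry == uy[j]]), 0)
  }
  m
}

#' Interface residues of a dimer
#'
#' A residue is an interface residue if any of its atoms lies within `cutoff`
#' of any atom of the other chain.
#'
#' @param dimer A `dimer_model`.
#' @param cutoff Distance cutoff in Angstrom (published value 4.0).
#' @return List with `chain_a` and `chain_b`: sorted integer residue numbers.
#' @export
interface_residues <- function(dimer, cutoff = 4.0) {
  assert_that(nrow(dimer$chain_a) >= 1L && nrow(dimer$chain_b) >= 1L,
              "both chains must be non-empty")
  m <- min_residue_distances(dimer$chain_a, dimer$chain_b)
  list(chain_a = as.integer(rownames(m)[apply(m, 1L, min) <= cutoff]),
       chain_b = as.integer(colnames(m)[apply(m, 2L, min) <= cutoff]))
}

# Kabsch: optimal proper rotation + translation mapping `moving` onto
# `fixed` (n x 3 matrices, matched rows), and the residual RMSD.
kabsch <- function(fixed, moving) {
  cf <- colMeans(fixed); cm <- colMeans(moving)
  A <- sweep(fixed, 2L, cf); B <- sweep(moving, 2L, cm)
  H <- crossprod(B, A)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- B %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - A)^2)))
  list(R = R, t_fixed = cf, t_moving = cm, rmsd = rmsd)
}

apply_kabsch <- function(coords, k) {
  sweep(sweep(coords, 2L, k$t_moving) %*% t(k$R), 2L, -k$t_fixed)
}

#' Superpose a trimer's second dimer onto the first via the common chain
#'
#' Least-squares rigid superposition (proper rotation enforced) of dimer 2's
#' common chain onto dimer 1's, over residues matched by residue number; the
#' transform is then applied to all of dimer 2.
#'
#' @param trimer A `trimer_candidate`.
#' @return List with `rmsd` (Angstrom, over matched common-chain atoms) and
#'   `trimer` (the candidate with dimer 2 transformed into dimer 1's frame).
#' @export
superpose_on_common <- function(trimer) {
  c1 <- trimer$dimer_1$chain_a; c2 <- trimer$dimer_2$chain_a
  shared <- intersect(unique(c1$resi), unique(c2$resi))
  if (length(shared) < 3L)
    stop("common chains share fewer than 3 residues; cannot superpose",
         call. = FALSE)
  # match on (resi, atom) so full-atom and CA-only models both align
  k1 <- paste(c1$resi, c1$atom); k2 <- paste(c2$resi, c2$atom)
  common_keys <- intersect(k1[c1$resi %in% shared], k2[c2$resi %in% shared])
  assert_that(length(common_keys) >= 3L, "fewer than 3 matched atoms")
  f <- chain_coords(c1)[match(common_keys, k1), , drop = FALSE]
  m <- chain_coords(c2)[match(common_keys, k2), , drop = FALSE]
  k <- kabsch(f, m)
  d2 <- trimer$dimer_2
  for (ch in c("chain_a", "chain_b")) {
    xyz <- apply_kabsch(chain_coords(d2[[ch]]), k)
    d2[[ch]]$x <- xyz[, 1L]; d2[[ch]]$y <- xyz[, 2L]; d2[[ch]]$z <- xyz[, 3L]
  }
  trimer$dimer_2 <- d2
  list(rmsd = k$rmsd, trimer = trimer)
}
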