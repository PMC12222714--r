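# Readers and writers for the plain-text interchange formats used throughout:
# complex lists (one complex per line, tab-separated identifiers), long-format
# presence tables, pair/feature TSVs, expression matrices with a lineage
# sidecar, and GMT annotation sets.

#' Read a complex list
#'
#' Complexes are stored as tab-separated lists of protein identifiers, one
#' complex per line (the Complex Portal flat-file convention).
#'
#' @param path File path.
#' @param source_tag Free-text provenance tag attached to the result.
#' @param strip_isoforms Drop isoform suffixes (`"-<n>"`) from UniProt-style
#'   identifiers, collapsing duplicates within a complex.
#' @return A `complex_list` object: a list of character vectors with a
#'   `source_tag` attribute.
#' @export
read_complexes <- function(path, source_tag = basename(path),
                           strip_isoforms = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  complexes <- lapply(strsplit(lines, "\t", fixed = TRUE), function(x) {
    x <- trimws(x)
    x <- x[nzchar(x)]
    if (strip_isoforms) x <- sub("-[0-9]+$", "", x)
    unique(x)
  })
  as_complex_list(complexes, source_tag = source_tag)
}

#' Construct a complex list object
#'
#' @param complexes List of character vectors of member identifiers.
#' @param source_tag Free-text provenance tag.
#' @return A `complex_list`.
#' @export
as_complex_list <- function(complexes, source_tag = "unspecified") {
  assert_that(is.list(complexes), "`complexes` must be a list of id vectors")
  complexes <- lapply(complexes, function(x) unique(as.character(x)))
  assert_that(all(lengths(complexes) >= 1L), "empty complex in input")
  structure(complexes, source_tag = source_tag, class = "complex_list")
}

#' @export
print.complex_list <- function(x, ...) {
  cat(sprintf("<complex_list> %d complexes, %d proteins (source: %s)\n",
              length(x), length(unique(unlist(x))),
              attr(x, "source_tag")))
  invisible(x)
}

#' Write a complex list
#'
#' @param complexes A `complex_list` or plain list of identifier vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(complexes, path) {
  lines <- vapply(complexes, function(x) paste(sort(x), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a long-format observation table into a presence matrix
#'
#' Expects a TSV with header `protein_id`, `experiment_id`, `present` (0/1)
#' and an optional `score` column used by [threshold_observations()].
#'
#' @param path File path.
#' @return An `obs_matrix` (see [as_obs_matrix()]); any `score` column is kept
#'   in the `score` attribute as a matrix aligned with the presence matrix.
#' @export
read_observations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(all(c("protein_id", "experiment_id", "present") %in% names(df)),
              "observation TSV needs columns protein_id, experiment_id, present")
  df <- df[df$present != 0, , drop = FALSE]
  proteins <- sort(unique(as.character(df$protein_id)))
  experiments <- sort(unique(as.character(df$experiment_id)))
  m <- matrix(FALSE, length(proteins), length(experiments),
              dimnames = list(proteins, experiments))
  idx <- cbind(match(df$protein_id, proteins), match(df$experiment_id, experiments))
  m[idx] <- TRUE
  score <- NULL
  if ("score" %in% names(df)) {
    score <- matrix(NA_real_, length(proteins), length(experiments),
                    dimnames = list(proteins, experiments))
    score[idx] <- df$score
  }
  as_obs_matrix(m, score = score)
}

#' Construct an observation (presence) matrix
#'
#' @param presence Logical or 0/1 matrix, proteins in rows (rownames) and
#'   experiments in columns (colnames).
#' @param score Optional numeric matrix of auxiliary per-entry scores with the
#'   same shape, `NA` where absent.
#' @param prune Drop proteins present in no experiment (the load-time rule).
#' @return An `obs_matrix` object.
#' @export
as_obs_matrix <- function(presence, score = NULL, prune = TRUE) {
  presence <- as.matrix(presence)
  storage.mode(presence) <- "logical"
  assert_that(!is.null(rownames(presence)) && !is.null(colnames(presence)),
              "presence matrix needs protein rownames and experiment colnames")
  assert_that(!anyDuplicated(rownames(presence)) && !anyDuplicated(colnames(presence)),
              "identifiers must be unique")
  assert_that(ncol(presence) >= 1L, "need at least one experiment")
  if (prune) {
    keep <- rowSums(presence) > 0L
    presence <- presence[keep, , drop = FALSE]
    if (!is.null(score)) score <- score[keep, , drop = FALSE]
  }
  assert_that(nrow(presence) >= 1L, "observation matrix has no present proteins")
  structure(list(presence = presence, score = score), class = "obs_matrix")
}

#' @export
print.obs_matrix <- function(x, ...) {
  cat(sprintf("<obs_matrix> %d proteins x %d experiments, %d present entries\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' Write an observation matrix as a long-format TSV
#'
#' Emits one row per present (protein, experiment) entry, plus a `score`
#' column when scores are attached.
#'
#' @param obs An `obs_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  idx <- which(obs$presence, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(protein_id = rownames(obs$presence)[idx[, 1L]],
                   experiment_id = colnames(obs$presence)[idx[, 2L]],
                   present = 1L, stringsAsFactors = FALSE)
  if (!is.null(obs$score)) df$score <- obs$score[idx]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write pair tables
#'
#' Pair TSVs have columns `id_a`, `id_b` and any further numeric columns
#' (features, scores, labels). Pairs are canonicalized on read.
#'
#' @param path File path.
#' @return Data frame with canonical `id_a < id_b`.
#' @export
read_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(all(c("id_a", "id_b") %in% names(df)),
              "pair TSV needs id_a and id_b columns")
  swap <- df$id_a > df$id_b
  tmp <- df$id_a[swap]
  df$id_a[swap] <- df$id_b[swap]
  df$id_b[swap] <- tmp
  df
}

#' @rdname read_pairs
#' @param pairs Data frame with `id_a`, `id_b` plus value columns.
#' @export
write_pairs <- function(pairs, path) {
  num <- vapply(pairs, is.numeric, TRUE)
  pairs[num] <- lapply(pairs[num], function(x) {
    ifelse(is.na(x), NA, sprintf("%.10g", x))
  })
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write expression matrices with a lineage sidecar
#'
#' The expression TSV has proteins in rows (first column `protein_id`) and
#' cell lines in columns; missing values are empty fields or `NA`. The lineage
#' map TSV has columns `cell_line`, `lineage`.
#'
#' @param path Expression TSV path.
#' @param lineage_path Lineage map TSV path.
#' @return An `expression_matrix`: numeric matrix with a `lineage` attribute
#'   (named character vector over cell lines).
#' @export
read_expression <- function(path, lineage_path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  lin <- utils::read.table(lineage_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lineage <- setNames(as.character(lin$lineage), lin$cell_line)
  as_expression_matrix(m, lineage)
}

#' Construct an expression matrix object
#'
#' @param m Numeric matrix, proteins x cell lines, `NA` for not-detected.
#' @param lineage Named character vector mapping every cell line (column) to a
#'   lineage label.
#' @return An `expression_matrix`.
#' @export
as_expression_matrix <- function(m, lineage) {
  assert_that(all(colnames(m) %in% names(lineage)),
              "every cell line needs a lineage label")
  attr(m, "lineage") <- lineage[colnames(m)]
  class(m) <- c("expression_matrix", class(m))
  m
}

#' @rdname read_expression
#' @param expr An `expression_matrix`.
#' @export
write_expression <- function(expr, path, lineage_path) {
  df <- data.frame(protein_id = rownames(expr), stringsAsFactors = FALSE)
  vals <- unclass(expr)
  attr(vals, "lineage") <- NULL
  df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  lin <- data.frame(cell_line = colnames(expr),
                    lineage = unname(attr(expr, "lineage")))
  utils::write.table(lin, lineage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT annotation file
#'
#' Standard GMT: term id, term name, then member identifiers, tab-separated.
#'
#' @param path File path.
#' @param ontology_tag Tag recorded on the result.
#' @return An `annotation_set`: named list of member vectors with `term_name`
#'   and `ontology` attributes.
#' @export
read_gmt <- function(path, ontology_tag = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  names_ <- vapply(parts, function(p) if (length(p) >= 2L) p[[2L]] else "", "")
  members <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  as_annotation_set(setNames(members, ids), setNames(names_, ids), ontology_tag)
}

#' @rdname read_gmt
#' @param terms Named list: term id -> member identifier vector.
#' @param term_names Named character vector of human-readable term names.
#' @export
as_annotation_set <- function(terms, term_names = setNames(names(terms), names(terms)),
                              ontology_tag = "unspecified") {
  assert_that(all(lengths(terms) >= 1L), "annotation term with no members")
  structure(terms, term_name = term_names[names(terms)],
            ontology = ontology_tag, class = "annotation_set")
}

#' @rdname read_gmt
#' @param anno An `annotation_set`.
#' @export
write_gmt <- function(anno, path) {
  nm <- attr(anno, "term_name")
  lines <- vapply(seq_along(anno), function(i) {
    paste(c(names(anno)[i], nm[[i]], anno[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a scored interaction network
#'
#' TSV with columns `id_a`, `id_b`, `score` (classifier confidence in [0,1]).
#'
#' @param path File path.
#' @return Data frame `id_a`, `id_b`, `score`, canonicalized.
#' @export
read_network <- function(path) {
  net <- read_pairs(path)
  assert_that("score" %in% names(net), "network TSV needs a score column")
  assert_that(all(net$score >= 0 & net$score <= 1), "scores must lie in [0,1]")
  net
}

#' @rdname read_network
#' @param net Data frame `id_a`, `id_b`, `score`.
#' @export
write_network <- function(net, path) write_pairs(net, path)
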