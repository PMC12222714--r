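# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without touching the caller's
# stream. RNG kind is pinned so fixed seeds are byte-identical across
# platforms and R sessions.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  has_old <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "Mersenne-Twister",
                            normal.kind = "Inversion", sample.kind = "Rejection"))
  force(expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 0L) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
                x == floor(x) && x >= min,
              sprintf("`%s` must be a single integer >= %d", name, min))
}

assert_prob <- function(x, name) {
  assert_that(is.numeric(x) && length(x) == 1L && is.finite(x) &&
                x >= 0 && x <= 1,
              sprintf("`%s` must be a probability in [0, 1]", name))
}

# Canonical string key for an unordered pair: smaller id first, "\t" joined.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

#' Canonicalize unordered protein pairs
#'
#' Stores each pair with the lexicographically smaller identifier first and
#' collapses duplicates. Self-pairs are rejected: a protein cannot form a
#' co-complex pair with itself.
#'
#' @param pairs A two-column data frame (or matrix) of identifiers.
#' @return A two-column data frame `id_a`, `id_b` with `id_a < id_b`,
#'   duplicate-free, in first-appearance order.
#' @export
canonicalize_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  assert_that(ncol(pairs) >= 2L, "`pairs` must have two columns")
  a <- as.character(pairs[[1L]])
  b <- as.character(pairs[[2L]])
  if (any(a == b)) {
    bad <- a[a == b][1L]
    stop(sprintf("self-pair (%s, %s) is not a valid protein pair", bad, bad),
         call. = FALSE)
  }
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\t"))
  data.frame(id_a = lo[keep], id_b = hi[keep], stringsAsFactors = FALSE)
}

# Jaccard coefficient of two identifier sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

# Deterministic complex-set ordering: descending size, then lexicographic on
# the sorted member string. Used wherever "remove the larger" needs a tie-break.
order_complexes <- function(complexes) {
  sizes <- lengths(complexes)
  keys <- vapply(complexes, function(x) paste(sort(x), collapse = "\t"), "")
  order(-sizes, keys)
}

complex_key <- function(members) paste(sort(members), collapse = "\t")
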