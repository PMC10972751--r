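## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a global seed
#'
#' One global seed deterministically derives per-stage seeds so that stages
#' are independently reproducible. The derivation hashes the stage name into
#' a 31-bit integer offset.
#'
#' @param seed Global integer seed.
#' @param stage Character stage name.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1009201L
  as.integer((abs(seed) %% 1000003L) * 2001L + h) %% 2147483647L
}

## Encode a character alignment matrix (rows = sequences) to integer codes
## 1..20, NA for gaps/ambiguity.
encode_alignment <- function(aln) {
  stopifnot(is.matrix(aln))
  codes <- match(toupper(aln), AA_ALPHABET)
  m <- matrix(codes, nrow = nrow(aln), dimnames = dimnames(aln))
  m
}

## Compress alignment columns into site patterns.
## Returns list(patterns = integer matrix [rows x npat], weights, index) where
## index maps each original site to its pattern column.
compress_patterns <- function(enc) {
  key <- apply(enc, 2L, paste, collapse = "\r")
  idx <- match(key, unique(key))
  keep <- !duplicated(key)
  list(patterns = enc[, keep, drop = FALSE],
       weights = as.vector(table(factor(idx, levels = seq_len(sum(keep))))),
       index = idx)
}

## Assert a phylo object is rooted and return it with singletons collapsed.
check_rooted <- function(phy) {
  if (!inherits(phy, "phylo")) stop("expected a 'phylo' tree")
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  phy
}

## Node ages (tips 0) from an ultrametric phylo; uses branch lengths.
node_ages_from_lengths <- function(phy) {
  depths <- ape::node.depth.edgelength(phy)
  max(depths) - depths
}

## Deterministic RNG scope: evaluate expr with a local seed, restoring the
## caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
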