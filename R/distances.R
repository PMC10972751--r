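#' Maximum-likelihood pairwise distance
#'
#' Under the equal-rates (Poisson) amino-acid model the ML distance has the
#' closed form \eqn{d = -(19/20)\,\log(1 - (20/19)\,p)} where \eqn{p} is the
#' proportion of differing sites among shared ungapped positions. For other
#' models the two-sequence likelihood is maximized numerically. Saturated
#' pairs (where the logarithm argument is non-positive) return \code{Inf}
#' with attribute \code{saturated = TRUE}.
#'
#' @param seqA,seqB Character vectors of residues or single sequence strings
#'   of equal length.
#' @param model A \code{\link{substitution_model}}.
#' @return The distance in expected substitutions per site.
#' @examples
#' ml_distance(strrep("A", 100), strrep("A", 100)) # 0
#' @export
ml_distance <- function(seqA, seqB, model = poisson_model()) {
  if (length(seqA) == 1L) seqA <- strsplit(seqA, "")[[1]]
  if (length(seqB) == 1L) seqB <- strsplit(seqB, "")[[1]]
  if (length(seqA) != length(seqB)) stop("sequences must have equal length")
  a <- match(toupper(seqA), AA_ALPHABET)
  b <- match(toupper(seqB), AA_ALPHABET)
  shared <- !is.na(a) & !is.na(b)
  n <- sum(shared)
  if (n == 0L) stop("no shared ungapped sites")
  p <- sum(a[shared] != b[shared]) / n
  if (model$poisson && length(model$rates) == 1L) {
    arg <- 1 - 20 * p / 19
    if (arg <= 0) return(structure(Inf, saturated = TRUE))
    return(max(0, -(19 / 20) * log(arg)))
  }
  ## numeric ML for general models from the 20x20 pair count table
  tab <- matrix(0, 20, 20)
  idx <- cbind(a[shared], b[shared])
  for (r in seq_len(nrow(idx))) tab[idx[r, 1], idx[r, 2]] <- tab[idx[r, 1], idx[r, 2]] + 1
  nll <- function(d) {
    P <- transition_probabilities(model, d)
    lp <- log(pmax(model$freqs * P, 1e-300))
    -sum(tab * lp)
  }
  if (p == 0) return(0)
  opt <- stats::optimize(nll, interval = c(1e-9, 20), tol = 1e-9)
  if (opt$minimum > 19) return(structure(Inf, saturated = TRUE))
  opt$minimum
}

#' Pairwise ML distance matrix
#'
#' Vectorized over all sequence pairs of an alignment; shared-site and
#' mismatch counts are accumulated with indicator-matrix products.
#'
#' @param alignment Character matrix, named sequence vector or
#'   \code{AAStringSet}.
#' @param model A \code{\link{substitution_model}}.
#' @param saturated Replacement value for saturated pairs (default
#'   \code{NA}); use a large finite value to keep downstream neighbor
#'   joining applicable.
#' @return A symmetric matrix of distances with zero diagonal.
#' @export
ml_distance_matrix <- function(alignment, model = poisson_model(),
                               saturated = NA_real_) {
  aln <- .aln_matrix(alignment)
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  G <- !is.na(enc)
  mode(G) <- "numeric"
  shared <- G %*% t(G)
  same <- matrix(0, n, n)
  for (s in seq_len(20)) {
    A <- enc == s
    A[is.na(A)] <- FALSE
    mode(A) <- "numeric"
    same <- same + A %*% t(A)
  }
  p <- 1 - same / pmax(shared, 1)
  if (model$poisson && length(model$rates) == 1L) {
    arg <- 1 - 20 * p / 19
    D <- ifelse(arg > 0, -(19 / 20) * log(pmax(arg, 1e-300)), saturated)
  } else {
    D <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d <- ml_distance(aln[i, ], aln[j, ], model)
      D[i, j] <- D[j, i] <- if (is.finite(d)) d else saturated
    }
  }
  diag(D) <- 0
  D[shared == 0] <- saturated
  dimnames(D) <- list(rownames(aln), rownames(aln))
  D
}

#' Neighbor joining
#'
#' Standard NJ agglomeration on a symmetric distance matrix; recovers
#' additive metrics exactly. Three taxa are resolved by the three-point
#' formulas. Tie-breaking follows the first index encountered, which makes
#' the result deterministic.
#'
#' @param D Symmetric numeric matrix with zero diagonal and finite entries,
#'   row/column names used as tip labels.
#' @return An unrooted \code{phylo} tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (n < 3) stop("need at least 3 taxa")
  if (n == 3L) {
    lab <- rownames(D)
    x <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    y <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    z <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", lab[1], max(x, 0),
                   lab[2], max(y, 0), lab[3], max(z, 0))
    return(ape::read.tree(text = txt))
  }
  ape::nj(D)
}
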