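## Nonparametric bootstrap supports by site resampling.

## Default tree builder: NJ on ML distances (saturated pairs replaced by a
## large finite distance so NJ stays applicable).
.nj_ml_builder <- function(model) {
  force(model)
  function(alignment) {
    D <- ml_distance_matrix(alignment, model, saturated = 8)
    neighbor_joining(D)
  }
}

#' Bootstrap support by site resampling
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with \code{builder}, and reports for each internal branch of the
#' reference tree the percentage of replicates containing that bipartition
#' (BP). With the default builder (neighbor joining on ML distances under the
#' Poisson model) replicates are computed from resampled site-pattern weights,
#' which avoids rebuilding alignments.
#'
#' @inheritParams log_likelihood
#' @param builder Function \code{alignment -> phylo}; default NJ on ML
#'   distances.
#' @param n Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param reference Optional reference tree; default \code{builder(alignment)}.
#' @return The reference tree with supports (0-100) in \code{node.label}.
#' @export
bootstrap_support <- function(alignment, model = poisson_model(),
                              builder = NULL, n = 100L, seed = 1L,
                              reference = NULL) {
  stopifnot(n >= 1)
  aln <- .aln_matrix(alignment)
  fast <- is.null(builder) && model$poisson && length(model$rates) == 1L
  if (is.null(builder)) builder <- .nj_ml_builder(model)
  if (is.null(reference)) reference <- builder(aln)
  nsites <- ncol(aln)
  trees <- vector("list", n)
  if (fast) {
    enc <- encode_alignment(aln)
    cp <- compress_patterns(enc)
    pat <- cp$patterns
    npat <- ncol(pat)
    ntax <- nrow(enc)
    prs <- utils::combn(ntax, 2L)
    M_sh <- matrix(0, ncol(prs), npat)
    M_mis <- matrix(0, ncol(prs), npat)
    for (r in seq_len(ncol(prs))) {
      a <- pat[prs[1, r], ]; b <- pat[prs[2, r], ]
      sh <- !is.na(a) & !is.na(b)
      M_sh[r, ] <- as.numeric(sh)
      M_mis[r, ] <- as.numeric(sh & (a != b))
    }
    with_seed(seed, {
      W <- stats::rmultinom(n, nsites, cp$weights / sum(cp$weights))
      for (i in seq_len(n)) {
        sh <- as.vector(M_sh %*% W[, i])
        mis <- as.vector(M_mis %*% W[, i])
        p <- ifelse(sh > 0, mis / sh, NA)
        arg <- 1 - 20 * p / 19
        d <- ifelse(!is.na(arg) & arg > 0,
                    -(19 / 20) * log(pmax(arg, 1e-300)), 8)
        D <- matrix(0, ntax, ntax, dimnames = list(rownames(enc), rownames(enc)))
        D[t(prs)] <- d
        D <- D + t(D)
        trees[[i]] <- neighbor_joining(D)
      }
    })
  } else {
    with_seed(seed, {
      for (i in seq_len(n)) {
        idx <- sample.int(nsites, nsites, replace = TRUE)
        trees[[i]] <- builder(aln[, idx, drop = FALSE])
      }
    })
  }
  class(trees) <- "multiPhylo"
  counts <- ape::prop.clades(reference, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  counts[.trivial_splits(reference)] <- n
  reference$node.label <- round(100 * counts / n, 1)
  reference
}
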