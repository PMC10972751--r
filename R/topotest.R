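#' Likelihood topology tests (RELL-based KH/SH)
#'
#' Compares candidate topologies on one alignment by resampling estimated
#' log-likelihoods (RELL): per-site log-likelihoods are computed once per
#' candidate (after branch-length optimization) and bootstrap sums are drawn
#' by resampling sites, without re-optimization. Two candidates are compared
#' by the two-sided Kishino-Hasegawa test; three or more by the
#' Shimodaira-Hasegawa procedure (centered replicate sums, worst-case
#' maximum). The maximum-likelihood candidate has \eqn{\Delta = 0} and is
#' never rejected.
#'
#' @param candidates List of \code{phylo} trees over the same tip set.
#' @inheritParams log_likelihood
#' @param n_rell Number of RELL resamples (default 1000).
#' @param seed Integer seed for resampling.
#' @param alpha Rejection level (default 0.05).
#' @param optimize Re-optimize branch lengths per candidate (default TRUE).
#' @param opt_sweeps,opt_tol Branch-length optimization budget per
#'   candidate.
#' @param method \code{"auto"} (KH for two candidates, SH otherwise),
#'   \code{"SH"}, or \code{"KH"} (each candidate tested one-sided against
#'   the maximum-likelihood candidate, mirroring "rejected when
#'   significantly less likely than the ML tree"; note the usual caveat
#'   that the best tree is selected from the same data).
#' @return A data.frame of class \code{"topology_test"} with columns
#'   \code{tree}, \code{logLik}, \code{delta}, \code{p} and \code{rejected}.
#' @export
topology_test <- function(candidates, alignment, model = poisson_model(),
                          n_rell = 1000L, seed = 1L, alpha = 0.05,
                          optimize = TRUE, method = c("auto", "KH", "SH"),
                          opt_sweeps = 50L, opt_tol = 1e-6) {
  method <- match.arg(method)
  if (length(candidates) < 2L) stop("need at least 2 candidate topologies")
  tips <- lapply(candidates, function(tr) sort(tr$tip.label))
  if (!all(vapply(tips, identical, logical(1), y = tips[[1]])))
    stop("candidates must share the same tip set")
  aln <- .aln_matrix(alignment)
  nsites <- ncol(aln)
  ncand <- length(candidates)
  S <- matrix(NA_real_, nsites, ncand)
  for (i in seq_len(ncand)) {
    tr <- candidates[[i]]
    if (optimize || is.null(tr$edge.length)) {
      if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
      tr <- suppressWarnings(
        optimize_branch_lengths(tr, aln, model, max_sweeps = opt_sweeps,
                                tol = opt_tol))$tree
    }
    S[, i] <- log_likelihood(tr, aln, model, per_site = TRUE)
  }
  tot <- colSums(S)
  best <- which.max(tot)
  delta <- tot[best] - tot
  ## RELL replicate sums via resampled site weights
  R <- with_seed(seed, {
    W <- stats::rmultinom(n_rell, nsites, rep(1 / nsites, nsites))
    t(S) %*% W
  })
  Rc <- R - rowMeans(R)
  if (method == "auto") method <- if (ncand == 2L) "KH2" else "SH"
  if (method == "KH2" || (method == "KH" && ncand == 2L)) {
    ## classic two-sided KH for a pair
    dstar <- Rc[1, ] - Rc[2, ]
    dobs <- tot[1] - tot[2]
    p <- rep(mean(abs(dstar) >= abs(dobs)), 2L)
  } else if (method == "KH") {
    ## each candidate vs the ML candidate, one-sided
    p <- vapply(seq_len(ncand), function(i) {
      if (i == best) return(1)
      dstar <- Rc[best, ] - Rc[i, ]
      mean(dstar >= delta[i])
    }, numeric(1))
  } else {
    mx <- apply(Rc, 2, max)
    p <- vapply(seq_len(ncand),
                function(i) mean(mx - Rc[i, ] >= delta[i]), numeric(1))
  }
  rejected <- p < alpha & delta > 0
  nm <- names(candidates) %||% paste0("tree", seq_len(ncand))
  out <- data.frame(tree = nm, logLik = tot, delta = delta, p = p,
                    rejected = rejected, stringsAsFactors = FALSE)
  class(out) <- c("topology_test", "data.frame")
  attr(out, "alpha") <- alpha
  out
}
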