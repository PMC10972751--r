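#' Evolve ungapped protein sequences along a dated tree
#'
#' Simulates one amino-acid sequence per tip under a reversible model and a
#' strict clock: the root sequence is drawn from the stationary frequencies
#' and each branch applies the transition matrix for
#' \code{rate * branch duration}. Sequences are indel-free, so per-family
#' alignments are columnwise by construction.
#'
#' @param tree A \code{gene_tree} from \code{\link{simulate_family_tree}},
#'   or a \code{phylo} whose branch lengths are durations in Ma.
#' @param length Number of sites (>= 1).
#' @param model A \code{\link{substitution_model}}.
#' @param rate Substitutions per site per Ma (>= 0).
#' @param seed Integer seed.
#' @return Character matrix (tips x sites) with tip labels as row names.
#' @examples
#' sc <- default_scenario()
#' tr <- simulate_family_tree(sc, "CLGA", seed = 7)
#' aln <- evolve_sequences(tr, length = 50, rate = 5e-4, seed = 7)
#' @export
evolve_sequences <- function(tree, length, model = poisson_model(),
                             rate = 5e-4, seed = 1L) {
  stopifnot(length >= 1, rate >= 0)
  phy <- if (inherits(tree, "gene_tree")) tree$phy else tree
  if (!inherits(phy, "phylo")) stop("tree must be a gene_tree or phylo")
  if (is.null(phy$edge.length) || any(phy$edge.length < 0))
    stop("tree must have non-negative branch durations")
  ntip <- base::length(phy$tip.label)
  nn <- ntip + phy$Nnode
  phy_pre <- ape::reorder.phylo(phy, "cladewise")
  with_seed(seed, {
    states <- matrix(NA_integer_, nn, length)
    root <- ntip + 1L
    states[root, ] <- sample.int(20L, length, replace = TRUE,
                                 prob = model$freqs)
    ## per-site rate multipliers under discrete-gamma heterogeneity
    site_rate <- if (base::length(model$rates) > 1L)
      sample(model$rates, length, replace = TRUE, prob = model$rate_probs)
    else rep(1, length)
    for (e in seq_len(nrow(phy_pre$edge))) {
      p <- phy_pre$edge[e, 1]; ch <- phy_pre$edge[e, 2]
      t <- rate * phy_pre$edge.length[e]
      if (t == 0) {
        states[ch, ] <- states[p, ]
        next
      }
      child <- integer(length)
      ps <- states[p, ]
      for (r in unique(site_rate)) {
        P <- transition_probabilities(model, t * r)
        in_cat <- site_rate == r
        for (s in unique(ps[in_cat])) {
          idx <- which(in_cat & ps == s)
          child[idx] <- sample.int(20L, base::length(idx), replace = TRUE,
                                   prob = P[s, ])
        }
      }
      states[ch, ] <- child
    }
    aln <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]],
                  nrow = ntip)
    rownames(aln) <- phy_pre$tip.label
    aln
  })
}
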