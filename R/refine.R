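## Likelihood-guided local refinement of a distance starting tree, and
## RELL-vote bootstrap supports over a bounded candidate neighborhood.
## The deep branches that separate successive polyploidizations are a few
## Ma long; pairwise distances cannot resolve them, so the pipeline
## evaluates the NJ tree's nearest-neighbor-interchange candidates with the
## pruning likelihood (local quartet evaluation around each internal edge,
## one accepted improvement per round, bounded rounds). This is candidate
## evaluation, not an unbounded topology search.

## Transfer a partial matrix across a branch. `up = TRUE` moves a subtree
## (conditional) partial toward the root (L %*% t(P)); `up = FALSE` moves a
## root-side (outside) partial toward the tips (O %*% P). Equal for the
## symmetric Poisson model, for which a closed form avoids the 20x20
## product.
.transfer <- function(M, t, model, up = TRUE) {
  if (model$poisson) {
    e <- exp(-20 * t / 19)
    return(e * M + ((1 - e) / 20) * rowSums(M))
  }
  P <- transition_probabilities(model, t)
  if (up) M %*% t(P) else M %*% P
}

## Outside partials: out[[v]] is the partial AT parent(v) of everything
## except v's subtree, root frequencies included; single rate category.
.out_partials <- function(ws, blen, down) {
  m <- ws$model
  edge <- ws$phy$edge
  nn <- ws$ntip + ws$phy$Nnode
  edge_of <- integer(nn)
  edge_of[edge[, 2]] <- seq_len(nrow(edge))
  out <- vector("list", nn)
  outlog <- vector("list", nn)
  freqrow <- matrix(m$freqs, ws$npat, 20, byrow = TRUE)
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    p <- edge[e, 1]; v <- edge[e, 2]
    if (p == ws$root) {
      base <- freqrow
      blog <- numeric(ws$npat)
    } else {
      base <- .transfer(out[[p]], blen[edge_of[p]], m, up = FALSE)
      blog <- outlog[[p]]
    }
    for (s in ws$children[[as.character(p)]]) {
      if (s == v) next
      base <- base * .transfer(down$part[[1]][[s]], blen[edge_of[s]], m)
      blog <- blog + down$logs[[1]][[s]]
    }
    sc <- rowSums(base); sc[sc == 0] <- 1e-300
    out[[v]] <- base / sc
    outlog[[v]] <- blog + log(sc)
  }
  list(part = out, logs = outlog)
}

## Likelihood of a quartet of subtree partials joined by a central edge.
## sides = list(u = list(list(M, t, is_out)), v = ...); te central length.
## If no out-type partial is present the stationary frequencies are applied
## at the junction. Scaling logs are omitted: they are identical across
## arrangements of the same four subtrees.
.quartet_lnl <- function(u_parts, v_parts, lens, te, ws, add_freqs) {
  m <- ws$model
  Lu <- 1
  for (i in seq_along(u_parts))
    Lu <- Lu * .transfer(u_parts[[i]]$M, lens[i], m, up = !u_parts[[i]]$out)
  if (add_freqs) Lu <- Lu * matrix(m$freqs, ws$npat, 20, byrow = TRUE)
  Lv <- 1
  for (j in seq_along(v_parts))
    Lv <- Lv * .transfer(v_parts[[j]]$M, lens[2 + j], m,
                         up = !v_parts[[j]]$out)
  core <- .transfer(Lu, te, m, up = FALSE) * Lv
  v <- rowSums(core)
  v[v <= 0] <- 1e-300
  sum(log(v) * ws$w)
}

## Optimize local branch lengths of one arrangement. Fast mode optimizes
## only the central edge with the four side products precomputed (used to
## scan candidates); full mode runs coordinate passes over all five local
## lengths (used at decision time).
.optimize_quartet <- function(u_parts, v_parts, lens0, te0, ws, add_freqs,
                              full = FALSE, min_edge = 1e-8, max_edge = 5) {
  m <- ws$model
  lens <- pmax(lens0, min_edge); te <- max(te0, min_edge)
  if (full) {
    for (i in 1:4) {
      f <- function(t) {
        l <- lens; l[i] <- t
        -.quartet_lnl(u_parts, v_parts, l, te, ws, add_freqs)
      }
      lens[i] <- stats::optimize(f, c(min_edge, max_edge), tol = 1e-3)$minimum
    }
    fte <- function(t) -.quartet_lnl(u_parts, v_parts, lens, t, ws,
                                     add_freqs)
    te <- stats::optimize(fte, c(min_edge, max_edge), tol = 1e-3)$minimum
    return(list(lnl = .quartet_lnl(u_parts, v_parts, lens, te, ws, add_freqs),
                lens = lens, te = te))
  }
  Lu <- 1
  for (i in seq_along(u_parts))
    Lu <- Lu * .transfer(u_parts[[i]]$M, lens[i], m, up = !u_parts[[i]]$out)
  if (add_freqs) Lu <- Lu * matrix(m$freqs, ws$npat, 20, byrow = TRUE)
  Lv <- 1
  for (j in seq_along(v_parts))
    Lv <- Lv * .transfer(v_parts[[j]]$M, lens[2 + j], m,
                         up = !v_parts[[j]]$out)
  fte <- function(t) {
    v <- rowSums(.transfer(Lu, t, m, up = FALSE) * Lv)
    v[v <= 0] <- 1e-300
    -sum(log(v) * ws$w)
  }
  opt <- stats::optimize(fte, c(min_edge, max_edge), tol = 1e-3)
  list(lnl = -opt$objective, lens = lens, te = opt$minimum)
}

## Apply an NNI: move subtree x (child of u) below v, and subtree c (child
## of v) below u, across internal edge (u, v).
.apply_nni <- function(phy, x, c_node) {
  ex <- which(phy$edge[, 2] == x)
  ec <- which(phy$edge[, 2] == c_node)
  u <- phy$edge[ex, 1]; v <- phy$edge[ec, 1]
  phy$edge[ex, 1] <- v
  phy$edge[ec, 1] <- u
  attr(phy, "order") <- NULL  # edges changed; force a true reorder
  ape::reorder.phylo(phy, "postorder")
}

#' Refine a starting topology by likelihood-evaluated NNI candidates
#'
#' Evaluates, for every internal edge, the two nearest-neighbor-interchange
#' arrangements against the current one using the exact local quartet
#' likelihood (five local branch lengths re-optimized per arrangement, all
#' other branch lengths held fixed), applies the single best improvement,
#' and repeats for at most \code{max_rounds} rounds. Intended to polish a
#' neighbor-joining starting tree whose short deep branches are below the
#' resolution of pairwise distances; it is a bounded candidate evaluation,
#' not a full topology search.
#'
#' @inheritParams log_likelihood
#' @param max_rounds Maximum accepted rearrangements (default 10).
#' @param eps Minimum local log-likelihood gain to accept (default 0.1).
#' @return List: \code{tree} (refined, same tips), \code{n_moves},
#'   \code{moves} (data.frame of accepted swaps with gains).
#' @export
refine_topology <- function(tree, alignment, model = poisson_model(),
                            max_rounds = 10L, eps = 0.1) {
  if (length(model$rates) > 1L)
    stop("topology refinement supports single-rate models")
  phy <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  moves <- list()
  cache <- .aln_cache(alignment)
  for (round in seq_len(max_rounds)) {
    ws <- .lik_workspace(phy, alignment, model, cache = cache)
    phy <- ws$phy
    blen <- phy$edge.length
    edge <- phy$edge
    nn <- ws$ntip + phy$Nnode
    edge_of <- integer(nn)
    edge_of[edge[, 2]] <- seq_len(nrow(edge))
    down <- .down_partials(ws, blen)
    out <- .out_partials(ws, blen, down)
    internal_edges <- which(edge[, 2] > ws$ntip)
    cand_moves <- list()
    for (e in internal_edges) {
      u <- edge[e, 1]; v <- edge[e, 2]
      v_kids <- ws$children[[as.character(v)]]
      u_kids <- setdiff(ws$children[[as.character(u)]], v)
      u_parts <- list()
      u_nodes <- c()
      for (s in u_kids) {
        u_parts[[length(u_parts) + 1L]] <-
          list(M = down$part[[1]][[s]], out = FALSE)
        u_nodes <- c(u_nodes, s)
      }
      add_freqs <- TRUE
      if (u != ws$root) {
        u_parts[[length(u_parts) + 1L]] <- list(M = out$part[[u]], out = TRUE)
        u_nodes <- c(u_nodes, NA)  # parent side, not swappable here
        add_freqs <- FALSE
      }
      if (length(u_parts) != 2L || length(v_kids) != 2L) next
      v_parts <- lapply(v_kids, function(s)
        list(M = down$part[[1]][[s]], out = FALSE))
      lens0 <- c(
        vapply(seq_along(u_parts), function(i) {
          if (is.na(u_nodes[i])) blen[edge_of[u]] else blen[edge_of[u_nodes[i]]]
        }, numeric(1)),
        blen[edge_of[v_kids]])
      te0 <- blen[e]
      cur <- .optimize_quartet(u_parts, v_parts, lens0, te0, ws, add_freqs)
      ## swap the first real child of u against each v child: these two
      ## arrangements are exactly the edge's distinct NNI alternatives
      i <- which(!is.na(u_nodes))[1]
      if (!is.na(i)) {
        for (j in 1:2) {
          up2 <- u_parts; vp2 <- v_parts
          tmp <- up2[[i]]; up2[[i]] <- vp2[[j]]; vp2[[j]] <- tmp
          l2 <- lens0
          tmp <- l2[i]; l2[i] <- l2[2 + j]; l2[2 + j] <- tmp
          alt <- .optimize_quartet(up2, vp2, l2, te0, ws, add_freqs)
          gain <- alt$lnl - cur$lnl
          if (gain > eps)
            cand_moves[[length(cand_moves) + 1L]] <-
              list(gain = gain, x = u_nodes[i], c_node = v_kids[j],
                   e = e, te = alt$te, u = u, v = v)
        }
      }
    }
    if (!length(cand_moves)) break
    ## apply all non-conflicting improvements, best first; conflicts are
    ## moves touching any node of an already-applied quartet
    ord <- order(-vapply(cand_moves, `[[`, numeric(1), "gain"))
    used <- integer(0)
    for (mv in cand_moves[ord]) {
      nodes <- c(mv$u, mv$v, mv$x, mv$c_node)
      if (any(nodes %in% used)) next
      phy$edge.length[mv$e] <- mv$te
      ex <- which(phy$edge[, 2] == mv$x)
      ec <- which(phy$edge[, 2] == mv$c_node)
      phy$edge[ex, 1] <- mv$v
      phy$edge[ec, 1] <- mv$u
      used <- c(used, nodes)
      moves[[length(moves) + 1L]] <- data.frame(round = round, gain = mv$gain)
    }
    attr(phy, "order") <- NULL
    phy <- ape::reorder.phylo(phy, "postorder")
  }
  list(tree = phy, n_moves = length(moves),
       moves = if (length(moves)) do.call(rbind, moves) else NULL)
}

#' All nearest-neighbor-interchange candidates of a tree
#'
#' @param tree Unrooted binary \code{phylo}.
#' @return List of \code{phylo} trees (two per internal edge).
#' @export
nni_neighbors <- function(tree) {
  phy <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(phy$tip.label)
  children <- split(phy$edge[, 2], phy$edge[, 1])
  out <- list()
  for (e in which(phy$edge[, 2] > ntip)) {
    u <- phy$edge[e, 1]; v <- phy$edge[e, 2]
    v_kids <- children[[as.character(v)]]
    u_kids <- setdiff(children[[as.character(u)]], v)
    if (length(v_kids) != 2L || !length(u_kids)) next
    x <- u_kids[1]
    for (j in 1:2)
      out[[length(out) + 1L]] <- .apply_nni(phy, x, v_kids[j])
  }
  out
}

#' RELL-vote bootstrap supports over a candidate set
#'
#' Per-site log-likelihoods are computed once per candidate topology (with
#' the branch lengths they carry); site-resampled replicate sums (RELL)
#' each vote for their best candidate, and the support of a bipartition of
#' the reference tree is the percentage of votes for candidates containing
#' it. A fast approximation to the rebuild-per-replicate bootstrap when a
#' sensible candidate neighborhood (e.g. the reference tree plus its NNI
#' rearrangements) is available.
#'
#' @param reference Reference tree (rooted or unrooted); receives supports
#'   in \code{node.label}.
#' @param candidates List of candidate trees with branch lengths, normally
#'   including the reference topology.
#' @inheritParams log_likelihood
#' @param n Number of RELL replicates.
#' @param seed Integer seed.
#' @return The reference tree with supports (0-100) in \code{node.label}.
#' @export
rell_bootstrap_support <- function(reference, candidates, alignment,
                                   model = poisson_model(), n = 1000L,
                                   seed = 1L) {
  aln <- .aln_matrix(alignment)
  nsites <- ncol(aln)
  cache <- .aln_cache(aln)
  S <- vapply(candidates, function(tr) {
    ws <- .lik_workspace(tr, aln, model, cache = cache)
    down <- .down_partials(ws, ws$phy$edge.length)
    .pattern_loglik(ws, down)[ws$index]
  }, numeric(nsites))
  votes <- with_seed(seed, {
    W <- stats::rmultinom(n, nsites, rep(1 / nsites, nsites))
    R <- t(S) %*% W
    apply(R, 2, which.max)
  })
  share <- tabulate(votes, nbins = length(candidates)) / n
  ntip <- length(reference$tip.label)
  support <- numeric(reference$Nnode)
  for (ci in seq_along(candidates)) {
    if (share[ci] == 0) next
    trees <- list(candidates[[ci]])
    class(trees) <- "multiPhylo"
    inref <- ape::prop.clades(reference, trees, rooted = FALSE)
    inref[is.na(inref)] <- 0
    support <- support + share[ci] * inref
  }
  ## splits that are trivial in the unrooted sense (the root split and
  ## complements of single tips) are present in every tree by construction
  support[.trivial_splits(reference)] <- 1
  reference$node.label <- round(100 * support, 1)
  reference
}

## Internal nodes of `phy` whose bipartition is trivial when unrooted:
## the root and any node subtending all tips but one (or all tips).
.trivial_splits <- function(phy) {
  ntip <- length(phy$tip.label)
  ndesc <- integer(ntip + phy$Nnode)
  ndesc[seq_len(ntip)] <- 1L
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge)))
    ndesc[po$edge[e, 1]] <- ndesc[po$edge[e, 1]] + ndesc[po$edge[e, 2]]
  which(ndesc[(ntip + 1L):(ntip + phy$Nnode)] >= ntip - 1L)
}
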