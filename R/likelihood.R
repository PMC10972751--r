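## Felsenstein pruning likelihood with site-pattern compression, per-site
## log-likelihoods (for RELL resampling) and per-branch coordinate-ascent
## branch-length optimization. Partial likelihoods are rescaled per node
## (rowSums scaling) so deep trees do not underflow.

## Coerce the supported alignment representations to a character matrix with
## one row per sequence.
.aln_matrix <- function(alignment) {
  if (inherits(alignment, "AAStringSet"))
    alignment <- as.character(alignment)
  if (is.character(alignment) && !is.matrix(alignment)) {
    if (is.null(names(alignment)))
      stop("sequence vector must be named")
    alignment <- do.call(rbind, lapply(alignment, function(s) strsplit(s, "")[[1]]))
  }
  if (!is.matrix(alignment)) stop("unsupported alignment representation")
  if (is.null(rownames(alignment))) stop("alignment rows must be named")
  alignment
}

## Precomputed per-alignment data reusable across trees on the same
## alignment: compressed site patterns and per-sequence partial matrices.
.aln_cache <- function(alignment) {
  aln <- .aln_matrix(alignment)
  enc <- encode_alignment(aln)
  cp <- compress_patterns(enc)
  npat <- length(cp$weights)
  tip_part <- vector("list", nrow(aln))
  names(tip_part) <- rownames(aln)
  for (i in seq_len(nrow(aln))) {
    M <- matrix(0, npat, 20)
    st <- cp$patterns[i, ]
    known <- which(!is.na(st))
    M[cbind(known, st[known])] <- 1
    M[setdiff(seq_len(npat), known), ] <- 1
    tip_part[[i]] <- M
  }
  list(labels = rownames(aln), npat = npat, w = cp$weights,
       index = cp$index, tip_part = tip_part)
}

## Workspace shared by the likelihood functions: postorder tree, compressed
## site patterns and per-tip partial matrices. Pass a precomputed `cache`
## (from .aln_cache) to avoid recompressing when many trees are evaluated
## on one alignment.
.lik_workspace <- function(tree, alignment, model, cache = NULL) {
  stopifnot(inherits(model, "subst_model"))
  if (is.null(cache)) cache <- .aln_cache(alignment)
  missing_tips <- setdiff(tree$tip.label, cache$labels)
  if (length(missing_tips))
    stop("alignment lacks rows for tips: ", paste(missing_tips, collapse = ", "))
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  phy <- ape::reorder.phylo(tree, "postorder")
  npat <- cache$npat
  ntip <- length(phy$tip.label)
  tip_part <- cache$tip_part[phy$tip.label]
  children <- split(phy$edge[, 2], phy$edge[, 1])
  parent <- integer(ntip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  list(phy = phy, npat = npat, w = cache$w, index = cache$index,
       tip_part = tip_part, children = children, parent = parent,
       root = root, ntip = ntip, model = model)
}

## Conditional (down) partials for every node, one set per rate category.
## Returns part[[cat]][[node]] (npat x 20) and logs[[cat]][[node]] (npat).
.down_partials <- function(ws, blen) {
  m <- ws$model
  ncat <- length(m$rates)
  nn <- ws$ntip + ws$phy$Nnode
  part <- lapply(seq_len(ncat), function(k) vector("list", nn))
  logs <- lapply(seq_len(ncat), function(k) vector("list", nn))
  zero <- numeric(ws$npat)
  edge <- ws$phy$edge
  for (k in seq_len(ncat)) {
    for (i in seq_len(ws$ntip)) {
      part[[k]][[i]] <- ws$tip_part[[i]]
      logs[[k]][[i]] <- zero
    }
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1]; ch <- edge[e, 2]
      contrib <- .transfer(part[[k]][[ch]], blen[e] * m$rates[k], m)
      lg <- logs[[k]][[ch]]
      if (is.null(part[[k]][[p]])) {
        part[[k]][[p]] <- contrib
        logs[[k]][[p]] <- lg
      } else {
        part[[k]][[p]] <- part[[k]][[p]] * contrib
        logs[[k]][[p]] <- logs[[k]][[p]] + lg
      }
      ## rescale the accumulating parent partial to keep magnitudes bounded
      s <- rowSums(part[[k]][[p]])
      s[s == 0] <- 1e-300
      part[[k]][[p]] <- part[[k]][[p]] / s
      logs[[k]][[p]] <- logs[[k]][[p]] + log(s)
    }
  }
  list(part = part, logs = logs)
}

## Pattern log-likelihoods from completed down partials.
.pattern_loglik <- function(ws, down) {
  m <- ws$model
  ncat <- length(m$rates)
  lls <- matrix(NA_real_, ws$npat, ncat)
  for (k in seq_len(ncat)) {
    lik <- as.vector(down$part[[k]][[ws$root]] %*% m$freqs)
    lik[lik <= 0] <- 1e-300
    lls[, k] <- log(lik) + down$logs[[k]][[ws$root]]
  }
  if (ncat == 1L) return(lls[, 1])
  mx <- apply(lls, 1, max)
  mx + log(rowSums(exp(lls - mx) *
                     matrix(m$rate_probs, ws$npat, ncat, byrow = TRUE)))
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Computes the exact log-likelihood of an alignment on a tree under a
#' reversible amino-acid model, with site-pattern compression and per-node
#' rescaling. Gap and ambiguous states are treated as missing data. The value
#' is independent of the traversal order and, for unrooted trees, of the root
#' placement (pulley principle).
#'
#' @param tree A \code{phylo} tree with branch lengths in expected
#'   substitutions per site. Rooted or unrooted.
#' @param alignment Character matrix (rows named by tip), named character
#'   vector of sequences, or \code{AAStringSet}.
#' @param model A \code{\link{substitution_model}}.
#' @param per_site If \code{TRUE}, return the vector of per-site
#'   log-likelihoods (uncompressed) instead of their sum.
#' @return Total log-likelihood, or a numeric vector if \code{per_site}.
#' @export
log_likelihood <- function(tree, alignment, model = poisson_model(),
                           per_site = FALSE) {
  ws <- .lik_workspace(tree, alignment, model)
  blen <- ws$phy$edge.length
  down <- .down_partials(ws, blen)
  pat_ll <- .pattern_loglik(ws, down)
  if (per_site) pat_ll[ws$index] else sum(pat_ll * ws$w)
}

#' Optimize branch lengths by per-branch coordinate ascent
#'
#' Each sweep performs one postorder pass to collect inside (down) partials
#' and one preorder walk that maintains outside partials incrementally,
#' optimizing every branch in turn by Brent search; each Brent evaluation
#' is a cheap spectral product. The total log-likelihood is checked after
#' every sweep: a sweep that fails to improve it is rolled back, so the
#' reported per-sweep log-likelihoods are non-decreasing. Iteration stops
#' when a sweep improves the log-likelihood by less than \code{tol} or
#' after \code{max_sweeps} sweeps (then a warning is issued and
#' \code{converged = FALSE}).
#'
#' @inheritParams log_likelihood
#' @param max_sweeps Maximum number of full sweeps (default 50).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param min_edge Lower bound for branch lengths (default 1e-8).
#' @param max_edge Upper bound for branch lengths (default 10).
#' @return A list with \code{tree} (optimized branch lengths),
#'   \code{logLik}, \code{converged} and \code{sweep_logLik} (the
#'   non-decreasing per-sweep trace).
#' @export
optimize_branch_lengths <- function(tree, alignment, model = poisson_model(),
                                    max_sweeps = 50L, tol = 1e-6,
                                    min_edge = 1e-8, max_edge = 10) {
  ws <- .lik_workspace(tree, alignment, model)
  m <- model
  ncat <- length(m$rates)
  blen <- pmax(ws$phy$edge.length, min_edge)
  edge <- ws$phy$edge
  nn <- ws$ntip + ws$phy$Nnode
  edge_of <- integer(nn)
  edge_of[edge[, 2]] <- seq_len(nrow(edge))
  freqrow <- matrix(m$freqs, ws$npat, 20, byrow = TRUE)
  total_ll <- function(bl) {
    down <- .down_partials(ws, bl)
    sum(.pattern_loglik(ws, down) * ws$w)
  }
  last_ll <- total_ll(blen)
  trace <- last_ll
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    prev_blen <- blen
    down <- .down_partials(ws, blen)
    out <- vector("list", nn)      # per node: list over categories
    outlog <- vector("list", nn)
    for (e in rev(seq_len(nrow(edge)))) {   # preorder walk
      p <- edge[e, 1]; v <- edge[e, 2]
      O <- vector("list", ncat); Olog <- vector("list", ncat)
      for (k in seq_len(ncat)) {
        if (p == ws$root) {
          base <- freqrow
          blog <- numeric(ws$npat)
        } else {
          base <- .transfer(out[[p]][[k]], blen[edge_of[p]] * m$rates[k],
                            m, up = FALSE)
          blog <- outlog[[p]][[k]]
        }
        for (s in ws$children[[as.character(p)]]) {
          if (s == v) next
          base <- base * .transfer(down$part[[k]][[s]],
                                   blen[edge_of[s]] * m$rates[k], m)
          blog <- blog + down$logs[[k]][[s]]
        }
        sc <- rowSums(base); sc[sc == 0] <- 1e-300
        O[[k]] <- base / sc
        Olog[[k]] <- blog + log(sc)
      }
      out[[v]] <- O
      outlog[[v]] <- Olog
      ## Brent on this branch with spectral precompute
      ab <- vector("list", ncat); base_log <- vector("list", ncat)
      for (k in seq_len(ncat)) {
        a <- O[[k]] %*% m$evec
        b <- down$part[[k]][[v]] %*% t(m$ivec)
        ab[[k]] <- a * b
        base_log[[k]] <- Olog[[k]] + down$logs[[k]][[v]]
      }
      obj <- function(t) {
        lls <- matrix(NA_real_, ws$npat, ncat)
        for (k in seq_len(ncat)) {
          val <- as.vector(ab[[k]] %*% exp(m$evals * (t * m$rates[k])))
          val[val <= 0] <- 1e-300
          lls[, k] <- log(val) + base_log[[k]]
        }
        pat <- if (ncat == 1L) lls[, 1] else {
          mx <- apply(lls, 1, max)
          mx + log(rowSums(exp(lls - mx) *
                             matrix(m$rate_probs, ws$npat, ncat, byrow = TRUE)))
        }
        -sum(pat * ws$w)
      }
      opt <- stats::optimize(obj, interval = c(min_edge, max_edge), tol = 1e-7)
      if (opt$objective < obj(blen[e])) blen[e] <- opt$minimum
    }
    ll <- total_ll(blen)
    if (ll < last_ll) {
      ## outside partials were stale enough to hurt: roll back and stop
      blen <- prev_blen
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    if (ll - last_ll < tol) {
      last_ll <- ll
      converged <- TRUE
      break
    }
    last_ll <- ll
  }
  if (!converged)
    warning("branch-length optimization did not converge in ",
            max_sweeps, " sweeps")
  out_tree <- ws$phy
  out_tree$edge.length <- blen
  list(tree = out_tree, logLik = last_ll, converged = converged,
       sweep_logLik = trace)
}
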