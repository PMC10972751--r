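#' Strict-clock least-squares dating
#'
#' Estimates node ages on a rooted tree by minimizing
#' \eqn{\sum_e (b_e - r\,\Delta t_e)^2} over node ages and a single global
#' rate, subject to parent-older-than-child ordering and user calibration
#' bounds. Tips are fixed at age 0. The solver alternates a closed-form rate
#' update with a sparse linear solve for the free ages, then projects onto
#' the constraints; it is deterministic and recovers clock-like trees
#' exactly given one exact calibration. Ages are scale-invariant in the
#' branch lengths (the rate absorbs any global rescaling).
#'
#' @param tree Rooted \code{phylo} with branch lengths.
#' @param calibrations data.frame with columns \code{node} (internal node id,
#'   see \code{\link[ape]{getMRCA}}), \code{age_min}, \code{age_max} (equal
#'   values pin the age exactly). At least one calibration is required.
#' @param tol Convergence tolerance on ages (relative).
#' @param max_iter Maximum alternation iterations.
#' @return A list of class \code{"dated_tree"}: \code{tree}, \code{ages}
#'   (length Ntip + Nnode, tips 0) and \code{rate}.
#' @export
date_nodes <- function(tree, calibrations, tol = 1e-10, max_iter = 200L) {
  phy <- check_rooted(tree)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  if (missing(calibrations) || is.null(calibrations) || !nrow(calibrations))
    stop("at least one calibration is required")
  stopifnot(all(c("node", "age_min", "age_max") %in% names(calibrations)))
  if (any(calibrations$age_min > calibrations$age_max))
    stop("calibration with age_min > age_max")
  cal_min <- rep(0, nn)
  cal_max <- rep(Inf, nn)
  cal_min[calibrations$node] <- calibrations$age_min
  cal_max[calibrations$node] <- calibrations$age_max
  ## feasibility: a descendant's lower bound may not exceed an ancestor's
  ## upper bound
  anc <- function(v) {
    out <- integer(0)
    repeat {
      e <- which(phy$edge[, 2] == v)
      if (!length(e)) break
      v <- phy$edge[e, 1]
      out <- c(out, v)
    }
    out
  }
  for (v in calibrations$node) {
    bad <- cal_max[anc(v)] < cal_min[v]
    if (any(bad)) stop("infeasible calibrations: descendant bound older than ancestor bound")
  }
  edge <- phy$edge
  bl <- phy$edge.length
  ## Residuals of the clock fit: one per edge (bl - r (t_p - t_c)), except
  ## that a binary root's two edges are merged into a single residual
  ## (bl1 + bl2 - r (2 t_root - t_c1 - t_c2)): the root's position along
  ## that path is unidentifiable from the data (pulley principle) and a
  ## zero-length rooting artifact would otherwise bias its neighbors.
  root_node <- ntip + 1L
  root_edges <- which(edge[, 1] == root_node)
  resid_nodes <- list(); resid_coefs <- list(); resid_bl <- numeric(0)
  if (length(root_edges) == 2L) {
    ordinary <- setdiff(seq_len(nrow(edge)), root_edges)
    resid_nodes <- c(lapply(ordinary, function(e) edge[e, ]),
                     list(c(root_node, edge[root_edges, 2])))
    resid_coefs <- c(rep(list(c(1, -1)), length(ordinary)),
                     list(c(2, -1, -1)))
    resid_bl <- c(bl[ordinary], sum(bl[root_edges]))
  } else {
    resid_nodes <- lapply(seq_len(nrow(edge)), function(e) edge[e, ])
    resid_coefs <- rep(list(c(1, -1)), nrow(edge))
    resid_bl <- bl
  }
  ## initial ages: mean subtree path length, scaled through a pinned-ish node
  mean_depth <- numeric(nn)
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    contrib <- mean_depth[ch] + po$edge.length[e]
    mean_depth[p] <- if (mean_depth[p] == 0) contrib else (mean_depth[p] + contrib) / 2
  }
  cal_mid <- (calibrations$age_min +
                pmin(calibrations$age_max, calibrations$age_min * 2 + 1)) / 2
  ref <- which.max(cal_mid)
  rate <- mean_depth[calibrations$node[ref]] / max(cal_mid[ref], 1e-12)
  if (!is.finite(rate) || rate <= 0) rate <- 1
  ages <- mean_depth / rate
  ages[seq_len(ntip)] <- 0
  pinned <- cal_min == cal_max & is.finite(cal_max)
  ages[pinned] <- cal_min[pinned]
  free <- setdiff((ntip + 1L):nn, which(pinned))
  project <- function(a) {
    a <- pmin(pmax(a, cal_min), ifelse(is.finite(cal_max), cal_max, a))
    a[seq_len(ntip)] <- 0
    ## parent at least as old as children (preorder from tips up)
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      if (!pinned[p] && a[p] < a[ch]) a[p] <- a[ch]
    }
    a
  }
  ages <- project(ages)
  for (iter in seq_len(max_iter)) {
    d <- vapply(seq_along(resid_bl), function(e)
      sum(resid_coefs[[e]] * ages[resid_nodes[[e]]]), numeric(1))
    denom <- sum(d^2)
    rate <- if (denom > 0) sum(resid_bl * d) / denom else rate
    if (!is.finite(rate) || rate <= 0) rate <- 1e-12
    if (length(free)) {
      idx <- match(seq_len(nn), free)
      A <- matrix(0, length(free), length(free))
      b <- numeric(length(free))
      for (e in seq_along(resid_bl)) {
        nodes <- resid_nodes[[e]]
        cf <- resid_coefs[[e]]
        fi <- idx[nodes]
        for (i in seq_along(nodes)) {
          if (is.na(fi[i])) next
          b[fi[i]] <- b[fi[i]] + cf[i] * resid_bl[e] / rate
          for (j in seq_along(nodes)) {
            if (is.na(fi[j])) {
              b[fi[i]] <- b[fi[i]] - cf[i] * cf[j] * ages[nodes[j]]
            } else {
              A[fi[i], fi[j]] <- A[fi[i], fi[j]] + cf[i] * cf[j]
            }
          }
        }
      }
      sol <- try(solve(A, b), silent = TRUE)
      if (!inherits(sol, "try-error")) {
        new_ages <- ages
        new_ages[free] <- sol
        new_ages <- project(new_ages)
        if (max(abs(new_ages - ages)) < tol * max(1, max(ages))) {
          ages <- new_ages
          break
        }
        ages <- new_ages
      } else break
    } else break
  }
  structure(list(tree = phy, ages = ages, rate = rate), class = "dated_tree")
}

#' MRCA node helper for calibrations
#'
#' @param tree Rooted \code{phylo}.
#' @param tips Character vector of tip labels.
#' @return Internal node id of the most recent common ancestor.
#' @export
mrca_node <- function(tree, tips) {
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}
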