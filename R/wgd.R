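## Reading duplication vs speciation nodes off paralogon trees, the
## ancestral-vs-lineage-specific rediploidization tests with
## constrained-topology enumeration, per-CLG tallies, and the bimodality
## summary of cyclostome paralogon divergence times.

#' Classify internal nodes as duplication or speciation
#'
#' Applies the species-overlap rule: a node is a duplication iff its child
#' clades share at least one species. Duplication nodes are assigned to
#' events by lineage composition: both cyclostome and gnathostome
#' descendants on both sides = \code{"1R"} (pre-split duplication);
#' gnathostome-only descendants = \code{"2R_JV"}; cyclostome-only =
#' \code{"2R_CY"}; anything else = \code{"none"}.
#'
#' @param tree Rooted \code{phylo} whose tips are \code{"species|segment"}
#'   keys (or supply \code{tip_species}), or a \code{dated_tree}.
#' @param lineages Named character vector species -> lineage
#'   (\code{"outgroup"}, \code{"cyclostome"}, \code{"gnathostome"}).
#' @param tip_species Optional named vector tip label -> species.
#' @param ages Optional node-age vector (taken from a \code{dated_tree}
#'   automatically).
#' @param support Optional numeric node supports (defaults to
#'   \code{tree$node.label}).
#' @return data.frame of class \code{"node_reading"}: node, type, event,
#'   support, age.
#' @export
classify_nodes <- function(tree, lineages, tip_species = NULL, ages = NULL,
                           support = NULL) {
  if (inherits(tree, "dated_tree")) {
    if (is.null(ages)) ages <- tree$ages
    tree <- tree$tree
  }
  phy <- check_rooted(tree)
  ntip <- length(phy$tip.label)
  if (is.null(tip_species))
    tip_species <- setNames(sub("\\|.*", "", phy$tip.label), phy$tip.label)
  if (is.null(support) && !is.null(phy$node.label))
    support <- suppressWarnings(as.numeric(phy$node.label))
  spp <- unname(tip_species[phy$tip.label])
  if (any(is.na(lineages[spp])))
    stop("species without lineage assignment: ",
         paste(unique(spp[is.na(lineages[spp])]), collapse = ", "))
  po <- ape::reorder.phylo(phy, "postorder")
  nn <- ntip + phy$Nnode
  spset <- vector("list", nn)
  for (i in seq_len(ntip)) spset[[i]] <- spp[i]
  kids <- vector("list", nn)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    kids[[p]] <- c(kids[[p]], ch)
    spset[[p]] <- union(spset[[p]], spset[[ch]])
  }
  rows <- lapply((ntip + 1L):nn, function(v) {
    chs <- kids[[v]]
    sets <- lapply(chs, function(ch) spset[[ch]])
    dup <- FALSE
    for (i in seq_along(sets)) for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]]))) dup <- TRUE
    }
    lin_sets <- lapply(sets, function(s)
      unique(lineages[setdiff(s, names(lineages)[lineages == "outgroup"])]))
    all_lin <- unique(unlist(lin_sets))
    event <- "none"
    if (dup) {
      both_sides <- all(vapply(lin_sets, function(l)
        all(c("cyclostome", "gnathostome") %in% l), logical(1)))
      if (both_sides) event <- "1R"
      else if (identical(all_lin, "gnathostome")) event <- "2R_JV"
      else if (identical(all_lin, "cyclostome")) event <- "2R_CY"
    }
    data.frame(node = v, type = if (dup) "duplication" else "speciation",
               event = if (dup) event else "none",
               support = if (!is.null(support)) support[v - ntip] else NA_real_,
               age = if (!is.null(ages)) ages[v] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("node_reading", "data.frame")
  out
}

#' Does a shared pre-split 1R duplication node have support above a BP
#' threshold?
#'
#' @param readings A \code{node_reading} table.
#' @param bp Bootstrap-percentage threshold (default 60).
#' @return Logical.
#' @export
has_presplit_1r <- function(readings, bp = 60) {
  any(readings$event == "1R" &
        (is.na(readings$support) | readings$support > bp) &
        !is.na(readings$event))
}

## Cyclostome segment-orthology groups for one family: genes grouped by
## (species, segment), then merged across species through the constraint
## list (each constraint a character vector of "species|segment" keys).
.cyclostome_groups <- function(genes, lineages, constraints = NULL) {
  cy <- genes[lineages[genes$species] == "cyclostome", , drop = FALSE]
  if (!nrow(cy)) return(list())
  segkey <- paste(cy$species, cy$paralogon, sep = "|")
  us <- unique(segkey)
  grp <- setNames(us, us)  # each segment its own group at first
  if (!is.null(constraints)) {
    for (cons in constraints) {
      present <- intersect(cons, unique(segkey))
      if (length(present) > 1L) {
        tgt <- sort(present)[1]
        for (s in present) grp[grp %in% grp[s]] <- grp[tgt]
      }
    }
  }
  out <- split(cy$gene_id, grp[segkey])
  attr(out, "group_of") <- grp
  out
}

## Newick ladder over a character vector of labels.
.ladder <- function(labels) {
  if (!length(labels)) return(NULL)
  Reduce(function(a, b) paste0("(", a, ",", b, ")"), labels)
}

.join2 <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  paste0("(", a, ",", b, ")")
}

#' Enumerate constrained rediploidization topologies
#'
#' Ancestral mode: gnathostome 1R_1 and 1R_2 gene copies seed two clades;
#' every assignment of the cyclostome segment-orthology groups to the two
#' clades (groups of orthologous hagfish/lamprey segments placed jointly)
#' yields one constrained topology, so \eqn{2^g} topologies for \eqn{g}
#' groups. With \code{balanced = TRUE} the two clades are unlabeled and
#' each must receive exactly one segment per species (the paired test used
#' for duplications inside one 1R copy), and mirror-image assignments are
#' deduplicated. Lineage-specific mode: the single topology grouping
#' cyclostome genes as a clade structured by lineage.
#'
#' @param family Family object with \code{genes} (gene_id, species,
#'   paralogon).
#' @param mode \code{"ancestral"} or \code{"lineage_specific"}.
#' @param lineages Named vector species -> lineage.
#' @param constraints Optional list of character vectors of
#'   \code{"species|segment"} keys constrained to the same clade
#'   (well-supported cross-species chromosomal orthologies), or a list
#'   with elements \code{orthologs} (that list) and \code{exclusions}.
#' @param exclusions Optional list of character pairs of segment keys that
#'   may not share a clade: chromosomal paralogons known (from the prior
#'   classification or the chromosome-scale tree) to descend from
#'   different duplication copies must be split across the duplicate
#'   clades under the ancestral model.
#' @param balanced Unlabeled-clade balanced mode (see above).
#' @return Named list of Newick strings (with trailing semicolon).
#' @export
enumerate_constrained_topologies <- function(family,
                                             mode = c("ancestral", "lineage_specific"),
                                             lineages, constraints = NULL,
                                             exclusions = NULL,
                                             balanced = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(constraints) && !is.null(names(constraints)) &&
      any(c("orthologs", "exclusions") %in% names(constraints))) {
    exclusions <- exclusions %||% constraints$exclusions
    constraints <- constraints$orthologs
  }
  g <- family$genes
  if (any(g$paralogon == "unplaced"))
    stop("family has unplaced genes; classify or drop them first")
  out_genes <- g$gene_id[lineages[g$species] == "outgroup"]
  gn <- g[lineages[g$species] == "gnathostome", , drop = FALSE]
  copy_of <- paralogon_1r_copy(gn$paralogon)
  gn_clade <- function(copy) {
    sub <- gn[copy_of == copy, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    parts <- lapply(split(sub$gene_id, sub$paralogon), .ladder)
    Reduce(.join2, parts)
  }
  groups <- .cyclostome_groups(g, lineages, constraints)
  grp_clade <- function(ids) {
    sub <- g[g$gene_id %in% ids, , drop = FALSE]
    parts <- lapply(split(sub$gene_id, sub$species), .ladder)
    Reduce(.join2, parts)
  }
  finish <- function(core) paste0(.join2(.ladder(out_genes), core), ";")
  if (mode == "lineage_specific") {
    if (!length(groups)) stop("no cyclostome genes; family is uninformative")
    cy <- g[lineages[g$species] == "cyclostome", , drop = FALSE]
    by_sp <- lapply(split(cy, cy$species), function(s) {
      segs <- lapply(split(s$gene_id, s$paralogon), .ladder)
      Reduce(.join2, segs)
    })
    cy_clade <- Reduce(.join2, by_sp)
    gn_part <- .join2(gn_clade("1R_1"), gn_clade("1R_2"))
    return(setNames(list(finish(.join2(gn_part, cy_clade))),
                    "lineage_specific"))
  }
  if (!length(groups)) return(list())
  gnames <- names(groups)
  ng <- length(gnames)
  assignments <- as.matrix(expand.grid(rep(list(1:2), ng)))
  colnames(assignments) <- gnames
  if (!is.null(exclusions) && ng > 1L) {
    group_of <- attr(groups, "group_of")
    for (ex in exclusions) {
      ga <- group_of[ex[1]]; gb <- group_of[ex[2]]
      if (is.na(ga) || is.na(gb)) next
      if (ga == gb)
        stop("contradictory constraints: ", ex[1], " and ", ex[2],
             " are constrained both together and apart")
      keep <- assignments[, ga] != assignments[, gb]
      assignments <- assignments[keep, , drop = FALSE]
    }
  }
  if (balanced) {
    species_of_group <- lapply(groups, function(ids)
      unique(g$species[g$gene_id %in% ids]))
    ok <- apply(assignments, 1, function(a) {
      for (cl in 1:2) {
        sp <- unlist(species_of_group[a == cl])
        if (any(duplicated(sp))) return(FALSE)
        if (!setequal(sp, unique(unlist(species_of_group)))) return(FALSE)
      }
      TRUE
    })
    assignments <- assignments[ok, , drop = FALSE]
    ## deduplicate mirror images (clades unlabeled): fix group 1 in clade 1
    if (nrow(assignments))
      assignments <- assignments[assignments[, 1] == 1, , drop = FALSE]
  }
  topos <- list()
  for (r in seq_len(nrow(assignments))) {
    a <- assignments[r, ]
    clade <- function(cl, copy) {
      cy_parts <- lapply(gnames[a == cl], function(nm) grp_clade(groups[[nm]]))
      cy_core <- Reduce(.join2, cy_parts)
      .join2(gn_clade(copy), cy_core)
    }
    c1 <- clade(1, "1R_1"); c2 <- clade(2, "1R_2")
    if (is.null(c1) || is.null(c2)) next  # a clade with no leaves at all
    topos[[paste0("ancestral_", r)]] <- finish(.join2(c1, c2))
  }
  topos
}

#' Select families informative for the rediploidization test
#'
#' Keeps families satisfying: (i) at least one gnathostome species retains
#' both 1R_1 (alpha1/beta1) and 1R_2 (alpha2/beta2) copies; (ii) at least
#' one gene from each cyclostome species; (iii) at least one outgroup gene;
#' (iv) at most \code{max_topologies} possible ancestral rediploidization
#' topologies (evaluated by running the enumerator); and no unplaced genes.
#'
#' @param families Named list of family objects with \code{genes} carrying
#'   paralogon labels.
#' @param lineages Named vector species -> lineage.
#' @param constraints Constraint list passed to the enumerator.
#' @param max_topologies Criterion-(iv) bound (default 10).
#' @return The retained subset, with attribute \code{"reasons"} recording
#'   why each dropped family failed.
#' @export
select_redip_families <- function(families, lineages, constraints = NULL,
                                  max_topologies = 10L) {
  reasons <- character(0)
  keep <- logical(length(families))
  for (i in seq_along(families)) {
    f <- families[[i]]
    g <- f$genes
    if (any(g$paralogon == "unplaced")) { reasons[i] <- "unplaced"; next }
    gn <- g[lineages[g$species] == "gnathostome", , drop = FALSE]
    both <- vapply(split(paralogon_1r_copy(gn$paralogon), gn$species),
                   function(cp) all(c("1R_1", "1R_2") %in% cp), logical(1))
    if (!any(both)) { reasons[i] <- "no_gnathostome_with_both_1R_copies"; next }
    cy_species <- names(lineages)[lineages == "cyclostome"]
    if (!all(cy_species %in% g$species)) { reasons[i] <- "missing_cyclostome"; next }
    if (!any(lineages[g$species] == "outgroup")) { reasons[i] <- "no_outgroup"; next }
    nt <- length(enumerate_constrained_topologies(f, "ancestral", lineages,
                                                  constraints))
    if (nt < 1L || nt > max_topologies) { reasons[i] <- "too_many_topologies"; next }
    keep[i] <- TRUE
    reasons[i] <- "kept"
  }
  out <- families[keep]
  attr(out, "reasons") <- setNames(reasons, names(families))
  out
}

#' Test one family for ancestral vs lineage-specific rediploidization
#'
#' Builds an unconstrained tree (NJ on ML distances, branch lengths
#' optimized), optimizes every constrained topology and runs the RELL
#' topology test; the verdict is \code{"ancestral"} only if every
#' lineage-specific topology is rejected and at least one ancestral
#' topology is not (and symmetrically for \code{"lineage_specific"});
#' otherwise \code{"inconclusive"}. Alignments without variable sites are
#' inconclusive with a flag.
#'
#' @param family Family object (with \code{alignment}).
#' @param lineages Named vector species -> lineage.
#' @param constraints Constraint list for the enumerator.
#' @param model Substitution model.
#' @param alpha Rejection level (default 0.05).
#' @param n_rell RELL resamples.
#' @param seed Integer seed.
#' @param balanced Balanced enumeration (paired within-copy test).
#' @return List of class \code{"redip_verdict"}: family_id, clg, verdict,
#'   p (named per topology), n_ancestral_topologies, degenerate.
#' @export
test_family <- function(family, lineages, constraints = NULL,
                        model = poisson_model(), alpha = 0.05,
                        n_rell = 1000L, seed = 1L, balanced = FALSE) {
  anc <- enumerate_constrained_topologies(family, "ancestral", lineages,
                                          constraints, balanced = balanced)
  ls <- enumerate_constrained_topologies(family, "lineage_specific", lineages,
                                         constraints)
  if (!length(anc)) stop("no ancestral topology can be derived; family is uninformative")
  aln <- family$alignment
  degenerate <- all(apply(aln, 2, function(col) {
    u <- unique(col[!col %in% GAP_CHARS]); length(u) <= 1L
  }))
  if (degenerate) {
    return(structure(list(family_id = family$family_id, clg = family$clg,
                          verdict = "inconclusive", p = NULL,
                          n_ancestral_topologies = length(anc),
                          degenerate = TRUE),
                     class = "redip_verdict"))
  }
  ml_tree <- neighbor_joining(ml_distance_matrix(aln, model, saturated = 8))
  cands <- c(list(ML = ml_tree),
             lapply(anc, function(s) ape::read.tree(text = s)),
             lapply(ls, function(s) ape::read.tree(text = s)))
  tt <- topology_test(cands, aln, model, n_rell = n_rell, seed = seed,
                      alpha = alpha, method = "KH", opt_sweeps = 6L,
                      opt_tol = 1e-2)
  is_anc <- grepl("^ancestral", tt$tree)
  is_ls <- tt$tree == "lineage_specific"
  anc_ok <- any(!tt$rejected[is_anc])
  ls_ok <- any(!tt$rejected[is_ls])
  anc_all_rej <- all(tt$rejected[is_anc])
  ls_all_rej <- all(tt$rejected[is_ls])
  verdict <- if (ls_all_rej && anc_ok) "ancestral"
  else if (anc_all_rej && ls_ok) "lineage_specific"
  else "inconclusive"
  structure(list(family_id = family$family_id, clg = family$clg,
                 verdict = verdict, p = setNames(tt$p, tt$tree),
                 n_ancestral_topologies = length(anc), degenerate = FALSE),
            class = "redip_verdict")
}

#' Tally rediploidization verdicts per CLG
#'
#' @param verdicts List of \code{redip_verdict} objects.
#' @return data.frame: clg, ancestral, lineage_specific, inconclusive,
#'   n_tested; column sums conserve the number of tested families.
#' @export
tally_by_clg <- function(verdicts) {
  df <- data.frame(
    clg = vapply(verdicts, `[[`, character(1), "clg"),
    verdict = vapply(verdicts, `[[`, character(1), "verdict"),
    stringsAsFactors = FALSE)
  tab <- table(df$clg, factor(df$verdict, levels = c("ancestral",
                                                     "lineage_specific",
                                                     "inconclusive")))
  out <- data.frame(clg = rownames(tab),
                    ancestral = as.vector(tab[, "ancestral"]),
                    lineage_specific = as.vector(tab[, "lineage_specific"]),
                    inconclusive = as.vector(tab[, "inconclusive"]),
                    stringsAsFactors = FALSE)
  out$n_tested <- out$ancestral + out$lineage_specific + out$inconclusive
  rownames(out) <- NULL
  out
}

#' Summarize paralogon divergence times (bimodality check)
#'
#' Fits one- and two-component normal mixtures by maximum likelihood
#' (equal-variance parameterization, deterministic hierarchical
#' initialization) and reports the component means and the BIC-preferred
#' number of components. Fewer than \code{min_n} ages refuses to fit and
#' returns the ages only.
#'
#' @param ages Numeric vector of duplication-node ages (Ma), e.g. the
#'   2R_CY readings of \code{\link{classify_nodes}} across CLG trees.
#' @param min_n Minimum number of ages for mixture fitting (default 4).
#' @return List of class \code{"divergence_summary"}: ages, n, fitted
#'   (logical), means (per component count), bic, preferred (1 or 2).
#' @export
divergence_time_distribution <- function(ages, min_n = 4L) {
  ages <- ages[is.finite(ages)]
  out <- list(ages = ages, n = length(ages), fitted = FALSE,
              means = NULL, bic = NULL, preferred = NA_integer_)
  if (length(ages) < min_n) {
    class(out) <- "divergence_summary"
    return(out)
  }
  if (stats::sd(ages) == 0) {
    out$fitted <- TRUE
    out$means <- list(`1` = mean(ages), `2` = c(mean(ages), mean(ages)))
    out$bic <- c(`1` = 0, `2` = -Inf)
    out$preferred <- 1L
    class(out) <- "divergence_summary"
    return(out)
  }
  f1 <- mclust::Mclust(ages, G = 1, modelNames = "E", verbose = FALSE)
  f2 <- mclust::Mclust(ages, G = 2, modelNames = "E", verbose = FALSE)
  out$fitted <- TRUE
  out$means <- list(`1` = unname(f1$parameters$mean),
                    `2` = sort(unname(f2$parameters$mean)))
  out$bic <- c(`1` = unname(f1$bic), `2` = if (!is.null(f2)) unname(f2$bic) else -Inf)
  out$preferred <- if (out$bic["2"] > out$bic["1"]) 2L else 1L
  class(out) <- "divergence_summary"
  out
}
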