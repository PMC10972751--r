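## Dated gene-tree simulation from the scripted event history. A per-CLG
## template realizes every WGD on the lineage as a duplication node at the
## scheduled rediploidization (or progenitor divergence) age; gene loss then
## prunes tips i.i.d. per copy per terminal lineage.

## Recursive template for one CLG. Node = list(age, event, children) or tip =
## list(age = 0, event = "tip", species, segment).
.clg_template <- function(scenario, clg) {
  sp <- scenario$speciations
  ev <- scenario$events
  t_jv <- ev[["2R_JV"]]$progenitor_divergences[1]
  t_cy <- ev[["2R_CY"]]$progenitor_divergences
  tip <- function(species, seg)
    list(age = 0, event = "tip", species = species, segment = seg)
  gn_clade <- function(copy, t_dup) {
    segs <- paste0(c("alpha", "beta"), copy)
    sub <- function(seg)
      list(age = sp[["gnathostome_crown"]], event = "speciation",
           children = list(tip("gar", seg), tip("frog", seg)))
    list(age = t_dup, event = "2R_JV",
         children = list(sub(segs[1]), sub(segs[2])))
  }
  cy_pair <- function(seg)
    list(age = sp[["hagfish_lamprey"]], event = "speciation",
         children = list(tip("hagfish", seg), tip("lamprey", seg)))
  ls_clg <- !is.na(scenario$lineage_specific_clg) &&
    identical(clg, scenario$lineage_specific_clg)
  if (!ls_clg) {
    cy_clade <- function(copy) {
      segs <- paste0("c", copy, c("a", "b", "c"))
      inner <- list(age = t_cy[2], event = "2R_CY",
                    children = list(cy_pair(segs[2]), cy_pair(segs[3])))
      list(age = t_cy[1], event = "2R_CY",
           children = list(cy_pair(segs[1]), inner))
    }
    copy_clade <- function(k)
      list(age = sp[["cyclostome_gnathostome"]], event = "speciation",
           children = list(gn_clade(k, t_jv), cy_clade(k)))
    vert <- list(age = scenario$redip_1R[[clg]], event = "1R",
                 children = list(copy_clade(1), copy_clade(2)))
  } else {
    ls <- scenario$ls_redip
    gn <- list(age = ls[["gnathostome"]], event = "1R",
               children = list(gn_clade(1, t_jv), gn_clade(2, t_jv)))
    hag <- list(age = ls[["hagfish"]], event = "1R",
                children = list(tip("hagfish", "h1"), tip("hagfish", "h2")))
    lam <- list(age = ls[["lamprey"]], event = "1R",
                children = list(tip("lamprey", "l1"), tip("lamprey", "l2")))
    cy <- list(age = sp[["hagfish_lamprey"]], event = "speciation",
               children = list(hag, lam))
    vert <- list(age = sp[["cyclostome_gnathostome"]], event = "speciation",
                 children = list(gn, cy))
  }
  list(age = sp[["root"]], event = "speciation",
       children = list(tip("outgroup", "out"), vert))
}

## Prune tips failing `keep`, collapsing unary internal nodes.
.prune_template <- function(node, keep) {
  if (node$event == "tip") return(if (keep(node)) node else NULL)
  kids <- Filter(Negate(is.null),
                 lapply(node$children, .prune_template, keep = keep))
  if (!length(kids)) return(NULL)
  if (length(kids) == 1L) return(kids[[1]])
  node$children <- kids
  node
}

## Convert a recursive template to phylo + per-node age/event annotations.
.template_to_phylo <- function(node) {
  tips <- list(); inner <- list(); edges <- list()
  count_tips <- function(n) {
    if (n$event == "tip") return(1L)
    sum(vapply(n$children, count_tips, integer(1)))
  }
  ntip <- count_tips(node)
  tip_i <- 0L; node_i <- ntip
  tip_lab <- character(ntip)
  tip_info <- vector("list", ntip)
  ages <- numeric(0); events <- character(0)
  rec <- function(n) {
    if (n$event == "tip") {
      tip_i <<- tip_i + 1L
      tip_lab[tip_i] <<- paste(n$species, n$segment, sep = "|")
      tip_info[[tip_i]] <<- data.frame(label = tip_lab[tip_i],
                                       species = n$species,
                                       segment = n$segment,
                                       stringsAsFactors = FALSE)
      ages[tip_i] <<- 0
      return(tip_i)
    }
    node_i <<- node_i + 1L
    me <- node_i
    ages[me] <<- n$age
    events[me] <<- n$event
    for (ch in n$children) {
      id <- rec(ch)
      edges[[length(edges) + 1L]] <<- c(me, id)
    }
    me
  }
  if (node$event == "tip") stop("family reduced to a single gene")
  rec(node)
  edge <- do.call(rbind, edges)
  ages <- ages[seq_len(node_i)]
  phy <- list(edge = edge, Nnode = node_i - ntip, tip.label = tip_lab,
              edge.length = ages[edge[, 1]] - ages[edge[, 2]])
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  events[seq_len(ntip)] <- "tip"
  list(phy = phy, ages = ages, events = events,
       tips = do.call(rbind, tip_info))
}

#' Simulate a dated gene-family tree for one CLG
#'
#' Realizes the scenario's duplication history for one chordate linkage
#' group: each WGD on the family's lineage creates duplicate subtrees whose
#' divergence age equals the scheduled rediploidization (or
#' progenitor-divergence) age for that CLG, exactly; gene loss prunes each
#' tip independently with probability 1 - retention of the events it
#' descends from. The outgroup copy is retained. Trees are ultrametric in
#' Ma with node annotations recording the generating event.
#'
#' @param scenario An \code{\link{default_scenario}} object.
#' @param clg CLG id (e.g. \code{"CLGA"}).
#' @param seed Integer seed.
#' @return An object of class \code{"gene_tree"}: \code{phy} (dated
#'   \code{phylo}, branch lengths in Ma), \code{ages}, \code{events} (per
#'   node: \code{"tip"}, \code{"speciation"}, \code{"1R"}, \code{"2R_JV"},
#'   \code{"2R_CY"}), \code{tips} (data.frame label/species/segment) and
#'   \code{clg}.
#' @export
simulate_family_tree <- function(scenario, clg, seed = 1L) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  if (!clg %in% scenario$clgs) stop("unknown CLG: ", clg)
  tmpl <- .clg_template(scenario, clg)
  ev <- scenario$events
  surv <- c(outgroup = 1,
            gnathostome = ev[["1R"]]$retention * ev[["2R_JV"]]$retention,
            cyclostome = ev[["1R"]]$retention * ev[["2R_CY"]]$retention)
  lineage_of <- setNames(scenario$species$lineage, scenario$species$species)
  keep_draw <- with_seed(seed, {
    ## deterministic per-tip retention draws in template tip order
    draws <- new.env()
    collect <- function(n) {
      if (n$event == "tip") {
        key <- paste(n$species, n$segment, sep = "|")
        assign(key, stats::runif(1) <= surv[[lineage_of[[n$species]]]],
               envir = draws)
      } else lapply(n$children, collect)
      invisible(NULL)
    }
    collect(tmpl)
    draws
  })
  keep <- function(tipnode) {
    get(paste(tipnode$species, tipnode$segment, sep = "|"), envir = keep_draw)
  }
  pruned <- .prune_template(tmpl, keep)
  n_vert <- function(n) {
    if (is.null(n)) return(0L)
    if (n$event == "tip") return(as.integer(n$species != "outgroup"))
    sum(vapply(n$children, n_vert, integer(1)))
  }
  if (n_vert(pruned) == 0L)
    stop("all gene copies lost in all vertebrate species; resample")
  out <- .template_to_phylo(pruned)
  out$tips$clg <- clg
  out$clg <- clg
  class(out) <- "gene_tree"
  out
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree (", x$clg, "): ", nrow(x$tips), " genes, root age ",
      max(x$ages), " Ma\n", sep = "")
  invisible(x)
}
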