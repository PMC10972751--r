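## Stage orchestration: per-CLG paralogon trees (supermatrix -> NJ ->
## bootstrap -> rooting -> dating -> node readings), rediploidization
## testing, synteny/CLG recovery and the coverage scan, plus a config-driven
## run_pipeline() with a checksummed manifest.

#' Attach chromosomes and paralogon labels to simulated families
#'
#' @param dataset A \code{sim_dataset}.
#' @param karyotype A \code{karyotype_sim} on the same dataset.
#' @return The dataset with each family's \code{genes} gaining
#'   \code{chromosome} and \code{paralogon} columns.
#' @export
annotate_families <- function(dataset, karyotype) {
  ref <- paralogon_reference(karyotype)
  gm <- karyotype$gene_map
  for (nm in names(dataset$families)) {
    g <- dataset$families[[nm]]$genes
    g$chromosome <- gm$chromosome[match(g$gene_id, gm$gene_id)]
    g <- classify_paralogons(g, ref)
    dataset$families[[nm]]$genes <- g
  }
  dataset
}

## Species sets below every node of a rooted tree (tips "species|segment").
.node_species_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  spp <- sub("\\|.*", "", phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- spp[i]
  for (e in seq_len(nrow(po$edge)))
    sets[[po$edge[e, 1]]] <- union(sets[[po$edge[e, 1]]], sets[[po$edge[e, 2]]])
  sets
}

## Fossil-style calibrations: the root (outgroup divergence) plus
## speciation cherries. Only cherries whose two tips are different species
## of one lineage AND carry the same segment key are calibrated: matching
## segments identify chromosomal orthologs, so the cherry is a true
## speciation; mismatched segments may be hidden paralogy (divergence older
## than the speciation) or lineage-specific rediploidization (younger) and
## are left free.
.speciation_calibrations <- function(phy, lineages, cal_ages) {
  ntip <- length(phy$tip.label)
  sp <- sub("\\|.*", "", phy$tip.label)
  seg <- sub(".*\\|", "", phy$tip.label)
  rows <- list(data.frame(node = ntip + 1L, age_min = cal_ages[["root"]],
                          age_max = cal_ages[["root"]]))
  children <- split(phy$edge[, 2], phy$edge[, 1])
  for (v in (ntip + 2L):(ntip + phy$Nnode)) {
    ch <- children[[as.character(v)]]
    if (length(ch) != 2L || any(ch > ntip)) next
    s1 <- sp[ch[1]]; s2 <- sp[ch[2]]
    if (s1 == s2 || seg[ch[1]] != seg[ch[2]]) next
    lin <- unique(lineages[c(s1, s2)])
    if (length(lin) != 1L) next
    key <- paste0(lin, "_pair")
    if (!is.null(cal_ages[[key]]))
      rows[[length(rows) + 1L]] <- data.frame(node = v,
                                              age_min = cal_ages[[key]],
                                              age_max = cal_ages[[key]])
  }
  do.call(rbind, rows)
}

#' Build and date one CLG paralogon tree
#'
#' Concatenates the CLG's families into a supermatrix keyed by (species,
#' segment), builds a neighbor-joining tree on ML distances, polishes its
#' topology with likelihood-evaluated NNI candidates and re-fits branch
#' lengths by maximum likelihood, attaches RELL-vote bootstrap supports
#' over the candidate neighborhood, roots on the outgroup row, dates the
#' tree by strict-clock least squares with fossil-style calibrations on
#' speciation nodes, and reads duplication/speciation nodes off the result.
#'
#' @param families The CLG's annotated families.
#' @param lineages Named vector species -> lineage.
#' @param model Substitution model.
#' @param n_boot Support resolution: RELL-vote replicates are
#'   \code{10 * n_boot} (default 100, i.e. 1000 votes).
#' @param seed Integer seed.
#' @param cal_ages Named list of calibration ages (\code{root},
#'   \code{cyclostome_pair}, \code{gnathostome_pair}); \code{NULL} entries
#'   are skipped.
#' @param min_occupancy Supermatrix row-occupancy threshold.
#' @return List of class \code{"clg_tree"}: clg, supermatrix, tree (rooted,
#'   supports as node labels), dated (\code{dated_tree}), readings
#'   (\code{node_reading}), and summary components (presplit_1r,
#'   event_ages, split_ages).
#' @export
analyze_clg <- function(families, lineages, model = poisson_model(),
                        n_boot = 100L, seed = 1L,
                        cal_ages = list(root = 600, cyclostome_pair = 457,
                                        gnathostome_pair = 430),
                        min_occupancy = 0.2) {
  clg <- unique(vapply(families, `[[`, character(1), "clg"))
  sm <- suppressWarnings(build_supermatrix(families, min_occupancy))
  if (nrow(sm$alignment) < 4)
    stop("CLG ", clg, ": fewer than 4 supermatrix rows")
  nj <- neighbor_joining(ml_distance_matrix(sm$alignment, model,
                                            saturated = 8))
  og <- grep("^outgroup\\|", nj$tip.label, value = TRUE)
  if (!length(og)) stop("CLG ", clg, ": no outgroup row to root on")
  ## polish the NJ topology with likelihood-evaluated NNI candidates (the
  ## deep inter-polyploidization branches are below distance resolution),
  ## then re-fit branch lengths by ML for dating
  rf <- refine_topology(nj, sm$alignment, model)
  opt <- suppressWarnings(
    optimize_branch_lengths(rf$tree, sm$alignment, model,
                            max_sweeps = 20L, tol = 1e-3))
  final <- opt$tree
  ## root before computing supports so node labels stay aligned
  rooted <- ape::root(final, outgroup = og, resolve.root = TRUE)
  candidates <- c(list(final), nni_neighbors(final))
  rooted <- rell_bootstrap_support(rooted, candidates, sm$alignment, model,
                                   n = n_boot * 10L,
                                   seed = stage_seed(seed, paste0("boot_", clg)))
  support <- suppressWarnings(as.numeric(rooted$node.label))
  cal <- .speciation_calibrations(rooted, lineages, cal_ages)
  dated <- date_nodes(rooted, cal)
  readings <- classify_nodes(rooted, lineages, ages = dated$ages,
                             support = support)
  sets <- .node_species_sets(rooted)
  ntip <- length(rooted$tip.label)
  cy <- names(lineages)[lineages == "cyclostome"]
  gn <- names(lineages)[lineages == "gnathostome"]
  has_out <- vapply(sets, function(s) any(lineages[s] == "outgroup"), logical(1))
  cygn <- vapply(sets, function(s)
    any(lineages[s] == "cyclostome") && any(lineages[s] == "gnathostome"),
    logical(1))
  spec <- readings$type == "speciation"
  nodes <- readings$node
  split_ages <- list(
    cyclostome_gnathostome = readings$age[spec & cygn[nodes] & !has_out[nodes]],
    hagfish_lamprey = readings$age[spec & vapply(sets[nodes], setequal, logical(1), y = cy)],
    gnathostome_crown = readings$age[spec & vapply(sets[nodes], setequal, logical(1), y = gn)])
  event_ages <- split(readings$age[readings$type == "duplication"],
                      readings$event[readings$type == "duplication"])
  structure(list(clg = clg, supermatrix = sm, tree = rooted, dated = dated,
                 readings = readings,
                 presplit_1r = has_presplit_1r(readings, bp = 60),
                 event_ages = event_ages, split_ages = split_ages),
            class = "clg_tree")
}

#' Run the paralogon-tree stage over all CLGs
#'
#' @param dataset Annotated \code{sim_dataset} (see
#'   \code{\link{annotate_families}}).
#' @param lineages Named vector species -> lineage.
#' @inheritParams analyze_clg
#' @return List of class \code{"wgd_analysis"}: \code{clg_trees}, and
#'   aggregate \code{summary} (fraction of CLG trees with a pre-split 1R
#'   node at BP > 60, presence of gnathostome-only and cyclostome-only
#'   duplications, mean event/speciation age estimates, pooled 2R_CY ages
#'   and their mixture summary).
#' @export
run_wgd_analysis <- function(dataset, lineages, model = poisson_model(),
                             n_boot = 100L, seed = 1L,
                             cal_ages = list(root = 600,
                                             cyclostome_pair = 457,
                                             gnathostome_pair = 430)) {
  fams <- dataset$families
  clgs <- unique(vapply(fams, `[[`, character(1), "clg"))
  trees <- list()
  for (clg in clgs) {
    fc <- fams[vapply(fams, function(f) f$clg == clg, logical(1))]
    trees[[clg]] <- tryCatch(
      analyze_clg(fc, lineages, model, n_boot, seed, cal_ages),
      error = function(e) structure(list(clg = clg, error = conditionMessage(e)),
                                    class = "clg_tree_error"))
  }
  ok <- trees[vapply(trees, inherits, logical(1), "clg_tree")]
  presplit <- vapply(ok, `[[`, logical(1), "presplit_1r")
  ages_of <- function(ev) unlist(lapply(ok, function(t) t$event_ages[[ev]]))
  splits_of <- function(nm) unlist(lapply(ok, function(t) t$split_ages[[nm]]))
  cy_ages <- ages_of("2R_CY")
  ## shared (pre-speciation) duplication divergences only: a cyclostome
  ## duplication node younger than the hagfish-lamprey split cannot reflect
  ## a shared polyploidy - it is lineage-specific rediploidization
  cy_floor <- cal_ages$cyclostome_pair %||% -Inf
  cy_shared <- cy_ages[cy_ages > cy_floor]
  summary <- list(
    n_clgs = length(ok),
    presplit_1r_fraction = mean(presplit),
    has_gnathostome_duplications = mean(vapply(ok, function(t)
      length(t$event_ages[["2R_JV"]]) > 0, logical(1))),
    has_cyclostome_duplications = mean(vapply(ok, function(t)
      length(t$event_ages[["2R_CY"]]) > 0, logical(1))),
    age_1R = mean(ages_of("1R")),
    age_2R_JV = mean(ages_of("2R_JV")),
    age_cyclostome_gnathostome = mean(splits_of("cyclostome_gnathostome")),
    cy_ages = cy_ages,
    cy_ages_shared = cy_shared,
    cy_mixture = divergence_time_distribution(cy_shared))
  structure(list(clg_trees = trees, summary = summary),
            class = "wgd_analysis")
}

#' Reference cyclostome chromosomal constraints
#'
#' The chromosomal knowledge the per-family tests borrow from the
#' chromosome-scale classification, as the real analysis borrows
#' well-supported chromosomal orthologies: \code{orthologs} are
#' hagfish/lamprey derivatives of the same segment (constrained to joint
#' clade placement) and \code{exclusions} are segment pairs descending
#' from different duplication copies (constrained to opposite clades under
#' the ancestral model). For the lineage-specific CLG no true cross-species
#' orthology exists: its segments are paired positionally (as an ambiguous
#' synteny assignment would be) and each species' two segments are mutually
#' exclusive.
#'
#' @param scenario The \code{evolution_scenario}.
#' @return Named list (per CLG) with elements \code{orthologs} and
#'   \code{exclusions} for \code{\link{enumerate_constrained_topologies}}.
#' @export
cyclostome_orthology_constraints <- function(scenario) {
  out <- list()
  copy1 <- paste0("c1", c("a", "b", "c"))
  copy2 <- paste0("c2", c("a", "b", "c"))
  anc_ex <- list()
  for (s1 in copy1) for (s2 in copy2) for (sp in c("hagfish", "lamprey"))
    anc_ex[[length(anc_ex) + 1L]] <- paste(sp, c(s1, s2), sep = "|")
  for (clg in scenario$clgs) {
    if (!is.na(scenario$lineage_specific_clg) &&
        clg == scenario$lineage_specific_clg) {
      out[[clg]] <- list(
        orthologs = list(c("hagfish|h1", "lamprey|l1"),
                         c("hagfish|h2", "lamprey|l2")),
        exclusions = list(c("hagfish|h1", "hagfish|h2"),
                          c("lamprey|l1", "lamprey|l2")))
    } else {
      out[[clg]] <- list(
        orthologs = lapply(c(copy1, copy2), function(s)
          c(paste0("hagfish|", s), paste0("lamprey|", s))),
        exclusions = anc_ex)
    }
  }
  out
}

#' Run the rediploidization tests over all CLGs
#'
#' Selects informative families (criteria i-iv), tests each against its
#' constrained ancestral and lineage-specific topologies, tallies verdicts
#' per CLG and flags CLGs with more lineage-specific than ancestral
#' support.
#'
#' @param dataset Annotated \code{sim_dataset}.
#' @param lineages Named vector species -> lineage.
#' @param constraints Per-CLG constraint lists (e.g.
#'   \code{\link{cyclostome_orthology_constraints}}).
#' @param model Substitution model.
#' @param alpha Rejection level.
#' @param n_rell RELL resamples per test.
#' @param seed Integer seed.
#' @param max_topologies Criterion-(iv) bound.
#' @return List of class \code{"redip_analysis"}: verdicts, tally,
#'   flagged_clgs, n_selected.
#' @export
run_redip_tests <- function(dataset, lineages, constraints = NULL,
                            model = poisson_model(), alpha = 0.05,
                            n_rell = 500L, seed = 1L, max_topologies = 10L) {
  verdicts <- list()
  n_selected <- 0L
  for (clg in unique(dataset$gene_table$clg)) {
    fams <- dataset$families[vapply(dataset$families, function(f)
      f$clg == clg, logical(1))]
    cons <- if (!is.null(constraints)) constraints[[clg]] else NULL
    sel <- select_redip_families(fams, lineages, cons, max_topologies)
    n_selected <- n_selected + length(sel)
    for (f in sel) {
      v <- tryCatch(
        test_family(f, lineages, cons, model, alpha, n_rell,
                    seed = stage_seed(seed, paste0("redip_", f$family_id))),
        error = function(e) NULL)
      if (!is.null(v)) verdicts[[f$family_id]] <- v
    }
  }
  tally <- if (length(verdicts)) tally_by_clg(verdicts) else NULL
  flagged <- if (!is.null(tally))
    tally$clg[tally$lineage_specific > tally$ancestral] else character(0)
  structure(list(verdicts = verdicts, tally = tally,
                 flagged_clgs = flagged, n_selected = n_selected),
            class = "redip_analysis")
}

#' Synteny stage: MBH orthology, enrichment and CLG recovery
#'
#' Runs the reciprocal similarity search between a focal species and the
#' outgroup reference, keeps mutual best hits, transfers CLG labels from
#' the reference, tests chromosome-by-chromosome enrichment and assigns
#' per-bin CLG composition.
#'
#' @param dataset A \code{sim_dataset}.
#' @param karyotype Matching \code{karyotype_sim}.
#' @param focal Focal species (default \code{"hagfish"}).
#' @param reference_species Reference species carrying CLG labels
#'   (default \code{"outgroup"}).
#' @param k Word size for the similarity search.
#' @param bin_size Genes per bin.
#' @return List of class \code{"synteny_analysis"}: pairs, enrichment
#'   (focal vs reference chromosomes), assignment
#'   (\code{\link{assign_clgs}} result), mbh_family_precision.
#' @export
run_synteny <- function(dataset, karyotype, focal = "hagfish",
                        reference_species = "outgroup", k = 4L,
                        bin_size = 20L) {
  prot <- proteomes(dataset)
  hits_fr <- similarity_search(prot[[focal]], prot[[reference_species]], k = k)
  hits_rf <- similarity_search(prot[[reference_species]], prot[[focal]], k = k)
  pairs <- mutual_best_hits(hits_fr, hits_rf)
  gt <- dataset$gene_table
  fam <- setNames(gt$family_id, gt$gene_id)
  precision <- mean(fam[pairs$geneA] == fam[pairs$geneB])
  gm <- karyotype$gene_map
  mapF <- gm[gm$species == focal, c("gene_id", "chromosome", "start")]
  mapR <- gm[gm$species == reference_species, c("gene_id", "chromosome", "start")]
  enrichment <- chromosome_association_test(pairs, mapF, mapR)
  ## CLG labels transfer through each focal gene's top reference hit (the
  ## reference has one copy per CLG, so mutual matching would label at most
  ## one focal gene per family); the MBH pairs stay the basis of the
  ## chromosome-association matrix above
  top <- hits_fr[order(hits_fr$query, -hits_fr$score, hits_fr$target), ]
  top <- top[!duplicated(top$query), ]
  labels <- transfer_clg_labels(data.frame(geneA = top$query,
                                           geneB = top$target,
                                           stringsAsFactors = FALSE),
                                data.frame(gene_id = gt$gene_id,
                                           clg = gt$clg))
  assignment <- assign_clgs(mapF, labels, bin_size = bin_size)
  structure(list(pairs = pairs, enrichment = enrichment,
                 assignment = assignment,
                 mbh_family_precision = precision),
            class = "synteny_analysis")
}

#' Coverage-scan stage: mask, score, segment and call
#'
#' @param germ,soma \code{\link{depth_track}} objects.
#' @param params \code{\link{scan_params}}.
#' @param n_perm Permutations per segmentation split.
#' @param seed Integer seed.
#' @return List of class \code{"elimination_analysis"}: modal_germ,
#'   modal_soma, intervals (scored), segments, calls.
#' @export
run_elimination <- function(germ, soma, params = scan_params(),
                            n_perm = 500L, seed = 1L) {
  mg <- modal_depth(germ); ms <- modal_depth(soma)
  mask <- mask_positions(germ, soma, params, mg, ms)
  iv <- make_intervals(mask, params$v)
  scored <- interval_enrichment(iv, germ, soma, params, mask, mg, ms)
  segs <- segment_scores(scored, n_perm = n_perm, seed = seed)
  calls <- call_germline_specific(segs, params$call_threshold)
  structure(list(modal_germ = mg, modal_soma = ms, intervals = scored,
                 segments = segs, calls = calls),
            class = "elimination_analysis")
}

#' Base-level precision and recall of called regions against a truth set
#'
#' @param calls data.frame contig, start, end (0-based half-open).
#' @param truth data.frame contig, start, end.
#' @return List: precision, recall, called_bases, truth_bases,
#'   overlap_bases.
#' @export
region_overlap_stats <- function(calls, truth) {
  bases <- function(df, ct) {
    sub <- df[df$contig == ct, , drop = FALSE]
    if (!nrow(sub)) return(integer(0))
    unlist(lapply(seq_len(nrow(sub)), function(i)
      if (sub$end[i] > sub$start[i]) (sub$start[i] + 1L):sub$end[i] else integer(0)))
  }
  cts <- union(unique(calls$contig), unique(truth$contig))
  called <- 0; tru <- 0; ovl <- 0
  for (ct in cts) {
    cb <- unique(bases(calls, ct)); tb <- unique(bases(truth, ct))
    called <- called + length(cb)
    tru <- tru + length(tb)
    ovl <- ovl + length(intersect(cb, tb))
  }
  list(precision = if (called > 0) ovl / called else NA_real_,
       recall = if (tru > 0) ovl / tru else NA_real_,
       called_bases = called, truth_bases = tru, overlap_bases = ovl)
}

#' Run the full pipeline from a configuration
#'
#' Executes the requested stages (\code{simulate}, \code{synteny},
#' \code{trees}, \code{infer_wgd}, \code{eliminate}) with per-stage seeds
#' derived from the global seed, writes stage outputs under \code{outdir}
#' and records an append-only manifest of artifacts with MD5 checksums.
#' Identical configuration and seed give identical outputs.
#'
#' @param config Nested list; see the package vignette. Recognized blocks:
#'   \code{scenario} (clg_count, rate, n_families, sites),
#'   \code{synteny}, \code{trees} (n_boot), \code{infer_wgd} (alpha,
#'   n_rell), \code{eliminate} (layout and scan parameters). A block must
#'   be present (even if empty) for its stage to run; \code{eliminate}
#'   alone runs without the simulation stages.
#' @param seed Global integer seed.
#' @param outdir Output directory (created).
#' @return List of class \code{"pipeline_run"} with stage results and the
#'   \code{manifest} data.frame.
#' @export
run_pipeline <- function(config = list(scenario = list()), seed = 1L,
                         outdir = tempfile("paralogon_run_")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(name, file) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      artifact = name, file = file,
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }
  res <- list(outdir = outdir, seed = seed)
  lineages <- NULL
  needs_sim <- any(c("scenario", "synteny", "trees", "infer_wgd") %in%
                     names(config))
  if (needs_sim) {
    sc_cfg <- config$scenario %||% list()
    scenario <- default_scenario(
      clg_count = sc_cfg$clg_count %||% 17L,
      rate = sc_cfg$rate %||% 5e-4)
    lineages <- setNames(scenario$species$lineage, scenario$species$species)
    dataset <- simulate_gene_families(
      scenario, n_families = sc_cfg$n_families %||% 20L,
      sites = sc_cfg$sites %||% 300L,
      seed = stage_seed(seed, "simulate"))
    karyotype <- simulate_karyotypes(dataset,
                                     seed = stage_seed(seed, "karyotype"))
    dataset <- annotate_families(dataset, karyotype)
    gt_file <- file.path(outdir, "gene_map.tsv")
    write_tsv(karyotype$gene_map, gt_file); note("gene_map", gt_file)
    tl_file <- file.path(outdir, "truth_log.json")
    write_truth_log(list(genes = dataset$gene_table,
                         units = karyotype$units), tl_file)
    note("truth_log", tl_file)
    res$scenario <- scenario
    res$dataset <- dataset
    res$karyotype <- karyotype
  }
  if ("synteny" %in% names(config)) {
    syn <- run_synteny(dataset, karyotype,
                       focal = config$synteny$focal %||% "hagfish")
    f <- file.path(outdir, "enrichment.tsv")
    write_tsv(syn$enrichment, f); note("enrichment", f)
    f <- file.path(outdir, "clg_bins.tsv")
    write_tsv(syn$assignment$bins, f); note("clg_bins", f)
    res$synteny <- syn
  }
  if ("trees" %in% names(config)) {
    wgd <- run_wgd_analysis(dataset, lineages,
                            n_boot = config$trees$n_boot %||% 100L,
                            seed = stage_seed(seed, "trees"))
    f <- file.path(outdir, "wgd_summary.json")
    s <- wgd$summary
    s$cy_mixture <- list(preferred = s$cy_mixture$preferred,
                         means = s$cy_mixture$means[["2"]])
    jsonlite::write_json(s, f, auto_unbox = TRUE, digits = NA, force = TRUE)
    note("wgd_summary", f)
    res$wgd <- wgd
  }
  if ("infer_wgd" %in% names(config)) {
    cons <- cyclostome_orthology_constraints(res$scenario)
    redip <- run_redip_tests(dataset, lineages, cons,
                             alpha = config$infer_wgd$alpha %||% 0.05,
                             n_rell = config$infer_wgd$n_rell %||% 500L,
                             seed = stage_seed(seed, "redip"))
    if (!is.null(redip$tally)) {
      f <- file.path(outdir, "redip_tally.tsv")
      write_tsv(redip$tally, f); note("redip_tally", f)
    }
    res$redip <- redip
  }
  if ("eliminate" %in% names(config)) {
    el_cfg <- config$eliminate
    if (!is.null(el_cfg$germ) && !is.null(el_cfg$soma)) {
      germ <- el_cfg$germ; soma <- el_cfg$soma
      truth <- el_cfg$truth
    } else {
      layout <- default_depth_layout(seed = stage_seed(seed, "layout"))
      sim <- simulate_depth_tracks(layout$contigs, layout$planted_regions,
                                   seed = stage_seed(seed, "depth"))
      germ <- sim$germ; soma <- sim$soma; truth <- sim$truth
    }
    params <- el_cfg$params %||% scan_params()
    elim <- run_elimination(germ, soma, params,
                            n_perm = el_cfg$n_perm %||% 500L,
                            seed = stage_seed(seed, "eliminate"))
    if (!is.null(truth)) {
      elim$recovery <- region_overlap_stats(elim$calls$regions, truth)
      elim$truth <- truth
    }
    f <- file.path(outdir, "germline_specific.tsv")
    write_tsv(elim$calls$regions, f); note("germline_calls", f)
    res$eliminate <- elim
  }
  res$manifest <- do.call(rbind, manifest)
  mf <- file.path(outdir, "manifest.tsv")
  write_tsv(res$manifest, mf)
  class(res) <- "pipeline_run"
  res
}
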