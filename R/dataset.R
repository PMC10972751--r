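#' Simulate gene families with sequences for a whole scenario
#'
#' Draws \code{n_families} gene families per CLG (resampling families in
#' which every vertebrate copy was lost), evolves indel-free protein
#' alignments along each dated family tree, and assigns opaque gene ids.
#' The result carries a machine-readable truth log mapping every gene to
#' its species, CLG and true paralogon segment.
#'
#' @param scenario An \code{evolution_scenario}.
#' @param n_families Families per CLG (default 20).
#' @param sites Alignment length per family (default 300).
#' @param model Substitution model for sequence evolution.
#' @param seed Integer seed.
#' @param informative If \code{TRUE}, resample families until each contains
#'   at least one hagfish, one lamprey and one outgroup gene (mirroring
#'   post-hoc family selection by rejection).
#' @return A list of class \code{"sim_dataset"}: \code{families} (each with
#'   \code{family_id}, \code{clg}, \code{tree}, \code{genes}, \code{alignment}
#'   keyed by gene id), \code{gene_table} (one row per emitted gene) and
#'   \code{scenario}.
#' @export
simulate_gene_families <- function(scenario, n_families = 20L, sites = 300L,
                                   model = poisson_model(), seed = 1L,
                                   informative = FALSE) {
  stopifnot(inherits(scenario, "evolution_scenario"), n_families >= 1)
  families <- list()
  gene_counter <- 0L
  fam_counter <- 0L
  for (clg in scenario$clgs) {
    for (i in seq_len(n_families)) {
      fam_counter <- fam_counter + 1L
      fam_id <- sprintf("fam%04d", fam_counter)
      tr <- NULL
      for (try in 1:200) {
        s <- stage_seed(seed, paste0(fam_id, "_try", try))
        tr <- tryCatch(simulate_family_tree(scenario, clg, seed = s),
                       error = function(e) NULL)
        if (is.null(tr)) next
        if (informative) {
          sp <- tr$tips$species
          if (!all(c("hagfish", "lamprey", "outgroup") %in% sp)) {
            tr <- NULL
            next
          }
        }
        break
      }
      if (is.null(tr)) stop("could not simulate an acceptable family for ", clg)
      aln <- evolve_sequences(tr, length = sites, model = model,
                              rate = scenario$rate,
                              seed = stage_seed(seed, paste0(fam_id, "_seq")))
      ids <- sprintf("g%05d", gene_counter + seq_len(nrow(tr$tips)))
      gene_counter <- gene_counter + nrow(tr$tips)
      genes <- data.frame(gene_id = ids, family_id = fam_id,
                          species = tr$tips$species, clg = clg,
                          segment = tr$tips$segment,
                          stringsAsFactors = FALSE)
      ## rename tree tips and alignment rows to gene ids
      map <- setNames(ids, tr$tips$label)
      tr$phy$tip.label <- unname(map[tr$phy$tip.label])
      rownames(aln) <- unname(map[rownames(aln)])
      families[[fam_id]] <- list(family_id = fam_id, clg = clg, tree = tr,
                                 genes = genes, alignment = aln)
    }
  }
  gene_table <- do.call(rbind, lapply(families, `[[`, "genes"))
  rownames(gene_table) <- NULL
  structure(list(families = families, gene_table = gene_table,
                 scenario = scenario),
            class = "sim_dataset")
}

#' Per-species proteomes from a simulated dataset
#'
#' @param dataset A \code{sim_dataset}.
#' @return Named list (per species) of named character vectors of protein
#'   sequences.
#' @export
proteomes <- function(dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  seqs <- unlist(lapply(dataset$families, function(f)
    setNames(apply(f$alignment, 1, paste, collapse = ""),
             rownames(f$alignment))), use.names = TRUE)
  ## unlist mangles names when family lists are named; rebuild
  nm <- unlist(lapply(dataset$families, function(f) rownames(f$alignment)))
  names(seqs) <- nm
  split(seqs, dataset$gene_table$species[match(nm, dataset$gene_table$gene_id)])
}
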