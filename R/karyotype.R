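#' Simulate per-species karyotypes and gene maps
#'
#' Places every emitted gene on a chromosome with ordinal coordinates.
#' Post-WGD units are (CLG, segment) blocks per species. Outgroup, lamprey
#' and gnathostome chromosomes each derive from a single unit; hagfish
#' chromosomes are irreversible fusions of 2-6 units (per the fusion plan),
#' drawn from distinct CLGs. Gene order within a chromosome is shuffled
#' ("highly scrambled") while chromosome membership respects the truth log.
#' Coordinates are 0-based, half-open, 1 kb per gene with a 900 b body.
#'
#' @param dataset A \code{sim_dataset} from
#'   \code{\link{simulate_gene_families}}.
#' @param fusion_plan Optional named list for species whose chromosomes fuse
#'   several units: \code{list(hagfish = list(chr1 = c("CLGA|c1a", ...)))}.
#'   Units are keyed \code{"CLG|segment"}. \code{NULL} draws a random plan
#'   for hagfish (2-6 units per chromosome, distinct CLGs); an empty list
#'   for a species keeps one unit per chromosome.
#' @param seed Integer seed.
#' @return A list of class \code{"karyotype_sim"}: \code{gene_map}
#'   (data.frame gene_id, species, chromosome, start, end, family_id),
#'   \code{units} (data.frame species, chromosome, clg, segment: the
#'   truth-log ancestral-unit composition of every chromosome) and
#'   \code{fusion_plan}.
#' @export
simulate_karyotypes <- function(dataset, fusion_plan = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "sim_dataset"))
  gt <- dataset$gene_table
  gt$unit <- paste(gt$clg, gt$segment, sep = "|")
  species <- unique(gt$species)
  plan_given <- fusion_plan
  with_seed(stage_seed(seed, "karyotype"), {
    units_rows <- list()
    map_rows <- list()
    plan_out <- list()
    for (sp in species) {
      gsp <- gt[gt$species == sp, , drop = FALSE]
      sp_units <- sort(unique(gsp$unit))
      plan <- if (!is.null(plan_given) && sp %in% names(plan_given))
        plan_given[[sp]] else NULL
      if (is.null(plan) && sp == "hagfish" && is.null(plan_given)) {
        ## random fusion plan: 2-6 units per chromosome, distinct CLGs
        shuffled <- sample(sp_units)
        groups <- list()
        cur <- character(0)
        target <- sample(2:6, 1)
        for (u in shuffled) {
          uclg <- sub("\\|.*", "", u)
          cur_clgs <- sub("\\|.*", "", cur)
          if (length(cur) >= target || uclg %in% cur_clgs) {
            if (length(cur)) groups[[length(groups) + 1L]] <- cur
            cur <- u
            target <- sample(2:6, 1)
          } else cur <- c(cur, u)
        }
        if (length(cur)) groups[[length(groups) + 1L]] <- cur
        ## merge singleton groups into any compatible chromosome (distinct
        ## CLGs, at most 6 units) so fusions stay in the 2-6 range
        repeat {
          singles <- which(lengths(groups) == 1L)
          if (!length(singles) || length(groups) == 1L) break
          moved <- FALSE
          for (si in singles) {
            uclg <- sub("\\|.*", "", groups[[si]])
            for (gi in setdiff(seq_along(groups), si)) {
              if (length(groups[[gi]]) < 6L &&
                  !uclg %in% sub("\\|.*", "", groups[[gi]])) {
                groups[[gi]] <- c(groups[[gi]], groups[[si]])
                groups[si] <- NULL
                moved <- TRUE
                break
              }
            }
            if (moved) break
          }
          if (!moved) break
        }
        plan <- setNames(groups, sprintf("%s_chr%02d", sp, seq_along(groups)))
      }
      if (is.null(plan)) {
        plan <- setNames(as.list(sp_units),
                         sprintf("%s_chr%02d", sp, seq_along(sp_units)))
      }
      unknown <- setdiff(unlist(plan), sp_units)
      if (length(unknown))
        stop("fusion plan references unknown units for ", sp, ": ",
             paste(unknown, collapse = ", "))
      unplanned <- setdiff(sp_units, unlist(plan))
      if (length(unplanned)) {
        extra <- setNames(as.list(unplanned),
                          sprintf("%s_chr%02d", sp,
                                  length(plan) + seq_along(unplanned)))
        plan <- c(plan, extra)
      }
      plan_out[[sp]] <- plan
      for (chr in names(plan)) {
        us <- plan[[chr]]
        units_rows[[length(units_rows) + 1L]] <- data.frame(
          species = sp, chromosome = chr,
          clg = sub("\\|.*", "", us), segment = sub(".*\\|", "", us),
          stringsAsFactors = FALSE)
        genes <- gsp$gene_id[gsp$unit %in% us]
        genes <- sample(genes)
        if (!length(genes)) next
        map_rows[[length(map_rows) + 1L]] <- data.frame(
          gene_id = genes, species = sp, chromosome = chr,
          start = (seq_along(genes) - 1L) * 1000L,
          end = (seq_along(genes) - 1L) * 1000L + 900L,
          family_id = gsp$family_id[match(genes, gsp$gene_id)],
          stringsAsFactors = FALSE)
      }
    }
    structure(list(gene_map = do.call(rbind, map_rows),
                   units = do.call(rbind, units_rows),
                   fusion_plan = plan_out),
              class = "karyotype_sim")
  })
}
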