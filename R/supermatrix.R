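## Paralogon classification, strict/relaxed family selection and per-CLG
## concatenated supermatrices keyed by (species, paralogon segment).

GNATHOSTOME_PARALOGONS <- c("alpha1", "alpha2", "beta1", "beta2")

## 1R copy of a gnathostome paralogon label: alpha1/beta1 -> 1R_1,
## alpha2/beta2 -> 1R_2.
paralogon_1r_copy <- function(label) {
  ifelse(label %in% c("alpha1", "beta1"), "1R_1",
         ifelse(label %in% c("alpha2", "beta2"), "1R_2", NA_character_))
}

#' Classify family members into paralogons
#'
#' Labels every gene by lookup of its chromosome segment in a reference
#' table (for gnathostomes a paralogon among alpha1/alpha2/beta1/beta2;
#' for cyclostomes the chromosome/segment id of the CLG derivative; for
#' outgroups \code{"out"}). Genes whose chromosome is absent from the
#' reference are labeled \code{"unplaced"} (a value, not an error).
#'
#' @param genes data.frame with columns gene_id, species, clg and
#'   chromosome (merge a simulated truth table with a gene map, or supply
#'   real annotations).
#' @param reference data.frame with columns species, chromosome, clg,
#'   paralogon.
#' @return The input with a \code{paralogon} column.
#' @export
classify_paralogons <- function(genes, reference) {
  key <- function(df) paste(df$species, df$chromosome, df$clg, sep = "\r")
  lab <- reference$paralogon[match(key(genes), key(reference))]
  genes$paralogon <- ifelse(is.na(lab), "unplaced", lab)
  genes
}

#' Strict/relaxed gene-family selection
#'
#' Keeps families that include derivatives of both 1R paralogons in
#' gnathostomes and, among the gnathostome paralogon labels
#' alpha1/alpha2/beta1/beta2, at least three distinct labels (strict) or at
#' least two (relaxed). Strict selection is always a subset of relaxed.
#'
#' @param families Named list; each element has a \code{genes} data.frame
#'   carrying \code{paralogon} labels (see
#'   \code{\link{classify_paralogons}}).
#' @param mode \code{"strict"} or \code{"relaxed"}.
#' @return The retained subset of \code{families}.
#' @export
select_families <- function(families, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  need <- if (mode == "strict") 3L else 2L
  keep <- vapply(families, function(f) {
    g <- f$genes
    labs <- unique(g$paralogon[g$paralogon %in% GNATHOSTOME_PARALOGONS])
    copies <- unique(paralogon_1r_copy(labs))
    length(labs) >= need && all(c("1R_1", "1R_2") %in% copies)
  }, logical(1))
  families[keep]
}

#' Build a per-CLG concatenated supermatrix
#'
#' One row per observed (species, segment key): the gnathostome paralogon
#' identity, the chromosomal identity of the CLG derivative in cyclostomes,
#' or the outgroup key, whose chromosomally linked genes provide the
#' outgroup row. Each family contributes exactly one sequence (or an
#' all-gap block) per row; when a species has several genes of one family
#' on the same segment, the longest ungapped sequence is kept (ties by gene
#' id). Rows with occupancy below \code{min_occupancy} are dropped with a
#' warning.
#'
#' @param families List of family objects (with \code{genes} carrying
#'   \code{paralogon} labels and \code{alignment} keyed by gene id), all
#'   assigned to one CLG.
#' @param min_occupancy Minimum fraction of non-gap columns per row
#'   (default 0.2).
#' @return List of class \code{"supermatrix"}: \code{alignment} (character
#'   matrix, rows named \code{"species|segment"}), \code{partition}
#'   (data.frame family_id, start, end, 0-based half-open), \code{rows}
#'   (species, segment, occupancy).
#' @export
build_supermatrix <- function(families, min_occupancy = 0.2) {
  if (!length(families)) stop("no families supplied")
  clgs <- unique(vapply(families, `[[`, character(1), "clg"))
  if (length(clgs) != 1) stop("families span several CLGs: ",
                              paste(clgs, collapse = ", "))
  keys <- unique(do.call(rbind, lapply(families, function(f) {
    g <- f$genes[f$genes$paralogon != "unplaced", , drop = FALSE]
    unique(data.frame(species = g$species, segment = g$paralogon,
                      stringsAsFactors = FALSE))
  })))
  keys <- keys[order(keys$species, keys$segment), , drop = FALSE]
  rowkey <- paste(keys$species, keys$segment, sep = "|")
  lens <- vapply(families, function(f) ncol(f$alignment), integer(1))
  total <- sum(lens)
  aln <- matrix("-", nrow(keys), total, dimnames = list(rowkey, NULL))
  part <- data.frame(family_id = vapply(families, `[[`, character(1), "family_id"),
                     start = cumsum(c(0L, lens[-length(lens)])),
                     end = cumsum(lens), stringsAsFactors = FALSE)
  for (i in seq_along(families)) {
    f <- families[[i]]
    g <- f$genes[f$genes$paralogon != "unplaced", , drop = FALSE]
    gkey <- paste(g$species, g$paralogon, sep = "|")
    for (rk in unique(gkey)) {
      cand <- g$gene_id[gkey == rk]
      if (length(cand) > 1L) {
        ## tandem duplicates: keep the sequence with most non-gap sites,
        ## ties by lexicographic gene id
        occ <- vapply(cand, function(id)
          sum(!f$alignment[id, ] %in% GAP_CHARS), integer(1))
        cand <- cand[order(-occ, cand)][1]
      }
      aln[rk, (part$start[i] + 1L):part$end[i]] <- f$alignment[cand, ]
    }
  }
  occupancy <- rowMeans(!matrix(aln %in% GAP_CHARS, nrow(aln)))
  drop <- occupancy < min_occupancy
  if (any(drop)) {
    warning("dropping ", sum(drop), " row(s) with occupancy < ",
            min_occupancy, ": ", paste(rowkey[drop], collapse = ", "))
    aln <- aln[!drop, , drop = FALSE]
    keys <- keys[!drop, , drop = FALSE]
    occupancy <- occupancy[!drop]
  }
  structure(list(alignment = aln, partition = part,
                 rows = data.frame(keys, occupancy = occupancy,
                                   row.names = NULL)),
            class = "supermatrix")
}

#' Deconcatenate a supermatrix by its partition map
#'
#' @param sm A \code{supermatrix}.
#' @return Named list of per-family character matrices.
#' @export
split_supermatrix <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  out <- lapply(seq_len(nrow(sm$partition)), function(i)
    sm$alignment[, (sm$partition$start[i] + 1L):sm$partition$end[i],
                 drop = FALSE])
  names(out) <- sm$partition$family_id
  out
}

## Truth-derived paralogon reference for a simulated karyotype: maps each
## (species, chromosome, clg) unit to its segment key; gnathostome segments
## are already paralogon labels (alpha1..beta2 -> as-is), cyclostome
## segments keep the chromosome-derived segment id, outgroup units are
## "out".
#' Paralogon reference table from a simulated karyotype
#'
#' The analogue of the prior vertebrate paralogon classification the real
#' analysis relies on: every chromosome (unit) is assigned the paralogon /
#' segment key of the ancestral unit it derives from.
#'
#' @param karyotype A \code{karyotype_sim}.
#' @return data.frame species, chromosome, clg, paralogon.
#' @export
paralogon_reference <- function(karyotype) {
  u <- karyotype$units
  data.frame(species = u$species, chromosome = u$chromosome, clg = u$clg,
             paralogon = u$segment, stringsAsFactors = FALSE)
}
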