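## Orthology by mutual best hit and chromosome-scale synteny tests.

#' Proteome similarity search
#'
#' Ranks candidate homologs by shared k-word count, followed by ungapped
#' identity rescoring of the best candidates (adequate for indel-free
#' sequences; pluggable for real data). Queries sharing no k-word with any
#' target are absent from the table; empty sequences are skipped with a
#' warning.
#'
#' @param proteomeA,proteomeB Named character vectors of protein sequences
#'   (or \code{AAStringSet}).
#' @param k Word size (default 4).
#' @param min_shared Minimum shared k-words to report a candidate pair.
#' @param rescore Rescore candidate pairs of equal length by ungapped
#'   identity (default TRUE).
#' @param max_candidates Candidates per query retained for rescoring.
#' @return data.frame of class \code{"hit_table"}: query, target, score
#'   (higher is more similar).
#' @export
similarity_search <- function(proteomeA, proteomeB, k = 4L, min_shared = 3L,
                              rescore = TRUE, max_candidates = 5L) {
  pA <- if (inherits(proteomeA, "AAStringSet")) as.character(proteomeA) else proteomeA
  pB <- if (inherits(proteomeB, "AAStringSet")) as.character(proteomeB) else proteomeB
  stopifnot(length(pA) > 0, length(pB) > 0,
            !is.null(names(pA)), !is.null(names(pB)))
  drop_empty <- function(p, label) {
    empty <- !nzchar(p) | nchar(p) < k
    if (any(empty)) {
      warning(sum(empty), " empty/short sequence(s) skipped in ", label)
      p <- p[!empty]
    }
    p
  }
  pA <- drop_empty(pA, "proteomeA")
  pB <- drop_empty(pB, "proteomeB")
  kmers <- function(p) {
    data.table::rbindlist(lapply(names(p), function(g) {
      s <- p[[g]]
      n <- nchar(s) - k + 1L
      data.table::data.table(gene = g,
                             kmer = unique(substring(s, 1:n, k:(n + k - 1L))))
    }))
  }
  ka <- kmers(pA); kb <- kmers(pB)
  data.table::setkey(ka, kmer); data.table::setkey(kb, kmer)
  j <- merge(ka, kb, by = "kmer", allow.cartesian = TRUE,
             suffixes = c(".q", ".t"))
  if (!nrow(j))
    return(structure(data.frame(query = character(0), target = character(0),
                                score = numeric(0)),
                     class = c("hit_table", "data.frame")))
  cnt <- j[, list(shared = .N), by = list(query = gene.q, target = gene.t)]
  cnt <- cnt[cnt$shared >= min_shared, ]
  data.table::setorder(cnt, query, -shared, target)
  cnt <- cnt[, utils::head(.SD, max_candidates), by = query]
  cnt <- as.data.frame(cnt)
  if (rescore) {
    qa <- pA[cnt$query]; tb <- pB[cnt$target]
    same_len <- nchar(qa) == nchar(tb)
    ident <- rep(NA_real_, nrow(cnt))
    for (i in which(same_len)) {
      x <- strsplit(qa[i], "")[[1]]; y <- strsplit(tb[i], "")[[1]]
      ident[i] <- mean(x == y)
    }
    ## identity (scaled) dominates; shared-k-word count breaks unrescorable
    cnt$score <- ifelse(is.na(ident), cnt$shared / 1e6,
                        ident + cnt$shared / 1e9)
  } else cnt$score <- cnt$shared
  out <- cnt[, c("query", "target", "score")]
  out <- out[is.finite(out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Mutual best hits
#'
#' A pair (a, b) is kept iff b is a's unique top hit in A-vs-B and a is b's
#' unique top hit in B-vs-A. Score ties are broken by lexicographic gene id,
#' making the result deterministic; MBH is a partial matching, so each gene
#' appears in at most one pair.
#'
#' @param hits_AB,hits_BA \code{hit_table}s from the two search directions.
#' @return data.frame of class \code{"ortholog_pairs"}: geneA, geneB, score.
#' @export
mutual_best_hits <- function(hits_AB, hits_BA) {
  top <- function(h) {
    if (!nrow(h)) return(h)
    h <- h[order(h$query, -h$score, h$target), , drop = FALSE]
    h[!duplicated(h$query), , drop = FALSE]
  }
  ta <- top(hits_AB); tb <- top(hits_BA)
  ba <- setNames(tb$target, tb$query)
  keep <- !is.na(ba[ta$target]) & ba[ta$target] == ta$query
  keep[is.na(keep)] <- FALSE
  out <- data.frame(geneA = ta$query[keep], geneB = ta$target[keep],
                    score = ta$score[keep], stringsAsFactors = FALSE)
  out <- out[order(out$geneA), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_pairs", "data.frame")
  out
}

#' Chromosome-versus-chromosome orthologue enrichment
#'
#' For every chromosome pair, the 2x2 table (on/off chrA x on/off chrB over
#' all ortholog pairs) is tested one-sided for enrichment with Fisher's
#' exact test (hypergeometric tail), adjusted by Benjamini-Hochberg across
#' all chromosome pairs; pairs with adjusted p below \code{alpha} are
#' flagged significant.
#'
#' @param pairs \code{ortholog_pairs}.
#' @param mapA,mapB data.frames with columns gene_id, chromosome for the two
#'   species.
#' @param alpha Significance level for the adjusted p (default 0.05).
#' @return data.frame of class \code{"enrichment_matrix"}: chromA, chromB,
#'   n_shared, nA, nB, n_total, p, p_adj, significant.
#' @export
chromosome_association_test <- function(pairs, mapA, mapB, alpha = 0.05) {
  chrA <- mapA$chromosome[match(pairs$geneA, mapA$gene_id)]
  chrB <- mapB$chromosome[match(pairs$geneB, mapB$gene_id)]
  bad <- c(pairs$geneA[is.na(chrA)], pairs$geneB[is.na(chrB)])
  if (length(bad))
    stop("genes without a chromosome assignment: ",
         paste(utils::head(bad, 10), collapse = ", "))
  N <- nrow(pairs)
  tab <- table(chrA, chrB)
  nA <- rowSums(tab); nB <- colSums(tab)
  grid <- expand.grid(chromA = rownames(tab), chromB = colnames(tab),
                      stringsAsFactors = FALSE)
  x <- tab[cbind(grid$chromA, grid$chromB)]
  mA <- nA[grid$chromA]; mB <- nB[grid$chromB]
  ## one-sided Fisher p = upper hypergeometric tail
  p <- stats::phyper(x - 1, mA, N - mA, mB, lower.tail = FALSE)
  out <- data.frame(chromA = grid$chromA, chromB = grid$chromB,
                    n_shared = as.vector(x), nA = as.vector(mA),
                    nB = as.vector(mB), n_total = N,
                    p = as.vector(p), stringsAsFactors = FALSE)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$chromA, out$chromB), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_matrix", "data.frame")
  out
}

#' Transfer CLG labels through ortholog pairs
#'
#' @param pairs \code{ortholog_pairs} with the focal species as
#'   \code{geneA} and the reference species as \code{geneB}.
#' @param reference data.frame gene_id, clg for the reference species.
#' @return data.frame gene_id, clg for the focal species (labeled genes
#'   only).
#' @export
transfer_clg_labels <- function(pairs, reference) {
  clg <- reference$clg[match(pairs$geneB, reference$gene_id)]
  out <- data.frame(gene_id = pairs$geneA, clg = clg,
                    stringsAsFactors = FALSE)
  out[!is.na(out$clg), , drop = FALSE]
}

#' CLG composition of chromosomes in 20-gene bins
#'
#' Tests each chromosome x CLG combination for enrichment of CLG-labeled
#' genes (one-sided Fisher, BH-adjusted across combinations), then
#' partitions each chromosome into consecutive bins of \code{bin_size}
#' genes and counts genes per significantly enriched CLG per bin; genes of
#' non-enriched CLGs are zeroed. The final partial bin is retained and
#' labeled by its actual size.
#'
#' @param gene_map data.frame gene_id, chromosome, start for one species.
#' @param clg_labels data.frame gene_id, clg (e.g. from
#'   \code{\link{transfer_clg_labels}}).
#' @param bin_size Genes per bin (default 20).
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return List of class \code{"clg_assignment"}: \code{chromosome_calls}
#'   (chromosome, clgs (comma-joined), unassigned flag), \code{bins}
#'   (chromosome, bin, n_genes, clg, count) and \code{enrichment} (the
#'   chromosome x CLG test table).
#' @export
assign_clgs <- function(gene_map, clg_labels, bin_size = 20L, alpha = 0.05) {
  stopifnot(bin_size >= 1)
  lab <- clg_labels$clg[match(gene_map$gene_id, clg_labels$gene_id)]
  N <- sum(!is.na(lab))
  if (N == 0) stop("no mapped gene carries a CLG label")
  chroms <- unique(gene_map$chromosome)
  clgs <- sort(unique(lab[!is.na(lab)]))
  onchr <- table(factor(gene_map$chromosome[!is.na(lab)], levels = chroms),
                 factor(lab[!is.na(lab)], levels = clgs))
  grid <- expand.grid(chromosome = chroms, clg = clgs,
                      stringsAsFactors = FALSE)
  x <- onchr[cbind(grid$chromosome, grid$clg)]
  mC <- rowSums(onchr)[grid$chromosome]
  mL <- colSums(onchr)[grid$clg]
  p <- stats::phyper(x - 1, mL, N - mL, mC, lower.tail = FALSE)
  enr <- data.frame(grid, n = as.vector(x), p = as.vector(p),
                    stringsAsFactors = FALSE)
  enr$p_adj <- stats::p.adjust(enr$p, method = "BH")
  enr$significant <- enr$p_adj < alpha & enr$n > 0
  calls <- list(); bins <- list()
  for (ch in chroms) {
    sub <- gene_map[gene_map$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    sublab <- clg_labels$clg[match(sub$gene_id, clg_labels$gene_id)]
    sig <- enr$clg[enr$chromosome == ch & enr$significant]
    if (!any(!is.na(sublab))) {
      calls[[ch]] <- data.frame(chromosome = ch, clgs = "",
                                unassigned = TRUE, stringsAsFactors = FALSE)
      next
    }
    calls[[ch]] <- data.frame(chromosome = ch,
                              clgs = paste(sort(sig), collapse = ","),
                              unassigned = length(sig) == 0,
                              stringsAsFactors = FALSE)
    if (nrow(sub)) {
      binid <- (seq_len(nrow(sub)) - 1L) %/% bin_size
      for (b in unique(binid)) {
        inb <- sublab[binid == b]
        cnt <- table(factor(inb[inb %in% sig], levels = sort(sig)))
        if (length(cnt)) {
          bins[[length(bins) + 1L]] <- data.frame(
            chromosome = ch, bin = b, n_genes = sum(binid == b),
            clg = names(cnt), count = as.vector(cnt),
            stringsAsFactors = FALSE)
        } else {
          bins[[length(bins) + 1L]] <- data.frame(
            chromosome = ch, bin = b, n_genes = sum(binid == b),
            clg = NA_character_, count = 0L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(chromosome_calls = do.call(rbind, c(calls, list(make.row.names = FALSE))),
                 bins = do.call(rbind, bins),
                 enrichment = enr),
            class = "clg_assignment")
}
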