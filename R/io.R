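## Readers/writers shared across stages. FASTA goes through Biostrings,
## bedGraph through rtracklayer/GenomicRanges, tables are plain TSV and the
## truth log / manifests are JSON.

.need <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("package '", pkg, "' is required for this reader/writer")
}

#' Write / read proteome FASTA
#'
#' @param sequences Named character vector of protein sequences.
#' @param file Path.
#' @return \code{read_fasta} returns a named character vector.
#' @export
write_fasta <- function(sequences, file) {
  .need("Biostrings")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), file)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  .need("Biostrings")
  x <- Biostrings::readAAStringSet(file)
  setNames(as.character(x), names(x))
}

#' Write / read a tab-separated table
#'
#' @param df data.frame.
#' @param file Path.
#' @export
write_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(file) {
  utils::read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write / read a depth track as bedGraph
#'
#' Runs of equal depth are emitted as 0-based half-open bedGraph records.
#'
#' @param track A \code{\link{depth_track}}.
#' @param file Path.
#' @export
write_bedgraph <- function(track, file) {
  .need("rtracklayer"); .need("GenomicRanges")
  runs <- do.call(rbind, lapply(names(track$contigs), function(ct) {
    r <- rle(track$contigs[[ct]])
    ends <- cumsum(r$lengths)
    data.frame(contig = ct, start = c(1L, utils::head(ends, -1) + 1L),
               end = ends, score = r$values, stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(runs$contig,
                               IRanges::IRanges(runs$start, runs$end),
                               score = runs$score)
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' @rdname write_bedgraph
#' @param sample Sample label for the reconstructed track.
#' @param contig_lengths Optional named lengths (defaults to the largest
#'   end coordinate seen per contig).
#' @export
read_bedgraph <- function(file, sample = "sample", contig_lengths = NULL) {
  .need("rtracklayer")
  gr <- rtracklayer::import(file, format = "bedGraph")
  contigs <- list()
  ct_all <- as.character(GenomicRanges::seqnames(gr))
  for (ct in unique(ct_all)) {
    sub <- gr[ct_all == ct]
    len <- if (!is.null(contig_lengths)) contig_lengths[[ct]]
    else max(GenomicRanges::end(sub))
    v <- integer(len)
    st <- GenomicRanges::start(sub); en <- GenomicRanges::end(sub)
    sc <- as.integer(round(S4Vectors::mcols(sub)$score))
    for (i in seq_along(sub)) v[st[i]:en[i]] <- sc[i]
    contigs[[ct]] <- v
  }
  depth_track(contigs, sample)
}

#' Write a gene tree in Newick with node annotations
#'
#' Node events and ages are embedded as NHX-style comments
#' (\code{[&&NHX:event=1R:age=527]}).
#'
#' @param gene_tree A \code{gene_tree}.
#' @param file Path.
#' @export
write_annotated_newick <- function(gene_tree, file) {
  phy <- gene_tree$phy
  ntip <- length(phy$tip.label)
  lab <- vapply((ntip + 1L):(ntip + phy$Nnode), function(v)
    sprintf("[&&NHX:event=%s:age=%g]", gene_tree$events[v],
            gene_tree$ages[v]), character(1))
  phy$node.label <- lab
  writeLines(ape::write.tree(phy), file)
  invisible(file)
}

#' Write a truth log as JSON
#'
#' @param truth A list (gene table, planted regions, units, scenario
#'   parameters, ...).
#' @param file Path.
#' @export
write_truth_log <- function(truth, file) {
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", force = TRUE)
  invisible(file)
}
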