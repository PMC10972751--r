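Package: paralogon
Title: Synteny-Based Inference of Ancient Whole-Genome Duplications and
    Germline-Specific DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the polyploid history of early vertebrate
    genomes from chromosome-scale data and to detect programmed DNA
    elimination from sequencing depth. Implements mutual-best-hit orthology
    with Fisher exact tests of chromosome-versus-chromosome orthologue
    enrichment, assignment of chromosomes to chordate linkage groups,
    classification of gene-family members into paralogons, per-linkage-group
    concatenated supermatrices, a maximum-likelihood phylogenetic core
    (Felsenstein pruning, maximum-likelihood distances, neighbor joining,
    branch-length optimization, bootstrap, RELL-based topology tests and
    strict-clock least-squares dating), likelihood tests of ancestral versus
    lineage-specific rediploidization, mixture summaries of paralogon
    divergence times, and a DifCover-style germline-versus-soma coverage
    scan with binary segmentation. A genome-evolution simulator generates
    gene families, proteomes, karyotypes and paired depth tracks from a
    scripted history of auto-, allo- and hexaploidization with a
    machine-readable truth log, so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    Biostrings,
    GenomicRanges,
    IRanges,
    optparse,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
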