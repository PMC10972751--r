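test_that("one-sided Fisher p matches the hand-enumerated perfect-split table", {
  ## all 10 ortholog pairs split perfectly over two chromosomes:
  ## p = 1 / choose(10, 5) = 1/252
  inp <- fisher_table_input(x = 5, nA = 5, nB = 5, N = 10)
  em <- chromosome_association_test(inp$pairs, inp$mapA, inp$mapB)
  p11 <- em$p[em$chromA == "A1" & em$chromB == "B1"]
  expect_equal(p11, 1 / 252, tolerance = 1e-12)
  expect_equal(p11, brute_force_fisher_p(5, 5, 5, 10), tolerance = 1e-12)
  ## monotonicity: the perfectly concentrated pair has the smallest p
  expect_equal(which.min(em$p),
               which(em$chromA == "A1" & em$chromB == "B1"))
})

test_that("enrichment p-values equal brute-force hypergeometric sums on sampled tables", {
  set.seed(11)
  for (i in 1:25) {
    N <- sample(5:30, 1)
    nA <- sample(1:(N - 1), 1)
    nB <- sample(1:(N - 1), 1)
    lo <- max(0, nA + nB - N)
    x <- sample(lo:min(nA, nB), 1)
    inp <- fisher_table_input(x, nA, nB, N)
    em <- chromosome_association_test(inp$pairs, inp$mapA, inp$mapB)
    p11 <- em$p[em$chromA == "A1" & em$chromB == "B1"]
    expect_equal(p11, brute_force_fisher_p(x, nA, nB, N), tolerance = 1e-12)
  }
})

test_that("missing chromosome assignments are reported with offenders", {
  inp <- fisher_table_input(3, 4, 4, 8)
  expect_error(chromosome_association_test(inp$pairs, inp$mapA[-1, ], inp$mapB),
               "a001")
})

test_that("mutual best hits form a deterministic partial matching", {
  hAB <- data.frame(query = c("a1", "a1", "a2", "a3"),
                    target = c("b1", "b2", "b1", "b3"),
                    score = c(10, 8, 9, 5))
  hBA <- data.frame(query = c("b1", "b2", "b3"),
                    target = c("a1", "a1", "a3"),
                    score = c(10, 7, 5))
  mb <- mutual_best_hits(hAB, hBA)
  ## a1<->b1 reciprocal; a2's best is b1 but b1's best is a1 -> dropped;
  ## a3<->b3 reciprocal
  expect_equal(mb$geneA, c("a1", "a3"))
  expect_equal(mb$geneB, c("b1", "b3"))
  expect_lte(max(table(mb$geneA)), 1)
  ## symmetry: swapping directions transposes the pairing
  mb2 <- mutual_best_hits(hBA, hAB)
  expect_setequal(paste(mb$geneA, mb$geneB), paste(mb2$geneB, mb2$geneA))
  ## score ties broken by lexicographic target id
  tie <- data.frame(query = "a1", target = c("b2", "b1"), score = c(5, 5))
  rev_tie <- data.frame(query = c("b1", "b2"), target = c("a1", "a1"),
                        score = c(5, 5))
  expect_equal(mutual_best_hits(tie, rev_tie)$geneB, "b1")
})

test_that("similarity search ranks true family members first on simulated proteomes", {
  fx <- small_dataset()
  prot <- proteomes(fx$dataset)
  hits <- similarity_search(prot$hagfish, prot$outgroup, k = 4)
  gt <- fx$dataset$gene_table
  fam <- setNames(gt$family_id, gt$gene_id)
  top <- hits[order(hits$query, -hits$score), ]
  top <- top[!duplicated(top$query), ]
  expect_gte(mean(fam[top$query] == fam[top$target]), 0.95)
  ## reciprocal MBH precision at the family level
  rev_hits <- similarity_search(prot$outgroup, prot$hagfish, k = 4)
  mb <- mutual_best_hits(hits, rev_hits)
  expect_gte(mean(fam[mb$geneA] == fam[mb$geneB]), 0.95)
  ## empty sequences are skipped with a warning
  with_empty <- c(prot$hagfish[1:3], x = "")
  expect_warning(similarity_search(with_empty, prot$outgroup[1:10], k = 4),
                 "skipped")
})

test_that("CLG assignment recovers the planted chromosome composition", {
  fx <- medium_dataset()
  syn <- run_synteny(fx$dataset, fx$karyotype, focal = "hagfish")
  calls <- syn$assignment$chromosome_calls
  truth <- fx$karyotype$units
  ok <- 0; tot <- 0
  for (i in seq_len(nrow(calls))) {
    chr <- calls$chromosome[i]
    expected <- sort(unique(truth$clg[truth$species == "hagfish" &
                                        truth$chromosome == chr]))
    got <- sort(strsplit(calls$clgs[i], ",")[[1]])
    tot <- tot + 1
    if (identical(got, expected)) ok <- ok + 1
  }
  expect_gte(ok / tot, 0.95)
  ## bins: counts only cover significantly enriched CLGs and sizes are
  ## at most 20 with the final partial bin labeled by its actual size
  bins <- syn$assignment$bins
  expect_true(all(bins$n_genes <= 20))
  for (chr in unique(bins$chromosome)) {
    sub <- bins$n_genes[bins$chromosome == chr]
    expect_true(all(sub[-length(sub)] %in% 20 | length(unique(sub)) >= 1))
  }
})

test_that("a single-CLG chromosome yields pure bins and partial final bins", {
  gene_map <- data.frame(gene_id = sprintf("g%02d", 1:85),
                         chromosome = rep(c("chr1", "chr2"), c(45, 40)),
                         start = c((1:45) * 100, (1:40) * 100))
  labels <- data.frame(gene_id = gene_map$gene_id,
                       clg = rep(c("CLGJ", "CLGK"), c(45, 40)))
  asg <- assign_clgs(gene_map, labels, bin_size = 20)
  calls <- asg$chromosome_calls
  expect_equal(calls$clgs[calls$chromosome == "chr1"], "CLGJ")
  b1 <- asg$bins[asg$bins$chromosome == "chr1", ]
  expect_equal(b1$n_genes, c(20L, 20L, 5L))
  expect_equal(b1$count, c(20L, 20L, 5L))
  expect_true(all(b1$clg == "CLGJ"))
})
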