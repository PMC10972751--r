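lin <- c(outgroup = "outgroup", hagfish = "cyclostome", lamprey = "cyclostome",
         gar = "gnathostome", frog = "gnathostome")

redip_family <- function(labels, id = "fx") {
  species <- names(labels)
  genes <- data.frame(gene_id = sprintf("%s_%s_%s", id, species, unname(labels)),
                      family_id = id, species = species, clg = "CLGT",
                      paralogon = unname(labels), stringsAsFactors = FALSE)
  list(family_id = id, clg = "CLGT", genes = genes)
}

test_that("species-overlap labeling distinguishes the two rediploidization patterns", {
  ## ancestral pattern: genes group by duplicated copy; the root-adjacent
  ## duplication has both lineages on both sides (1R)
  anc <- ape::read.tree(text = paste0(
    "(outgroup|out:6,((gar|alpha1:5,hagfish|c1a:5):1,",
    "(gar|alpha2:5,hagfish|c2a:5):1):1);"))
  r <- classify_nodes(anc, lin)
  expect_true(any(r$event == "1R"))
  expect_true(has_presplit_1r(r))
  ## lineage-specific pattern: genes group by lineage; no shared 1R node,
  ## instead gnathostome-only and cyclostome-only duplications
  ls <- ape::read.tree(text = paste0(
    "(outgroup|out:6,((gar|alpha1:5,gar|alpha2:5):1,",
    "(hagfish|h1:5,hagfish|h2:5):1):1);"))
  r2 <- classify_nodes(ls, lin)
  expect_false(any(r2$event == "1R"))
  expect_true(any(r2$event == "2R_JV"))
  expect_true(any(r2$event == "2R_CY"))
  ## unrooted input is rejected
  expect_error(classify_nodes(ape::unroot(anc), lin), "rooted")
})

test_that("family selection applies criteria i-iv", {
  keep <- redip_family(c(gar = "alpha1", gar = "alpha2", hagfish = "c1a",
                         lamprey = "c1a", outgroup = "out"))
  no_both <- redip_family(c(gar = "alpha1", frog = "beta1", hagfish = "c1a",
                            lamprey = "c1a", outgroup = "out"))
  no_lam <- redip_family(c(gar = "alpha1", gar = "alpha2", hagfish = "c1a",
                           outgroup = "out"))
  no_out <- redip_family(c(gar = "alpha1", gar = "alpha2", hagfish = "c1a",
                           lamprey = "c1a"))
  fams <- list(keep = keep, no_both = no_both, no_lam = no_lam,
               no_out = no_out)
  sel <- select_redip_families(fams, lin)
  expect_setequal(names(sel), "keep")
  reasons <- attr(sel, "reasons")
  expect_equal(unname(reasons["no_both"]), "no_gnathostome_with_both_1R_copies")
  expect_equal(unname(reasons["no_lam"]), "missing_cyclostome")
  expect_equal(unname(reasons["no_out"]), "no_outgroup")
  ## criterion iv: too many ancestral topologies (5 unconstrained segment
  ## groups -> 2^5 = 32 > 10)
  many <- redip_family(c(gar = "alpha1", gar = "alpha2", outgroup = "out",
                         hagfish = "c1a", hagfish = "c1b", hagfish = "c2a",
                         lamprey = "c1c", lamprey = "c2b"))
  expect_equal(names(select_redip_families(list(m = many), lin)), character(0))
  expect_equal(unname(attr(select_redip_families(list(m = many), lin),
                           "reasons")["m"]), "too_many_topologies")
})

test_that("constrained enumeration matches brute-force counts", {
  ## 1 hagfish + 1 lamprey gene on orthologous segments: exactly 2
  ## ancestral topologies (joint placement on 1R_1 or 1R_2)
  f1 <- redip_family(c(gar = "alpha1", gar = "alpha2", hagfish = "c1a",
                       lamprey = "c1a", outgroup = "out"))
  cons <- list(c("hagfish|c1a", "lamprey|c1a"))
  anc <- enumerate_constrained_topologies(f1, "ancestral", lin, cons)
  expect_length(anc, 2L)
  ## no cyclostome genes: ancestral set empty, lineage-specific impossible
  f0 <- redip_family(c(gar = "alpha1", gar = "alpha2", outgroup = "out"))
  expect_length(enumerate_constrained_topologies(f0, "ancestral", lin), 0L)
  expect_error(enumerate_constrained_topologies(f0, "lineage_specific", lin),
               "uninformative")
  ## brute force: g unconstrained groups -> 2^g assignments; verify for
  ## families with up to 4 cyclostome genes on distinct segments
  for (g in 1:4) {
    labels <- c(gar = "alpha1", gar = "alpha2", outgroup = "out")
    segs <- paste0("c1", letters[seq_len(g)])
    cy <- setNames(segs, rep("hagfish", g))
    fg <- redip_family(c(labels, cy))
    expect_length(enumerate_constrained_topologies(fg, "ancestral", lin),
                  2^g)
  }
  ## all enumerated topologies are distinct and carry every gene
  anc4 <- enumerate_constrained_topologies(
    redip_family(c(gar = "alpha1", gar = "alpha2", outgroup = "out",
                   hagfish = "c1a", lamprey = "c1b")), "ancestral", lin)
  expect_length(anc4, 4L)
  expect_equal(anyDuplicated(unlist(anc4)), 0L)
  tips <- lapply(anc4, function(s) sort(ape::read.tree(text = s)$tip.label))
  expect_true(all(vapply(tips, length, integer(1)) == 5L))
})

test_that("balanced mode reproduces the paired two-grouping enumeration", {
  ## two hagfish and two lamprey segments, clades unlabeled: the two
  ## ancestral groupings are the two cross-species pairings
  f <- redip_family(c(gar = "alpha1", gar = "alpha2", outgroup = "out",
                      hagfish = "c1a", hagfish = "c1b",
                      lamprey = "c2a", lamprey = "c2b"))
  anc <- enumerate_constrained_topologies(f, "ancestral", lin,
                                          balanced = TRUE)
  expect_length(anc, 2L)
})

test_that("exclusion constraints prune same-clade assignments and detect contradictions", {
  f <- redip_family(c(gar = "alpha1", gar = "alpha2", outgroup = "out",
                      hagfish = "h1", hagfish = "h2",
                      lamprey = "l1", lamprey = "l2"))
  cons <- list(orthologs = list(c("hagfish|h1", "lamprey|l1"),
                                c("hagfish|h2", "lamprey|l2")),
               exclusions = list(c("hagfish|h1", "hagfish|h2")))
  anc <- enumerate_constrained_topologies(f, "ancestral", lin, cons)
  expect_length(anc, 2L)  # the two pairings; all-in-one-clade pruned
  contra <- list(orthologs = list(c("hagfish|h1", "hagfish|h2")),
                 exclusions = list(c("hagfish|h1", "hagfish|h2")))
  expect_error(enumerate_constrained_topologies(f, "ancestral", lin, contra),
               "contradictory")
})

test_that("per-family tests recover the generating rediploidization mode", {
  sc <- default_scenario(clg_count = 3)
  cons <- cyclostome_orthology_constraints(sc)
  run_one <- function(clg, seed) {
    for (s in seed + 0:20) {
      tr <- tryCatch(simulate_family_tree(sc, clg, seed = s),
                     error = function(e) NULL)
      if (is.null(tr)) next
      genes <- data.frame(gene_id = tr$tips$label, family_id = "f",
                          species = tr$tips$species, clg = clg,
                          paralogon = tr$tips$segment,
                          stringsAsFactors = FALSE)
      fam <- list(family_id = "f", clg = clg, genes = genes)
      sel <- select_redip_families(list(f = fam), setNames(
        sc$species$lineage, sc$species$species), cons[[clg]])
      if (!length(sel)) next
      aln <- evolve_sequences(tr, 2000, rate = sc$rate, seed = s)
      rownames(aln) <- tr$tips$label
      fam$alignment <- aln
      lineages <- setNames(sc$species$lineage, sc$species$species)
      return(test_family(fam, lineages, cons[[clg]], n_rell = 300, seed = s))
    }
    NULL
  }
  verdicts_anc <- Filter(Negate(is.null), lapply(c(1, 30, 60), run_one,
                                                 clg = "CLGA"))
  expect_gte(length(verdicts_anc), 2)
  va <- vapply(verdicts_anc, `[[`, character(1), "verdict")
  expect_gte(sum(va == "ancestral"), length(va) - 1)
  expect_false(any(va == "lineage_specific"))
  verdicts_ls <- Filter(Negate(is.null), lapply(c(1, 30, 60), run_one,
                                                clg = "CLGB"))
  vl <- vapply(verdicts_ls, `[[`, character(1), "verdict")
  expect_gte(sum(vl == "lineage_specific"), length(vl) - 1)
  expect_false(any(vl == "ancestral"))
})

test_that("degenerate alignments are inconclusive with a flag", {
  f <- redip_family(c(gar = "alpha1", gar = "alpha2", hagfish = "c1a",
                      lamprey = "c1a", outgroup = "out"))
  f$alignment <- matrix("A", nrow(f$genes), 10,
                        dimnames = list(f$genes$gene_id, NULL))
  v <- test_family(f, lin, list(c("hagfish|c1a", "lamprey|c1a")))
  expect_equal(v$verdict, "inconclusive")
  expect_true(v$degenerate)
})

test_that("verdict tallies conserve family counts", {
  vs <- list(
    structure(list(family_id = "a", clg = "CLGJ", verdict = "ancestral"),
              class = "redip_verdict"),
    structure(list(family_id = "b", clg = "CLGJ", verdict = "ancestral"),
              class = "redip_verdict"),
    structure(list(family_id = "c", clg = "CLGJ", verdict = "ancestral"),
              class = "redip_verdict"),
    structure(list(family_id = "d", clg = "CLGJ", verdict = "inconclusive"),
              class = "redip_verdict"),
    structure(list(family_id = "e", clg = "CLGK", verdict = "lineage_specific"),
              class = "redip_verdict"))
  tl <- tally_by_clg(vs)
  j <- tl[tl$clg == "CLGJ", ]
  expect_equal(c(j$ancestral, j$lineage_specific, j$inconclusive),
               c(3L, 0L, 1L))
  expect_equal(sum(tl$n_tested), length(vs))
})

test_that("the divergence-time mixture detects planted bimodality and respects limits", {
  expect_false(divergence_time_distribution(c(500, 510, 505))$fitted)
  same <- divergence_time_distribution(rep(500, 10))
  expect_equal(same$preferred, 1L)
  set.seed(21)
  ages <- c(rnorm(30, 511, 4), rnorm(30, 493, 4))
  fit <- divergence_time_distribution(ages)
  expect_equal(fit$preferred, 2L)
  expect_lt(abs(fit$means[["2"]][1] - 493), 10)
  expect_lt(abs(fit$means[["2"]][2] - 511), 10)
  ## unimodal input rarely prefers two components under BIC
  set.seed(22)
  pref2 <- vapply(1:10, function(i)
    divergence_time_distribution(rnorm(60, 500, 5))$preferred == 2L,
    logical(1))
  expect_lte(mean(pref2), 0.2)
})
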