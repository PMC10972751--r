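test_that("default scenario encodes the scripted event chronology", {
  sc <- default_scenario()
  expect_equal(speciation_age(sc, "cyclostome_gnathostome"), 520)
  expect_equal(speciation_age(sc, "hagfish_lamprey"), 457)
  expect_equal(unname(sc$redip_1R["CLGA"]), 527)
  expect_equal(sc$events[["2R_JV"]]$progenitor_divergences, 508)
  expect_equal(sc$events[["2R_CY"]]$progenitor_divergences, c(511, 493))
  expect_equal(sc$clg_count, 17L)
  expect_length(sc$clgs, 17L)
})

test_that("scenario and event invariants are enforced", {
  expect_error(default_scenario(clg_count = 0), "clg_count")
  expect_error(default_scenario(rate = 0), "rate")
  expect_error(wgd_event("allo_tetraploidy", "x", 500), "exactly one")
  expect_error(wgd_event("hexaploidy_two_step", "x", 490,
                         progenitor_divergences = c(493, 511)),
               "strictly decreasing")
  expect_error(wgd_event("auto_tetraploidy", "x", 530, retention = 0),
               "retention")
  ## allo merger cannot predate the progenitor divergence
  expect_error(wgd_event("allo_tetraploidy", "x", 510,
                         progenitor_divergences = 508), "predate")
})

test_that("family trees realize scheduled duplication ages exactly", {
  sc <- default_scenario(clg_count = 3)
  tr <- simulate_family_tree(sc, "CLGA", seed = 7)
  dup_ages <- tr$ages[tr$events %in% c("1R", "2R_JV", "2R_CY")]
  expect_true(all(dup_ages %in% c(527, 508, 511, 493)))
  ## the 1R node (if retained) predates the 520 Ma speciation
  ages_1r <- tr$ages[tr$events == "1R"]
  if (length(ages_1r)) expect_true(all(ages_1r > 520))
  ## conservation: emitted genes = surviving tips
  expect_equal(nrow(tr$tips), length(tr$phy$tip.label))
  ## ultrametric in Ma
  depths <- ape::node.depth.edgelength(tr$phy)
  tipd <- depths[seq_along(tr$phy$tip.label)]
  expect_true(max(tipd) - min(tipd) < 1e-9)
})

test_that("the designated CLG rediploidizes lineage-specifically in cyclostomes", {
  sc <- default_scenario(clg_count = 3)
  found <- FALSE
  for (seed in 1:12) {
    tr <- simulate_family_tree(sc, "CLGB", seed = seed)
    cy_dups <- tr$ages[tr$events == "1R"]
    cy_dups <- cy_dups[cy_dups < 457]
    if (length(cy_dups)) {
      found <- TRUE
      expect_true(all(cy_dups %in% c(431, 442)))
    }
  }
  expect_true(found)
})

test_that("family tree simulation is deterministic under a fixed seed", {
  sc <- default_scenario(clg_count = 3)
  t1 <- simulate_family_tree(sc, "CLGA", seed = 5)
  t2 <- simulate_family_tree(sc, "CLGA", seed = 5)
  expect_identical(t1$tips, t2$tips)
  expect_identical(ape::write.tree(t1$phy), ape::write.tree(t2$phy))
})

test_that("sequence evolution honors the zero-rate limit, determinism and the expected p-distance", {
  m <- poisson_model()
  sc <- default_scenario(clg_count = 3)
  tr <- simulate_family_tree(sc, "CLGA", seed = 3)
  a0 <- evolve_sequences(tr, length = 40, model = m, rate = 0, seed = 1)
  expect_true(all(apply(a0, 2, function(col) length(unique(col)) == 1)))
  a1 <- evolve_sequences(tr, length = 60, model = m, rate = 5e-4, seed = 9)
  a2 <- evolve_sequences(tr, length = 60, model = m, rate = 5e-4, seed = 9)
  expect_identical(a1, a2)
  ## closed-form expected proportion of differing sites at distance d
  two <- ape::read.tree(text = "(a:0.25,b:0.25);")
  L <- 10000
  aln <- evolve_sequences(two, length = L, model = m, rate = 1, seed = 11)
  p_obs <- mean(aln[1, ] != aln[2, ])
  d <- 0.5
  p_exp <- (19 / 20) * (1 - exp(-20 * d / 19))
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
  neg <- two; neg$edge.length[1] <- -0.1
  expect_error(evolve_sequences(neg, 10, m, 1, 1), "non-negative")
})

test_that("karyotype simulation fuses hagfish units and conserves gene content", {
  ## a full-width CLG complement so fusions can draw on 17 distinct CLGs
  sc17 <- default_scenario()
  d17 <- simulate_gene_families(sc17, n_families = 2, sites = 5, seed = 9)
  k17 <- simulate_karyotypes(d17, seed = 9)
  sizes17 <- table(k17$units$chromosome[k17$units$species == "hagfish"])
  expect_true(all(sizes17 >= 2 & sizes17 <= 6))
  fx <- small_dataset()
  k <- fx$karyotype
  hag_units <- k$units[k$units$species == "hagfish", ]
  sizes <- table(hag_units$chromosome)
  expect_true(all(sizes <= 6))
  ## fused units on one chromosome come from distinct CLGs
  for (chr in unique(hag_units$chromosome)) {
    cl <- hag_units$clg[hag_units$chromosome == chr]
    expect_equal(anyDuplicated(cl), 0L)
  }
  ## lamprey chromosomes each derive from a single unit
  lam_units <- k$units[k$units$species == "lamprey", ]
  expect_true(all(table(lam_units$chromosome) == 1))
  ## conservation: every emitted gene mapped exactly once
  expect_setequal(k$gene_map$gene_id, fx$dataset$gene_table$gene_id)
  expect_equal(anyDuplicated(k$gene_map$gene_id), 0L)
  ## chromosome membership respects the truth log
  gt <- fx$dataset$gene_table
  gm <- k$gene_map
  unit_of <- paste(gt$clg, gt$segment, sep = "|")[match(gm$gene_id, gt$gene_id)]
  key <- paste(gm$species, gm$chromosome)
  ukey <- paste(k$units$species, k$units$chromosome)
  for (i in sample(nrow(gm), 50)) {
    allowed <- paste(k$units$clg, k$units$segment, sep = "|")[ukey == key[i]]
    expect_true(unit_of[i] %in% allowed)
  }
})

test_that("explicit fusion plans are honored and unknown units rejected", {
  fx <- small_dataset()
  gt <- fx$dataset$gene_table
  hag_units <- sort(unique(paste(gt$clg, gt$segment, sep = "|")[gt$species == "hagfish"]))
  plan <- list(hagfish = list(hag_chrA = hag_units[1:3]))
  k <- simulate_karyotypes(fx$dataset, fusion_plan = plan, seed = 1)
  got <- k$units[k$units$species == "hagfish" & k$units$chromosome == "hag_chrA", ]
  expect_setequal(paste(got$clg, got$segment, sep = "|"), hag_units[1:3])
  bad <- list(hagfish = list(chr1 = c("CLGZ|nope")))
  expect_error(simulate_karyotypes(fx$dataset, fusion_plan = bad, seed = 1),
               "unknown units")
})

test_that("depth simulation plants exact regions in the noise-free limit", {
  regions <- data.frame(contig = "c1", start = 100L, end = 200L,
                        kind = "germline_specific", copy_ratio = 1,
                        stringsAsFactors = FALSE)
  sim <- simulate_depth_tracks(c(c1 = 1000L), regions, modal_germ = 32,
                               modal_soma = 54, noise = 0, seed = 1)
  expect_equal(sim$germ$contigs$c1[150], 32L)
  expect_equal(sim$soma$contigs$c1[150], 0L)
  expect_equal(sim$soma$contigs$c1[50], 54L)
  expect_equal(sim$truth$start, 100L)  # truth log round-trip
  ## overlapping regions of different kinds are rejected
  bad <- rbind(regions,
               data.frame(contig = "c1", start = 150L, end = 250L,
                          kind = "somatic", copy_ratio = 2))
  expect_error(simulate_depth_tracks(c(c1 = 1000L), bad, noise = 0, seed = 1),
               "overlapping")
  ## noisy modal depths sit at the configured modes (+/- 1)
  sim2 <- simulate_depth_tracks(c(c1 = 200000L), NULL, seed = 2)
  expect_lt(abs(modal_depth(sim2$germ) - 32), 2)
  expect_lt(abs(modal_depth(sim2$soma) - 54), 2)
})

test_that("k-mer histograms yield the documented abundance thresholds", {
  h24 <- simulate_kmer_histogram(24, abundant_fraction = 0.01, seed = 1)
  expect_equal(kmer_abundance_threshold(h24)$threshold, 72)
  h40 <- simulate_kmer_histogram(40, abundant_fraction = 0.01, seed = 1)
  expect_equal(kmer_abundance_threshold(h40)$threshold, 120)
  ## no heavy tail when abundant_fraction = 0
  h0 <- simulate_kmer_histogram(24, abundant_fraction = 0, seed = 3)
  expect_equal(sum(h0$n_kmers[h0$count >= 72]), 0L)
})
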