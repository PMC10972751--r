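test_that("modal depth takes the most frequent positive depth, ties to the smaller", {
  expect_equal(modal_depth(depth_track(list(c1 = c(5L, 5L, 5L, 9L)))), 5L)
  expect_equal(modal_depth(depth_track(list(c1 = c(7L, 7L, 8L, 8L, 1L)))), 7L)
  expect_error(modal_depth(depth_track(list(c1 = c(0L, 0L)))), "all-zero")
})

test_that("masking applies the dual low/high rules conjunctively", {
  ## modals 32/54: low iff germ < 32/3 and soma < 18; high iff > 96 and > 162
  germ <- depth_track(list(c1 = c(10L, 10L, 200L, 32L, 200L)))
  soma <- depth_track(list(c1 = c(17L, 54L, 300L, 54L, 100L)))
  mask <- mask_positions(germ, soma, scan_params(), modal_g = 32, modal_s = 54)
  expect_equal(mask$c1, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  ## absolute low rule for the higher-copy run
  p_abs <- scan_params(lo_mode = "absolute", lo_abs = 10, hi_multiple = 30)
  germ2 <- depth_track(list(c1 = c(9L, 9L, 11L)))
  soma2 <- depth_track(list(c1 = c(9L, 12L, 9L)))
  m2 <- mask_positions(germ2, soma2, p_abs, modal_g = 32, modal_s = 54)
  expect_equal(m2$c1, c(TRUE, FALSE, FALSE))
  ## mismatched contigs are rejected
  expect_error(mask_positions(germ, depth_track(list(c1 = c(1L, 2L))),
                              scan_params(), 32, 54), "differ")
})

test_that("masking is monotone in the modal estimates", {
  set.seed(4)
  germ <- depth_track(list(c1 = as.integer(rnbinom(5000, mu = 32, size = 50))))
  soma <- depth_track(list(c1 = as.integer(rnbinom(5000, mu = 54, size = 50))))
  m_lo <- mask_positions(germ, soma, scan_params(), modal_g = 28, modal_s = 48)
  m_hi <- mask_positions(germ, soma, scan_params(), modal_g = 36, modal_s = 60)
  low_rule <- function(g, s, mg, ms) (g < mg / 3) & (s < ms / 3)
  high_rule <- function(g, s, mg, ms) (g > 3 * mg) & (s > 3 * ms)
  g <- germ$contigs$c1; s <- soma$contigs$c1
  ## raising modals can only grow the low mask and shrink the high mask
  expect_true(all(!low_rule(g, s, 28, 48) | low_rule(g, s, 36, 60)))
  expect_true(all(!high_rule(g, s, 36, 60) | high_rule(g, s, 28, 48)))
  expect_true(identical(m_lo$c1,
                        low_rule(g, s, 28, 48) | high_rule(g, s, 28, 48)))
  expect_true(identical(m_hi$c1,
                        low_rule(g, s, 36, 60) | high_rule(g, s, 36, 60)))
})

test_that("interval construction spans masked gaps and conserves valid bases", {
  mask <- list(c1 = rep(FALSE, 1500))
  iv <- make_intervals(mask, v = 500)
  expect_equal(nrow(iv), 3L)
  expect_equal(iv$valid, rep(500L, 3))
  expect_equal(iv$start, c(0L, 500L, 1000L))
  ## 400 valid + 1000 masked + 100 valid: one interval spanning the gap
  mask2 <- list(c1 = c(rep(FALSE, 400), rep(TRUE, 1000), rep(FALSE, 100)))
  iv2 <- make_intervals(mask2, v = 500)
  expect_equal(nrow(iv2), 1L)
  expect_equal(iv2$valid, 500L)
  expect_equal(iv2$start, 0L)
  expect_equal(iv2$end, 1500L)
  ## count = ceil(total valid / v), final partial flagged
  mask3 <- list(c1 = rep(c(FALSE, TRUE), 600))  # 600 valid
  iv3 <- make_intervals(mask3, v = 250)
  expect_equal(nrow(iv3), ceiling(600 / 250))
  expect_equal(sum(iv3$valid), 600L)
  expect_equal(iv3$partial, c(FALSE, FALSE, TRUE))
})

test_that("interval enrichment scores follow the normalized log2 ratio with clamps", {
  len <- 1000L
  germ <- depth_track(list(c1 = rep(32L, len)))
  soma <- depth_track(list(c1 = rep(54L, len)))
  params <- scan_params(v = 500)
  mask <- list(c1 = rep(FALSE, len))
  iv <- make_intervals(mask, 500)
  sc <- interval_enrichment(iv, germ, soma, params, mask,
                            modal_g = 32, modal_s = 54)
  expect_equal(sc$score, c(0, 0))  # null case
  germ2 <- depth_track(list(c1 = rep(64L, len)))
  sc2 <- interval_enrichment(iv, germ2, soma, params, mask, 32, 54)
  expect_equal(sc2$score, c(1, 1))  # doubled germline depth
  ## soma 0 clamped to b = 10 before the ratio: finite score
  soma0 <- depth_track(list(c1 = rep(0L, len)))
  sc3 <- interval_enrichment(iv, germ, soma0, params, mask, 32, 54)
  expect_equal(sc3$score, rep(log2((32 / 32) / (10 / 54)), 2),
               tolerance = 1e-12)
})

test_that("scores of swapped samples negate under symmetric clamps", {
  set.seed(9)
  g <- as.integer(rnbinom(4000, mu = 40, size = 30))
  s <- as.integer(rnbinom(4000, mu = 40, size = 30))
  germ <- depth_track(list(c1 = g)); soma <- depth_track(list(c1 = s))
  params <- scan_params(a = 10, b = 10, A = 1e8, B = 1e8)
  mask <- mask_positions(germ, soma, params, 40, 40)
  iv <- make_intervals(mask, 500)
  fwd <- interval_enrichment(iv, germ, soma, params, mask, 40, 40)
  rev <- interval_enrichment(iv, soma, germ, params, mask, 40, 40)
  expect_equal(fwd$score, -rev$score, tolerance = 1e-12)
})

test_that("segmentation finds a planted step and conserves interval counts", {
  set.seed(13)
  scores <- data.frame(contig = "c1",
                       start = (0:199) * 500L, end = (1:200) * 500L,
                       valid = 500L, partial = FALSE,
                       score = c(rnorm(100, 0, 0.3), rnorm(100, 3, 0.3)))
  segs <- segment_scores(scores, n_perm = 200, seed = 2)
  expect_equal(sum(segs$n_intervals), 200L)
  bk <- segs$first[which.max(segs$mean_score)]
  expect_lte(abs(bk - 101), 2)  # breakpoint within +/- 2 intervals
  ## flat scores: a single segment per contig
  flat <- scores; flat$score <- rnorm(200, 0, 0.3)
  segs_flat <- segment_scores(flat, n_perm = 200, seed = 2)
  expect_equal(nrow(segs_flat), 1L)
})

test_that("region calling respects the threshold and reports contained genes", {
  segs <- data.frame(contig = "c1", first = c(1L, 11L, 31L),
                     last = c(10L, 30L, 40L),
                     start = c(0L, 5000L, 15000L),
                     end = c(5000L, 15000L, 20000L),
                     n_intervals = c(10L, 20L, 10L),
                     mean_score = c(0.1, 3.4, 2.5))
  calls <- call_germline_specific(segs, call_threshold = 2,
                                  gene_map = data.frame(
                                    gene_id = c("gA", "gB"),
                                    chromosome = "c1",
                                    start = c(6000L, 1000L),
                                    end = c(7000L, 2000L)))
  expect_equal(nrow(calls$regions), 1L)  # adjacent segments merged
  expect_equal(calls$regions$start, 5000L)
  expect_equal(calls$regions$end, 20000L)
  expect_equal(calls$total_bases, 15000L)
  expect_equal(calls$genes, "gA")
  empty <- call_germline_specific(segs, call_threshold = Inf)
  expect_equal(nrow(empty$regions), 0L)
  expect_equal(empty$total_bases, 0L)
})

test_that("repeat spans reproduce the coverage-ratio formula", {
  expect_equal(repeat_span(rep(320L, 1000), modal_g = 32), 10000)
  expect_equal(repeat_span(rep(32L, 750), modal_g = 32), 750)
  expect_equal(repeat_span(rep(5L, 100), modal_g = 32), 0)
  ## selection rule: enrichment > 10 and span > 100 kb
  cands <- data.frame(score = c(12, 12, 8), span = c(2e5, 5e4, 2e5))
  kept <- cands$score > 10 & cands$span > 1e5
  expect_equal(kept, c(TRUE, FALSE, FALSE))
})

test_that("abundance thresholds scale the modal copy number", {
  h <- data.frame(count = c(10, 24, 40, 72, 100),
                  n_kmers = c(5, 1000, 20, 10, 2))
  th <- kmer_abundance_threshold(h)
  expect_equal(th$modal, 24)
  expect_equal(th$threshold, 72)
  expect_equal(th$n_abundant, 12L)
  expect_equal(kmer_abundance_threshold(h, factor = 1)$threshold, 24)
})

test_that("repeat alignment filtering keeps the 80 percent disjunction", {
  aln <- data.frame(repeat_fraction = c(0.9, 0.5, 0.1, 0.81),
                    read_fraction = c(0.1, 0.5, 0.81, 0.9))
  kept <- repeat_alignment_filter(aln)
  expect_equal(rownames(kept), c("1", "3", "4"))
  expect_error(repeat_alignment_filter(
    data.frame(repeat_fraction = 1.2, read_fraction = 0.5)), "fractions")
})

test_that("clustered repeat hits are flagged per window rules", {
  hits <- data.frame(family = c(rep("r1", 250), rep("r2", 150)),
                     contig = "c1",
                     pos = c(runif(250, 0, 9e5), runif(150, 0, 9e5)))
  expect_equal(somatic_repeat_windows(hits, min_hits = 200), "r1")
  ## centromeric mode needs the pattern on every contig
  hits2 <- rbind(hits[hits$family == "r1", ],
                 data.frame(family = "r1", contig = "c2",
                            pos = runif(10, 0, 9e5)))
  expect_equal(somatic_repeat_windows(hits2, min_hits = 200,
                                      centromeric = TRUE,
                                      contigs = c("c1", "c2")),
               character(0))
})

test_that("end-to-end scan recovers small planted regions on short contigs", {
  regions <- data.frame(contig = c("c1", "c2"),
                        start = c(20000L, 50000L), end = c(40000L, 80000L),
                        kind = "germline_specific", copy_ratio = 10,
                        stringsAsFactors = FALSE)
  sim <- simulate_depth_tracks(c(c1 = 150000L, c2 = 150000L), regions,
                               seed = 5)
  el <- run_elimination(sim$germ, sim$soma, scan_params(), n_perm = 200,
                        seed = 5)
  st <- region_overlap_stats(el$calls$regions, sim$truth)
  expect_gte(st$precision, 0.95)
  expect_gte(st$recall, 0.95)
})
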