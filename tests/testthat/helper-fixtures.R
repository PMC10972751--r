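## Shared fixtures (built once per run) and independent oracles.

.fixture_env <- new.env()

## A small simulated dataset (3 CLGs incl. the lineage-specific CLGB).
small_dataset <- function() {
  if (!exists("ds", envir = .fixture_env)) {
    sc <- default_scenario(clg_count = 3)
    d <- simulate_gene_families(sc, n_families = 8, sites = 200, seed = 42)
    k <- simulate_karyotypes(d, seed = 42)
    d <- annotate_families(d, k)
    assign("ds", list(scenario = sc, dataset = d, karyotype = k),
           envir = .fixture_env)
  }
  get("ds", envir = .fixture_env)
}

## A full-width (17-CLG) dataset with few families per CLG, for synteny
## tests that need realistic chromosome-level CLG contrast.
medium_dataset <- function() {
  if (!exists("md", envir = .fixture_env)) {
    sc <- default_scenario()
    d <- simulate_gene_families(sc, n_families = 40, sites = 200, seed = 77)
    k <- simulate_karyotypes(d, seed = 77)
    d <- annotate_families(d, k)
    assign("md", list(scenario = sc, dataset = d, karyotype = k),
           envir = .fixture_env)
  }
  get("md", envir = .fixture_env)
}

## Brute-force likelihood oracle: explicit summation over all internal-state
## assignments, no pruning, no pattern compression.
brute_force_loglik <- function(tree, aln, model) {
  phy <- ape::reorder.phylo(tree, "postorder")
  enc <- matrix(match(toupper(aln[phy$tip.label, , drop = FALSE]),
                      paralogon:::AA_ALPHABET),
                nrow = length(phy$tip.label))
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e)
    transition_probabilities(model, phy$edge.length[e]))
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  internal <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(1:20), length(internal))))
  tot <- 0
  for (site in seq_len(ncol(enc))) {
    lik <- 0
    states <- rep(NA_integer_, nn)
    states[seq_len(ntip)] <- enc[, site]
    for (g in seq_len(nrow(grid))) {
      states[internal] <- grid[g, ]
      pr <- model$freqs[states[root]]
      for (e in seq_len(nrow(phy$edge))) {
        b <- states[phy$edge[e, 2]]
        if (is.na(b)) next
        pr <- pr * Ps[[e]][states[phy$edge[e, 1]], b]
      }
      lik <- lik + pr
    }
    tot <- tot + log(lik)
  }
  tot
}

## Brute-force one-sided Fisher p-value: explicit hypergeometric sum via
## binomial coefficients.
brute_force_fisher_p <- function(x, nA, nB, N) {
  ks <- max(0, nA + nB - N):min(nA, nB)
  probs <- choose(nA, ks) * choose(N - nA, nB - ks) / choose(N, nB)
  sum(probs[ks >= x])
}

## Construct an ortholog-pairs table + maps realizing the 2x2 table
## [x, nA-x; nB-x, N-nA-nB+x] over chromosomes (A1/A2) x (B1/B2).
fisher_table_input <- function(x, nA, nB, N) {
  chrA <- c(rep("A1", nA), rep("A2", N - nA))
  onB1 <- c(rep(TRUE, x), rep(FALSE, nA - x),
            rep(TRUE, nB - x), rep(FALSE, N - nA - nB + x))
  chrB <- ifelse(onB1, "B1", "B2")
  ga <- sprintf("a%03d", seq_len(N))
  gb <- sprintf("b%03d", seq_len(N))
  pairs <- data.frame(geneA = ga, geneB = gb, score = 1)
  class(pairs) <- c("ortholog_pairs", "data.frame")
  list(pairs = pairs,
       mapA = data.frame(gene_id = ga, chromosome = chrA),
       mapB = data.frame(gene_id = gb, chromosome = chrB))
}

## A tiny random alignment over the amino-acid alphabet.
random_alignment <- function(ntax, nsites, seed = 1, labels = NULL) {
  set.seed(seed)
  aln <- matrix(sample(paralogon:::AA_ALPHABET, ntax * nsites, replace = TRUE),
                ntax, nsites)
  rownames(aln) <- labels %||% paste0("t", seq_len(ntax))
  aln
}

`%||%` <- function(a, b) if (is.null(a)) b else a
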