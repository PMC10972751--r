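m_pois <- poisson_model()

test_that("substitution models are valid stochastic generators", {
  expect_equal(rowSums(m_pois$Q), rep(0, 20), tolerance = 1e-12)
  P <- transition_probabilities(m_pois, 0.37)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12)
  expect_true(all(P >= 0))
  ## closed form matches the spectral path of a general model
  set.seed(1)
  ex <- matrix(runif(400, 0.5, 2), 20, 20); ex <- ex + t(ex)
  mg <- substitution_model(ex, freqs = runif(20, 0.5, 1.5))
  Pg <- transition_probabilities(mg, 0.2)
  expect_equal(rowSums(Pg), rep(1, 20), tolerance = 1e-10)
  ## discrete-gamma categories have mean rate 1
  mgam <- poisson_model(gamma_shape = 0.7)
  expect_equal(sum(mgam$rates * mgam$rate_probs), 1, tolerance = 1e-12)
})

test_that("pruning log-likelihood matches closed forms and the brute-force oracle", {
  ## identical sequences at zero distance: lnL = L log(1/20)
  aln0 <- rbind(a = rep("A", 10), b = rep("A", 10))
  tr0 <- ape::read.tree(text = "(a:0,b:0);")
  expect_equal(log_likelihood(tr0, aln0, m_pois), 10 * log(1 / 20),
               tolerance = 1e-10)
  ## brute force over internal states, 4 and 5 tips, incl. gaps
  for (seed in 1:2) {
    set.seed(seed)
    tr <- ape::rtree(4)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
    aln <- random_alignment(4, 8, seed = seed, labels = tr$tip.label)
    aln[1, 1] <- "-"
    expect_equal(log_likelihood(tr, aln, m_pois),
                 brute_force_loglik(tr, aln, m_pois), tolerance = 1e-8)
  }
  set.seed(5)
  tr5 <- ape::unroot(ape::rtree(5))
  tr5$edge.length <- runif(nrow(tr5$edge), 0.05, 0.5)
  aln5 <- random_alignment(5, 6, seed = 6, labels = tr5$tip.label)
  expect_equal(log_likelihood(tr5, aln5, m_pois),
               brute_force_loglik(tr5, aln5, m_pois), tolerance = 1e-8)
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(2)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  aln <- random_alignment(6, 50, seed = 3, labels = tr$tip.label)
  l0 <- log_likelihood(tr, aln, m_pois)
  for (og in c("t2", "t5")) {
    rooted <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(log_likelihood(rooted, aln, m_pois), l0, tolerance = 1e-8)
  }
  ## per-site values sum to the total
  expect_equal(sum(log_likelihood(tr, aln, m_pois, per_site = TRUE)), l0,
               tolerance = 1e-10)
  ## negative branch length is rejected
  bad <- tr; bad$edge.length[2] <- -0.01
  expect_error(log_likelihood(bad, aln, m_pois), "negative")
})

test_that("ML distances follow the closed form and flag saturation", {
  expect_equal(ml_distance(strrep("A", 50), strrep("A", 50)), 0)
  x <- c(rep("A", 81), rep("R", 19)); y <- rep("A", 100)
  expect_equal(ml_distance(x, y), -(19 / 20) * log(1 - (20 / 19) * 0.19),
               tolerance = 1e-12)
  sat <- ml_distance(c(rep("A", 5), rep("R", 95)), rep("A", 100))
  expect_true(is.infinite(sat))
  expect_true(attr(sat, "saturated"))
  expect_error(ml_distance("-", "A"), "shared")
  ## matrix version agrees with the pairwise closed form
  aln <- random_alignment(4, 120, seed = 8)
  D <- ml_distance_matrix(aln, m_pois, saturated = 9)
  expect_equal(D["t1", "t2"],
               {d <- ml_distance(aln["t1", ], aln["t2", ]); if (is.finite(d)) d else 9},
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(D, t(D))
})

test_that("neighbor joining recovers additive metrics exactly", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    D <- stats::cophenetic(tr)
    nj <- neighbor_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj), 0, ignore_attr = TRUE)
    ## branch lengths exact for additive input
    expect_equal(sort(stats::cophenetic(nj)[rownames(D), colnames(D)]),
                 sort(D), tolerance = 1e-8)
    ## permutation invariance
    perm <- sample(n)
    nj2 <- neighbor_joining(D[perm, perm])
    expect_equal(ape::dist.topo(nj, nj2), 0, ignore_attr = TRUE)
  }
  ## three taxa: three-point formulas
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(t3$edge.length), c(1, 2, 3))
  expect_error(neighbor_joining(matrix(c(0, Inf, Inf, 0), 2)), "finite")
})

test_that("branch-length optimization ascends and recovers simulated lengths", {
  tr <- ape::unroot(ape::read.tree(text = "((a:0.1,b:0.2):0.1,(c:0.15,d:0.05):0);"))
  aln <- evolve_sequences(tr, 20000, m_pois, rate = 1, seed = 5)
  fit <- optimize_branch_lengths(tr, aln, m_pois)
  expect_true(fit$converged)
  expect_true(all(diff(fit$sweep_logLik) >= 0))  # monotone ascent
  expect_true(all(fit$tree$edge.length >= 1e-8)) # clamped at the bound
  ## edge-matched recovery within 10%
  split_of <- function(phy, e) {
    ch <- phy$edge[e, 2]
    tips <- if (ch <= length(phy$tip.label)) phy$tip.label[ch]
    else ape::extract.clade(phy, ch)$tip.label
    paste(sort(tips), collapse = "+")
  }
  tk <- vapply(seq_len(nrow(tr$edge)), split_of, character(1), phy = tr)
  fk <- vapply(seq_len(nrow(fit$tree$edge)), split_of, character(1),
               phy = fit$tree)
  est <- fit$tree$edge.length[match(tk, fk)]
  big <- tr$edge.length >= 0.05
  expect_true(all(abs(est[big] - tr$edge.length[big]) / tr$edge.length[big] < 0.1))
})

test_that("bootstrap supports behave at the boundaries and resolve deep splits", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.15,(c:0.1,d:0.1):0.15);")
  aln <- evolve_sequences(ape::unroot(tr), 2000, m_pois, rate = 1, seed = 2)
  bs <- bootstrap_support(aln, m_pois, n = 50, seed = 4)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  expect_gt(max(sup, na.rm = TRUE), 95)   # clean deep split
  b1 <- bootstrap_support(aln, m_pois, n = 1, seed = 9)
  s1 <- suppressWarnings(as.numeric(b1$node.label))
  expect_true(all(s1 %in% c(0, 100)))
  expect_identical(bootstrap_support(aln, m_pois, n = 20, seed = 7)$node.label,
                   bootstrap_support(aln, m_pois, n = 20, seed = 7)$node.label)
})

test_that("topology tests never reject the best tree and handle duplicates", {
  tr <- ape::unroot(ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);"))
  aln <- evolve_sequences(tr, 500, m_pois, rate = 1, seed = 6)
  tt <- topology_test(list(tr, tr), aln, m_pois, n_rell = 200, seed = 1)
  expect_equal(tt$delta, c(0, 0))
  expect_equal(tt$p, c(1, 1))
  expect_false(any(tt$rejected))
  other <- ape::read.tree(text = "((a,c),(b,e));")
  expect_error(topology_test(list(tr, other), aln, m_pois), "tip set")
})

test_that("likelihood-guided NNI refinement repairs a misplaced deep branch", {
  true_tr <- ape::unroot(ape::read.tree(
    text = "(((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05):0.05,(e:0.1,f:0.1):0.05);"))
  aln <- evolve_sequences(true_tr, 2000, m_pois, rate = 1, seed = 12)
  start <- nni_neighbors(true_tr)[[1]]  # one NNI away from the truth
  rf <- refine_topology(start, aln, m_pois)
  expect_equal(ape::dist.topo(rf$tree, true_tr), 0, ignore_attr = TRUE)
})

test_that("strict-clock dating recovers exact ages and is scale invariant", {
  trc <- ape::read.tree(text = "((a:2,b:2):1,(c:1.5,d:1.5):1.5);")
  trc$edge.length <- trc$edge.length * 0.013
  cal <- data.frame(node = 5, age_min = 3, age_max = 3)
  dt <- date_nodes(trc, cal)
  expect_equal(dt$ages, c(0, 0, 0, 0, 3, 2, 1.5), tolerance = 1e-6)
  expect_equal(dt$rate, 0.013, tolerance = 1e-6)
  ## scaling branch lengths leaves ages unchanged (rate absorbs the scale)
  tr2 <- trc; tr2$edge.length <- tr2$edge.length * 7
  dt2 <- date_nodes(tr2, cal)
  expect_equal(dt2$ages, dt$ages, tolerance = 1e-6)
  expect_equal(dt2$rate, 7 * dt$rate, tolerance = 1e-6)
  ## infeasible calibrations are rejected
  bad <- rbind(cal, data.frame(node = 6, age_min = 5, age_max = 5))
  expect_error(date_nodes(trc, bad), "infeasible")
  expect_error(date_nodes(trc, NULL), "calibration")
})
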