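model <- jtt_model()

test_that("the JTT rate matrix is a proper reversible generator", {
  Q <- model$Q
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  expect_equal(-sum(model$pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance: diag(pi) Q is symmetric
  F <- model$pi * Q
  expect_equal(max(abs(F - t(F))), 0, tolerance = 1e-14)
  expect_equal(sum(model$pi), 1, tolerance = 1e-12)
  # frozen values agree with phangorn's embedded JTT tables
  jtt <- phangorn:::.JTT
  expect_equal(unname(model$s[lower.tri(model$s)]), jtt$Q)
  expect_equal(unname(model$pi), unname(jtt$bf))
})

test_that("P(t) is stochastic for a range of t and P(0) is the identity", {
  for (t in c(0.01, 0.1, 1, 5)) {
    P <- prob_matrix(model, t)
    expect_equal(max(abs(rowSums(P) - 1)), 0, tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  expect_equal(max(abs(prob_matrix(model, 0) - diag(20))), 0,
               tolerance = 1e-12)
})

test_that("identical sequences sit at the lower distance bound", {
  s <- paste(rep(aa20, length.out = 50), collapse = "")
  d <- jtt_distance(s, s)
  expect_lte(as.numeric(d), 1e-6)
  expect_false(attr(d, "saturated"))
})

test_that("ML distance matches a brute-force grid search of the likelihood", {
  set.seed(3)
  P <- prob_matrix(model, 0.3)
  a <- sample(model$alphabet, 100, replace = TRUE, prob = model$pi)
  b <- vapply(a, function(x)
    sample(model$alphabet, 1, prob = P[x, ]), "")
  d <- jtt_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  grid <- seq(1e-4, 2, by = 1e-4)
  ll <- vapply(grid, function(t) {
    Pt <- prob_matrix(model, t)
    sum(log(model$pi[a] * Pt[cbind(a, b)]))
  }, 0)
  expect_lt(abs(as.numeric(d) - grid[which.max(ll)]), 1e-4)
})

test_that("maximally divergent sequences set the saturation flag", {
  a <- paste(rep("A", 60), collapse = "")
  b <- paste(rep("W", 60), collapse = "")
  d <- jtt_distance(a, b)
  expect_true(attr(d, "saturated"))
  expect_error(jtt_distance("AC-", "ACD"), "alphabet")
})

test_that("estimated distance increases with true divergence", {
  set.seed(11)
  levels <- seq(0.05, 1.5, length.out = 20)
  est <- vapply(levels, function(t) {
    P <- prob_matrix(model, t)
    a <- sample(model$alphabet, 400, replace = TRUE, prob = model$pi)
    b <- vapply(a, function(x) sample(model$alphabet, 1, prob = P[x, ]), "")
    as.numeric(jtt_distance(paste(a, collapse = ""),
                            paste(b, collapse = "")))
  }, 0)
  expect_gt(cor(levels, est, method = "spearman"), 0.9)
})

test_that("NJ solves the three-taxon case in closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  len <- tr$edge.length[match(seq_len(3), tr$edge[, 2])]
  names(len) <- tr$tip.label
  expect_equal(len[["A"]], 0.5)
  expect_equal(len[["B"]], 1.5)
  expect_equal(len[["C"]], 2.5)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers topology and lengths exactly from additive distances", {
  # distances from the tree ((A:1,B:2):1,(C:3,D:4))
  ids <- c("A", "B", "C", "D")
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, dimnames = list(ids, ids))
  tr <- nj_tree(D)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(truth), tr)), 0)
  tip_len <- tr$edge.length[match(match(ids, tr$tip.label), tr$edge[, 2])]
  expect_equal(tip_len, c(1, 2, 3, 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sum(internal), 1)
})

test_that("equidistant taxa produce a star-like tree with zero internal branches", {
  ids <- paste0("t", 1:4)
  D <- matrix(2, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  tr <- nj_tree(D)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(unname(internal), rep(0, length(internal)))
})

test_that("a perfectly supported split gets 100 percent bootstrap support", {
  aln <- msa(c(a1 = "AAAAAKKKKK", a2 = "AAAAAKKKKR",
               b1 = "CCCCCDDDDD", b2 = "CCCCCDDDDE"))
  tr <- bootstrap_supports(aln, n_reps = 100, seed = 42)
  internal <- tr$node.label[-1]  # basal node is not a bipartition
  expect_true(all(internal == 100))
})

test_that("single-replicate supports are 0 or 100 and seeds reproduce", {
  aln <- random_msa(5, 60, seed = 2)
  tr1 <- suppressMessages(bootstrap_supports(aln, n_reps = 1, seed = 5,
                                             collapse = NULL))
  expect_true(all(tr1$node.label %in% c(0L, 100L)))
  tr2 <- suppressMessages(bootstrap_supports(aln, n_reps = 20, seed = 9))
  tr3 <- suppressMessages(bootstrap_supports(aln, n_reps = 20, seed = 9))
  expect_identical(ape::write.tree(tr2), ape::write.tree(tr3))
})

test_that("collapsing removes exactly the weakly supported branches", {
  tr <- ape::read.tree(text = "((A:1,B:1)40:1,(C:1,D:1)80:1,E:1);")
  got <- collapse_low_support(tr, 50)
  expect_equal(got$Nnode, 2L)
  expect_true("80" %in% got$node.label)
  expect_false("40" %in% got$node.label)
  # the CD clade survives
  expect_true(ape::is.monophyletic(got, c("C", "D")))
})

test_that("a single gap-free column at zero branch lengths gives log(pi)", {
  aln <- msa(c(x = "A", y = "A"))
  tr <- ape::read.tree(text = "(x:0,y:0);")
  expect_equal(tree_loglik(tr, aln), log(model$pi[["A"]]))
})

test_that("two-taxon pruning equals the pairwise likelihood formula", {
  set.seed(4)
  P <- prob_matrix(model, 0.25)
  a <- sample(model$alphabet, 80, replace = TRUE, prob = model$pi)
  b <- vapply(a, function(x) sample(model$alphabet, 1, prob = P[x, ]), "")
  aln <- msa(c(s1 = paste(a, collapse = ""), s2 = paste(b, collapse = "")))
  tr <- ape::read.tree(text = "(s1:0.1,s2:0.15);")
  expect_equal(tree_loglik(tr, aln),
               sum(log(model$pi[a] * P[cbind(a, b)])),
               tolerance = 1e-8)
})

test_that("log-likelihood is invariant to rooting and leaf order", {
  cfg <- sim_config(n_taxa = 6, pro_codons = 30, mature_codons = 30,
                    motif_pos = 10, gap_rate = 0, seed = 3)
  sim <- simulate_family(cfg)
  aln <- sim$proteins
  tr <- ape::read.tree(text = sim$truth$tree)
  ll <- tree_loglik(tr, aln)
  for (og in rownames(aln)[1:3]) {
    rr <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(tree_loglik(rr, aln), ll, tolerance = 1e-8)
  }
  perm <- msa(unclass(aln)[rev(rownames(aln)), , drop = FALSE])
  expect_equal(tree_loglik(tr, perm), ll, tolerance = 1e-10)
  bad <- tr
  bad$tip.label[1] <- "not_a_taxon"
  expect_error(tree_loglik(bad, aln), "match")
})

test_that("pruning agrees with an independent likelihood implementation", {
  cfg <- sim_config(n_taxa = 7, pro_codons = 40, mature_codons = 40,
                    motif_pos = 10, gap_rate = 0, seed = 8)
  sim <- simulate_family(cfg)
  tr <- ape::read.tree(text = sim$truth$tree)
  pd <- phangorn::phyDat(as.matrix(unclass(sim$proteins)), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "JTT")
  expect_equal(tree_loglik(tr, sim$proteins), fit$logLik, tolerance = 1e-6)
})

test_that("NJ on tree-derived JTT distances recovers the generating topology", {
  for (seed in c(21, 22)) {
    cfg <- sim_config(n_taxa = 8, pro_codons = 150, mature_codons = 150,
                      omega_pro = 1, omega_mature = 1, depth = 0.2,
                      motif_core = NULL, loss_clade = NULL, gap_rate = 0,
                      seed = seed)
    sim <- simulate_family(cfg)
    tr <- ape::read.tree(text = sim$truth$tree)
    D <- cophenetic(tr)
    est <- nj_tree(D)   # additive distances: exact recovery
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0)
  }
})
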