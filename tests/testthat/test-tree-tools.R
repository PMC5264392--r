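test_that("neighbor joining recovers additive trees exactly", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0.5);")
  est <- nj_tree(ape::cophenetic.phylo(tr))
  expect_equal(phangorn::RF.dist(est, ape::unroot(tr)), 0)
  expect_equal(sort(est$edge.length), sort(ape::unroot(tr)$edge.length),
               tolerance = 1e-10)

  # consistency over random additive 6-taxon matrices
  set.seed(81)
  for (i in 1:50) {
    t0 <- ape::rtree(6, br = function(n) runif(n, 0.05, 1))
    est <- nj_tree(ape::cophenetic.phylo(t0))
    expect_equal(phangorn::RF.dist(est, ape::unroot(t0)), 0)
  }

  # negative-branch clamping leaves no negative edges
  d <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 1, 9, 10, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(d)$edge.length >= 0))
  dd <- d; dd[1, 2] <- NA
  expect_error(nj_tree(dd), "incomplete")
})

test_that("Fitch parsimony equals the brute-force ancestral enumeration", {
  # hand cases
  quartet <- ape::read.tree(text = "((t1,t2),t3,t4);")
  aln <- aln_from_strings(c(t1 = "A", t2 = "A", t3 = "C", t4 = "C"))
  expect_equal(fitch_parsimony(quartet, aln), 1L)
  alt <- ape::read.tree(text = "((t1,t3),t2,t4);")
  expect_equal(fitch_parsimony(alt, aln), 2L)
  inv <- aln_from_strings(c(t1 = "AAA", t2 = "AAA", t3 = "AAA", t4 = "AAA"))
  expect_equal(fitch_parsimony(quartet, inv), 0L)

  # random 5-taxon columns incl. gaps against the oracle
  set.seed(82)
  for (i in 1:6) {
    tr <- ape::unroot(ape::rtree(5, tip.label = sprintf("t%02d", 1:5)))
    aln <- random_nt_alignment(5, 8, seed = 82 + i, gap_frac = 0.1)
    expect_equal(fitch_parsimony(tr, aln), fitch_brute(tr, aln))
  }
})

test_that("pruning log-likelihood matches closed form and brute-force summation", {
  # two taxa, JC, one matching site
  jc <- list(rates = rep(1, 6), bf = rep(0.25, 4), shape = NULL)
  t2 <- ape::read.tree(text = "(a:0.4,b:0.4);")
  a2 <- aln_from_strings(c(a = "A", b = "A"))
  expect_equal(gtr_gamma_loglik(t2, a2, jc),
               log(0.25 * (0.25 + 0.75 * exp(-4 * 0.8 / 3))), tolerance = 1e-9)

  # 4-taxon, GTR+G against brute force over internal states
  m <- default_sim_model()
  tr <- felsenstein_zone_tree(0.4, 0.1)
  aln <- simulate_alignment(tr, m, 3, seed = 83)
  ll <- gtr_gamma_loglik(tr, aln, m, k = 4)
  expect_equal(ll, loglik_brute(tr, aln, m, k = 4), tolerance = 1e-8)

  # 5-taxon, no gamma
  tr5 <- ape::rtree(5, br = function(n) runif(n, 0.1, 0.5))
  jc2 <- list(rates = rep(1, 6), bf = rep(0.25, 4), shape = NULL)
  aln5 <- simulate_alignment(tr5, jc2, 4, seed = 84)
  expect_equal(gtr_gamma_loglik(tr5, aln5, jc2),
               loglik_brute(tr5, aln5, jc2), tolerance = 1e-8)

  # invariance to re-rooting (reversible model)
  rr <- ape::root(tr, "B", resolve.root = TRUE)
  rr$edge.length[rr$edge.length == 0] <- 1e-9
  expect_equal(gtr_gamma_loglik(ape::unroot(rr), aln, m, k = 4), ll,
               tolerance = 1e-6)
})

test_that("branch-length optimization recovers generating lengths", {
  m <- list(rates = rep(1, 6), bf = rep(0.25, 4), shape = NULL)
  tr <- ape::read.tree(text = "((a:0.2,b:0.1):0.15,c:0.3,d:0.25);")
  aln <- simulate_alignment(tr, m, 50000, seed = 85)
  start <- tr
  start$edge.length <- start$edge.length * runif(length(start$edge.length), 0.5, 2)
  opt <- optimize_branch_lengths(start, aln, m)
  expect_equal(sum(opt$edge.length), sum(tr$edge.length), tolerance = 0.02)
  expect_gt(attr(opt, "logLik"), gtr_gamma_loglik(tr, aln, m))
})

test_that("exhaustive search scores all topologies and finds the generator", {
  m <- list(rates = rep(1, 6), bf = rep(0.25, 4), shape = NULL)
  # strong internal signal
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.3,c:0.05,d:0.05);")
  aln <- simulate_alignment(tr, m, 2000, seed = 86)
  res <- exhaustive_ml_search(aln, m, k = 1)
  expect_equal(res$n_topologies, 3)
  expect_equal(phangorn::RF.dist(res$tree, tr), 0)

  aln5 <- simulate_alignment(ape::rtree(5), m, 50, seed = 87)
  expect_equal(exhaustive_ml_search(aln5, m, k = 1)$n_topologies, 15)
  big <- random_nt_alignment(10, 20)
  expect_error(exhaustive_ml_search(big, m), "heuristic")
})

test_that("trichotomy classification names the odd clade out", {
  clades <- list(J = "J", C = "C", HCX = "H")
  t1 <- ape::read.tree(text = "((J,(C,H)),out);")
  expect_equal(classify_trichotomy(t1, clades, "out"), "J(C,HCX)")
  t2 <- ape::read.tree(text = "((H,(J,C)),out);")
  expect_equal(classify_trichotomy(t2, clades, "out"), "HCX(J,C)")

  # multi-taxon clades and a paraphyletic case
  clades2 <- list(J = c("J1", "J2"), C = c("C1", "C2"), HCX = c("H1", "H2"))
  t3 <- ape::read.tree(text = "(((J1,J2),((C1,C2),(H1,H2))),out);")
  expect_equal(classify_trichotomy(t3, clades2, "out"), "J(C,HCX)")
  t4 <- ape::read.tree(text = "(((J1,C1),((J2,C2),(H1,H2))),out);")
  expect_equal(classify_trichotomy(t4, clades2, "out"), "other")
})

test_that("stem branch report measures subtending edges and ratios", {
  txt <- "(((J1:1,J2:1):0.30,((C1:1,C2:1):0.20,(H1:1,H2:1):0.10):0.05):0.1,out:2);"
  tr <- ape::read.tree(text = txt)
  clades <- list(J = c("J1", "J2"), C = c("C1", "C2"), HCX = c("H1", "H2"))
  rep <- stem_branch_report(tr, clades, reference = "HCX", outgroup = "out")
  expect_equal(rep$stem, c(0.30, 0.20, 0.10))
  expect_equal(rep$ratio, c(3, 2, 1))
  expect_true(all(rep$monophyletic))

  # non-monophyletic clade flagged with NA
  bad <- list(J = c("J1", "C1"), C = c("J2", "C2"), HCX = c("H1", "H2"))
  rep2 <- stem_branch_report(tr, bad, reference = "HCX", outgroup = "out")
  expect_true(any(!rep2$monophyletic))
  expect_true(any(is.na(rep2$stem)))
})

test_that("bootstrap support is deterministic and finds overwhelming signal", {
  sc <- jcx_scenario(stem_J = 0.05, stem_C = 0.05, stem_HCX = 0.05,
                     internal_1 = 0.1, internal_2 = 0.1, pos3_rate = 1,
                     n_genes = 2, gene_length = 600)
  aln <- simulate_scenario(sc, seed = 88)$alignment
  bs <- bootstrap_support(aln, sc$clades, sc$outgroup, infer = "nj",
                          n_reps = 40, seed = 5)
  expect_equal(sum(bs$counts), 40)
  expect_equal(sum(bs$proportions), 1)
  expect_gte(bs$proportions["J(C,HCX)"], 0.95)

  bs2 <- bootstrap_support(aln, sc$clades, sc$outgroup, infer = "nj",
                           n_reps = 40, seed = 5)
  expect_identical(bs$counts, bs2$counts)
  expect_error(bootstrap_support(aln, sc$clades, sc$outgroup, n_reps = 0),
               "positive")
})

test_that("parsimony is inconsistent in the Felsenstein zone while ML is not", {
  m <- list(rates = rep(1, 6), bf = rep(0.25, 4), shape = NULL)
  tr <- felsenstein_zone_tree(0.5, 0.05)
  topos <- phangorn::allTrees(4, tip.label = c("A", "B", "C", "D"))
  wrong_pars <- 0; right_ml <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    sim <- simulate_alignment(tr, m, 2000, seed = 880 + s)
    scores <- vapply(topos, fitch_parsimony, 1L, aln = sim)
    best <- topos[[which.min(scores)]]
    wrong_pars <- wrong_pars +
      (ape::is.monophyletic(ape::root(best, "B"), c("A", "C")))
    ml <- exhaustive_ml_search(sim, m, k = 1)
    right_ml <- right_ml + (phangorn::RF.dist(ml$tree, tr) == 0)
  }
  expect_gt(wrong_pars / n_seeds, 0.5)
  expect_gt(right_ml / n_seeds, 0.5)
})
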