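test_that("induced quartet topologies match the structural oracle", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(induced_quartet(tr, c("a", "b", "c", "d")), "a,b|c,d")
  expect_equal(induced_quartet(tr, c("a", "c", "b", "d")), "a,b|c,d")
  star <- ape::read.tree(text = "(a,b,c,d);")
  expect_equal(induced_quartet(star, c("a", "b", "c", "d")), "unresolved")
  cat4 <- ape::read.tree(text = "(((a,b),c),d);")
  expect_equal(induced_quartet(cat4, c("a", "b", "c", "d")), "a,b|c,d")
  expect_error(induced_quartet(tr, c("a", "b", "c", "zz")), "not in tree")

  # larger random trees against the keep.tip/RF oracle
  set.seed(91)
  for (i in 1:5) {
    big <- ape::rtree(8)
    q <- sample(big$tip.label, 4)
    got <- induced_quartet(big, q)
    code <- induced_quartet_rf(big, q)
    want <- switch(code + 1L, "unresolved",
                   paste0(q[1], ",", q[2], "|", q[3], ",", q[4]),
                   paste0(q[1], ",", q[3], "|", q[2], ",", q[4]),
                   paste0(q[1], ",", q[4], "|", q[2], ",", q[3]))
    expect_equal(got, want)
  }
})

test_that("quartet score counts gene agreement and matches brute force", {
  t0 <- ape::unroot(ape::rtree(6))
  genes <- rep(list(t0), 7)
  s <- quartet_score(t0, genes)
  expect_equal(as.integer(s), 7 * choose(6, 4))
  expect_equal(attr(s, "n_quartets_total"), 7 * choose(6, 4))

  # random instances with missing taxa against the independent implementation
  set.seed(92)
  for (i in 1:8) {
    sp <- ape::unroot(ape::rtree(7))
    genes <- lapply(1:6, function(g) {
      gt <- ape::rtree(7, tip.label = sp$tip.label)
      if (g %% 2 == 0) gt <- ape::drop.tip(gt, sample(sp$tip.label, 1))
      ape::unroot(gt)
    })
    expect_equal(as.integer(quartet_score(sp, genes)),
                 quartet_score_brute(sp, genes))
  }

  # relabeling invariance
  sp <- ape::unroot(ape::rtree(6))
  genes <- lapply(1:5, function(i) ape::unroot(ape::rtree(6, tip.label = sp$tip.label)))
  relab <- setNames(sprintf("x%02d", 1:6), sp$tip.label)
  sp2 <- sp; sp2$tip.label <- unname(relab[sp$tip.label])
  genes2 <- lapply(genes, function(g) { g$tip.label <- unname(relab[g$tip.label]); g })
  expect_equal(as.integer(quartet_score(sp, genes)),
               as.integer(quartet_score(sp2, genes2)))
})

test_that("exhaustive species-tree search maximizes the quartet score", {
  # unanimous genes -> their topology, perfect score
  t0 <- ape::unroot(ape::rtree(6))
  res <- exact_species_tree(rep(list(t0), 9))
  expect_equal(phangorn::RF.dist(res$species_tree, t0), 0)
  expect_equal(res$score, 9 * choose(6, 4))
  expect_equal(res$search, "exact")

  # MSC-simulated genes on a 6-taxon species tree with >= 0.5 unit internals
  sp <- ape::read.tree(text =
    "(((A:2,B:2):1,(C:1.5,D:1.5):1.5):1,(E:1,F:1):3);")
  hits <- 0
  for (s in 1:10) {
    genes <- simulate_msc_gene_trees(sp, 200, seed = 900 + s)
    est <- exact_species_tree(genes)
    hits <- hits + (phangorn::RF.dist(est$species_tree, ape::unroot(sp)) == 0)
  }
  expect_gte(hits, 9)   # statistical consistency at 200 genes

  expect_error(exact_species_tree(list(ape::rtree(12))), "refusing")
})

test_that("exact search dominates the heuristic, which matches it on most instances", {
  set.seed(93)
  agree <- 0
  for (i in 1:20) {
    taxa <- sprintf("s%02d", 1:6)
    genes <- lapply(1:10, function(g) ape::unroot(ape::rtree(6, tip.label = taxa)))
    ex <- exact_species_tree(genes)
    he <- heuristic_species_tree(genes, seed = i)
    expect_gte(ex$score, he$score)
    agree <- agree + (ex$score == he$score)
  }
  expect_gte(agree, 16)   # >= 80% of random instances

  # unanimous genes: heuristic exact at initialization; determinism
  t0 <- ape::unroot(ape::rtree(7))
  he1 <- heuristic_species_tree(rep(list(t0), 5), seed = 4)
  expect_equal(phangorn::RF.dist(he1$species_tree, t0), 0)
  he2 <- heuristic_species_tree(rep(list(t0), 5), seed = 4)
  expect_equal(ape::write.tree(he1$species_tree), ape::write.tree(he2$species_tree))
})

test_that("deep coalescence can pull the gene-tree majority off the species tree", {
  # anomaly-prone caterpillar: two very short internals in sequence
  sp <- ape::read.tree(text =
    "((((A:0.02,B:0.02):0.1,C:0.12):0.1,D:0.22):3,E:3.22);")
  genes <- simulate_msc_gene_trees(sp, 600, seed = 94)
  est <- exact_species_tree(genes)
  # the quartet tree still recovers the species tree
  expect_equal(phangorn::RF.dist(est$species_tree, ape::unroot(sp)), 0)
  # while the single most common gene-tree topology is not the species tree
  topos <- phangorn::allTrees(5, tip.label = sp$tip.label)
  idx <- vapply(genes, function(g)
    which(vapply(topos, function(t) phangorn::RF.dist(t, g) == 0, logical(1)))[1],
    1L)
  modal <- topos[[as.integer(names(sort(table(idx), decreasing = TRUE))[1])]]
  expect_gt(phangorn::RF.dist(modal, ape::unroot(sp)), 0)
})
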