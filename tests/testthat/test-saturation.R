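test_that("p-distances count mismatches over comparable sites only", {
  aln <- aln_from_strings(c(a = "ACGT", b = "ACGA", c = "AC-T", d = "ACGT"))
  d <- p_distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)      # gap column excluded -> 0/3
  expect_equal(d["a", "d"], 0)
  expect_true(isSymmetric(unname(d)))
  expect_equal(unname(diag(d)), rep(0, 4))
})

test_that("JC69 ML distance matches the closed form and dominates p", {
  # engineered pair with p = 0.25
  aln <- aln_from_strings(c(a = paste(rep("A", 8), collapse = ""),
                            b = "AAAAAACG"))
  d <- ml_distance_matrix(aln, "JC69")
  expect_equal(d["a", "b"], -3 / 4 * log(1 - 4 / 3 * 0.25), tolerance = 1e-9)

  # identity -> 0
  same <- aln_from_strings(c(a = "ACGTACGT", b = "ACGTACGT"))
  expect_equal(ml_distance_matrix(same, "JC69")["a", "b"], 0)

  # JC >= p over a grid (property)
  for (s in 1:3) {
    sim <- simulate_alignment(ape::rtree(6), default_sim_model(), 400, seed = s)
    dj <- ml_distance_matrix(sim, "JC69")
    dp <- p_distance_matrix(sim)
    ut <- upper.tri(dj)
    ok <- is.finite(dj[ut])
    expect_true(all(dj[ut][ok] >= dp[ut][ok] - 1e-12))
  }
})

test_that("GTR+G pairwise distances recover the simulated divergence", {
  m <- default_sim_model()
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  sim <- simulate_alignment(tr, m, 100000, seed = 7)
  d <- ml_distance_matrix(sim, "GTR+G",
                          params = list(rates = m$rates, bf = m$bf,
                                        shape = m$shape, k = 4))
  expect_equal(d["a", "b"], 0.4, tolerance = 0.02)
})

test_that("patristic distances sum branch lengths along paths", {
  tr <- ape::read.tree(text = "((a:1,b:2):0.5,c:3);")
  d <- patristic_matrix(tr)
  expect_equal(d["a", "b"], 3)
  expect_equal(d["a", "c"], 4.5)
  # star tree with equal radii
  star <- ape::read.tree(text = "(a:2,b:2,c:2,d:2);")
  ds <- patristic_matrix(star)
  expect_true(all(ds[upper.tri(ds)] == 4))
  noblen <- ape::read.tree(text = "((a,b),c);")
  expect_error(patristic_matrix(noblen), "incomplete")
})

test_that("saturation regression returns exact slope and R2 on constructed data", {
  x <- patristic_matrix(ape::rtree(8, br = function(n) runif(n, 0.1, 1)))
  for (alpha in c(0.25, 0.5, 1)) {
    r <- saturation_regression(x, alpha * x)
    expect_equal(r$slope, alpha, tolerance = 1e-10)
    expect_equal(r$R2, 1, tolerance = 1e-10)
    expect_equal(r$n_pairs, 8 * 7 / 2)
  }
  # constant response -> slope 0
  y <- x; y[] <- 0.3; diag(y) <- 0
  expect_equal(saturation_regression(x, y)$slope, 0, tolerance = 1e-10)
  # degenerate predictor
  expect_error(saturation_regression(y, x), "degenerate")
})

test_that("saturation flattens the patristic-vs-p regression slope", {
  base <- ape::rtree(10, br = function(n) runif(n, 0.02, 0.1))
  long <- base; long$edge.length <- base$edge.length * 10
  m <- default_sim_model()
  sim_s <- simulate_alignment(base, m, 2000, seed = 21)
  sim_l <- simulate_alignment(long, m, 2000, seed = 21)
  slope_s <- saturation_regression(patristic_matrix(base),
                                   p_distance_matrix(sim_s))$slope
  slope_l <- saturation_regression(patristic_matrix(long),
                                   p_distance_matrix(sim_l))$slope
  expect_gt(slope_s, slope_l)
})

test_that("Iss hits its limits and increases with tree depth", {
  # invariant alignment
  inv <- aln_from_strings(c(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA"))
  ii <- iss_index(inv)
  expect_equal(ii$Iss, 0)
  expect_true(ii$degenerate)

  # engineered half-entropy alignment at many taxa
  set.seed(31)
  m2 <- matrix("A", 64, 2000, dimnames = list(sprintf("s%02d", 1:64), NULL))
  pairs <- list(c("A", "C"), c("G", "T"), c("A", "G"), c("C", "T"),
                c("A", "T"), c("C", "G"))
  for (j in seq_len(ncol(m2))) {
    two <- pairs[[1 + (j %% 6)]]
    m2[, j] <- rep(two, each = 32)[sample.int(64)]
  }
  expect_equal(iss_index(new_alignment(m2, "nucleotide"))$Iss, 0.5,
               tolerance = 0.02)

  # monotonicity in simulation depth
  m <- default_sim_model()
  mean_iss <- vapply(c(0.2, 0.8, 3.2), function(depth) {
    tr <- felsenstein_zone_tree(depth, depth / 4)
    mean(vapply(1:20, function(s)
      iss_index(simulate_alignment(tr, m, 300, seed = 1000 * depth + s))$Iss, 1))
  }, 1)
  expect_true(all(diff(mean_iss) > 0))
})

test_that("the Monte Carlo Iss test flags randomized genes and spares clean ones", {
  # i.i.d. uniform data is the saturation limit
  set.seed(41)
  rnd <- random_nt_alignment(8, 500, seed = 41)
  it <- iss_test(rnd, reps = 100, seed = 1, n_subsamples = 10, n_boot = 50)
  expect_true(it$saturated)
  expect_gt(it$Iss_obs, it$Iss_c_sym)

  # determinism under the same seed
  it2 <- iss_test(rnd, reps = 100, seed = 1, n_subsamples = 10, n_boot = 50)
  expect_identical(it[c("Iss_obs", "Iss_c_sym", "Iss_c_asym", "p_sym", "p_asym")],
                   it2[c("Iss_obs", "Iss_c_sym", "Iss_c_asym", "p_sym", "p_asym")])

  # invariant gene is never flagged
  inv <- aln_from_strings(c(a = strrep("A", 50), b = strrep("A", 50),
                            c = strrep("A", 50), d = strrep("A", 50)))
  it3 <- iss_test(inv, reps = 100, seed = 2, n_boot = 20)
  expect_false(it3$saturated)
  expect_warning(iss_test(rnd, reps = 50, seed = 1, n_subsamples = 4,
                          n_boot = 10), "unstable")
})

test_that("density-valley flagging finds the left shoulder", {
  set.seed(51)
  vals <- c(rnorm(12, 0.1, 0.02), rnorm(70, 0.9, 0.05))
  names(vals) <- paste0("g", seq_along(vals))
  fl <- flag_saturated_genes(vals, "valley")
  expect_setequal(fl$flagged, paste0("g", 1:12))
  expect_equal(fl$method, "valley")

  # unimodal sample falls back to the percentile rule
  uni <- setNames(rnorm(40, 0.5, 0.01), paste0("u", 1:40))
  expect_message(fl2 <- flag_saturated_genes(uni, "valley", param = 15),
                 "falling back")
  expect_equal(fl2$method, "percentile")
  expect_equal(length(fl2$flagged), 6)   # 15% of 40

  expect_error(flag_saturated_genes(vals[1:3]), ">= 5")
})
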