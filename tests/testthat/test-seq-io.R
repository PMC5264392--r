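test_that("FASTA and PHYLIP readers parse, normalize and round-trip", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "AC-T"), path)
  aln <- read_alignment(path, "fasta")
  expect_equal(n_taxa(aln), 2)
  expect_equal(n_cols(aln), 4)
  expect_equal(sum(aln$matrix == "-"), 1)

  # U mapped to T, unknown mapped to N with a message
  writeLines(c(">a", "ACGU", ">b", "AC!T"), path)
  expect_message(aln2 <- read_alignment(path, "fasta"), "unknown")
  expect_equal(unname(aln2$matrix["a", 4]), "T")
  expect_equal(unname(aln2$matrix["b", 3]), "N")

  # empty file errors
  writeLines(character(0), path)
  expect_error(read_alignment(path, "fasta"), "malformed")

  # round-trip identity for both formats
  aln3 <- random_nt_alignment(5, 60, seed = 3, gap_frac = 0.05)
  for (fmt in c("fasta", "phylip")) {
    p <- withr::local_tempfile()
    write_alignment(aln3, p, fmt)
    back <- read_alignment(p, fmt)
    expect_identical(back$matrix, aln3$matrix)
  }
})

test_that("alignment constructor enforces its invariants", {
  m <- matrix(c("A", "C"), 2, 1)
  expect_error(new_alignment(m), "row names")
  rownames(m) <- c("x", "x")
  expect_error(new_alignment(m), "duplicate")
  rownames(m) <- c("x", "y")
  m[1, 1] <- "!"
  expect_error(new_alignment(m), "alphabet")
})

test_that("partition map reader converts RAxML coordinates and validates", {
  path <- withr::local_tempfile()
  writeLines(c("DNA, g1 = 1-6", "DNA, g2 = 7-12"), path)
  pm <- read_partition_map(path)
  expect_equal(pm$start, c(0L, 6L))
  expect_equal(pm$end, c(6L, 12L))
  expect_equal(pm_width(pm), 12L)

  writeLines("DNA, g1 = 5-2", path)
  expect_error(read_partition_map(path), "range error")
  expect_error(new_partition_map(c("a", "b"), c(0, 3), c(4, 6)), "overlap")

  # write -> read round trip
  pm2 <- new_partition_map(c("rbcL", "matK"), c(0, 1428), c(1428, 2970))
  p2 <- withr::local_tempfile()
  write_partition_map(pm2, p2)
  expect_equal(read_partition_map(p2), pm2)
})

test_that("concatenation appends columns and records gene intervals", {
  a <- random_nt_alignment(4, 6, seed = 1)
  b <- random_nt_alignment(4, 9, seed = 2)
  cc <- concatenate_alignments(list(a, b), c("g1", "g2"))
  expect_equal(n_cols(cc$alignment), 15)
  expect_equal(cc$map$start, c(0L, 6L))
  expect_equal(cc$map$end, c(6L, 15L))

  # single alignment is the identity
  one <- concatenate_alignments(list(a), "g1")
  expect_identical(one$alignment$matrix, a$matrix)

  # mismatched taxa refuse
  c2 <- random_nt_alignment(5, 6, seed = 3)
  expect_error(concatenate_alignments(list(a, c2), c("g1", "g2")),
               "incompatible taxa")
})

test_that("codon-position extraction respects frames and partitions the columns", {
  aln <- random_nt_alignment(4, 9, seed = 4)
  expect_equal(n_cols(extract_codon_positions(aln, c(1, 2))), 6)
  expect_identical(extract_codon_positions(aln, 1:3)$matrix, aln$matrix)
  expect_error(extract_codon_positions(random_nt_alignment(4, 8), c(1, 2)),
               "frame error")

  # keep {1,2} and keep {3} partition the columns exactly
  p12 <- extract_codon_positions(aln, c(1, 2))
  p3 <- extract_codon_positions(aln, 3)
  expect_equal(n_cols(p12) + n_cols(p3), n_cols(aln))
  merged <- cbind(p12$matrix[, 1:2], p3$matrix[, 1, drop = FALSE])
  expect_identical(sort(paste(merged[1, ])), sort(paste(aln$matrix[1, 1:3])))

  # per-gene frame enforcement through a partition map
  pm <- new_partition_map(c("g1", "g2"), c(0, 4), c(4, 9))
  expect_error(extract_codon_positions(aln, c(1, 2), pm), "frame error")
})

test_that("translation maps codons to amino acids with gap/ambiguity policy", {
  aln <- aln_from_strings(c(a = "ATGGCT", b = "AT-GCT", c = "ATNGCT", d = "TAAGCT"))
  expect_warning(tr <- translate_codon_alignment(aln), "stop codon")
  expect_equal(tr$matrix["a", ], c("M", "A"))
  expect_equal(unname(tr$matrix["b", 1]), "-")    # gap codon -> gap
  expect_equal(unname(tr$matrix["c", 1]), "X")    # ambiguous codon -> X
  expect_equal(unname(tr$matrix["d", 1]), "*")    # internal stop
  expect_equal(tr$molecule, "amino-acid")
  expect_equal(n_cols(tr), 2)
})

test_that("gene subsetting keeps or drops named genes and rebuilds the map", {
  genes <- lapply(1:5, function(i) random_nt_alignment(4, 6, seed = i))
  cc <- concatenate_alignments(genes, paste0("g", 1:5))
  kept <- subset_genes(cc$alignment, cc$map, c("g2", "g4"), "keep")
  expect_equal(n_cols(kept$alignment), 12)
  expect_equal(kept$map$gene, c("g2", "g4"))
  expect_identical(kept$alignment$matrix[, 1:6], genes[[2]]$matrix)

  dropped <- subset_genes(cc$alignment, cc$map, c("g2", "g4"), "drop")
  expect_equal(dropped$map$gene, c("g1", "g3", "g5"))

  # keep-all identity, drop-all empty
  all_keep <- subset_genes(cc$alignment, cc$map, paste0("g", 1:5), "keep")
  expect_identical(all_keep$alignment$matrix, cc$alignment$matrix)
  none <- subset_genes(cc$alignment, cc$map, paste0("g", 1:5), "drop")
  expect_equal(n_cols(none$alignment), 0)
  expect_equal(nrow(none$map), 0)

  expect_error(subset_genes(cc$alignment, cc$map, "nope", "keep"), "unknown gene")
})

test_that("Newick reading and writing preserve structure round-trip", {
  path <- withr::local_tempfile()
  writeLines("((a:1,b:1):0.5,c:2);", path)
  trees <- read_trees(path)
  expect_length(trees, 1)
  expect_equal(sort(trees[[1]]$tip.label), c("a", "b", "c"))

  many <- replicate(8, ape::rtree(6), simplify = FALSE)
  write_trees(many, path)
  back <- read_trees(path)
  expect_length(back, 8)
  expect_equal(phangorn::RF.dist(back[[3]], many[[3]]), 0)

  writeLines("((a,b,;", path)
  expect_error(read_trees(path))
})
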