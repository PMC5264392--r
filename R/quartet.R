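# Quartet-agreement species-tree estimation: the coalescent objective is
# the number of gene-tree-induced four-taxon topologies that agree with the
# candidate species tree. The search is exhaustive for small taxon sets and
# NNI hill-climbing beyond; the objective itself is exact in both cases.

# node-count ("topological") cophenetic matrix: every edge length 1.
# For a quartet {a,b,c,d} the pairing with the smallest sum of within-pair
# distances is the induced split (four-point condition); all-equal sums mean
# the restriction is a star.
unit_cophenetic <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  as.matrix(stats::cophenetic(tree))
}

# induced quartet topology from a unit cophenetic matrix and 4 labels:
# 1 = q1q2|q3q4, 2 = q1q3|q2q4, 3 = q1q4|q2q3, 0 = unresolved
quartet_code <- function(D, q) {
  s <- c(D[q[1], q[2]] + D[q[3], q[4]],
         D[q[1], q[3]] + D[q[2], q[4]],
         D[q[1], q[4]] + D[q[2], q[3]])
  lo <- which(s == min(s))
  if (length(lo) > 1) 0L else lo
}

#' Induced quartet topology of a tree
#'
#' Restricts the unrooted tree to four taxa and reports the resulting split,
#' or \code{"unresolved"} when the restriction is a star (polytomy).
#'
#' @param tree a \code{phylo}.
#' @param q character vector of 4 taxon labels present in the tree.
#' @return A label like \code{"a,b|c,d"} using the supplied names, or
#'   \code{"unresolved"}.
#' @export
induced_quartet <- function(tree, q) {
  stopifnot(length(q) == 4)
  missing <- setdiff(q, tree$tip.label)
  if (length(missing)) stop("taxon not in tree: ", paste(missing, collapse = ", "))
  D <- unit_cophenetic(tree)
  code <- quartet_code(D, q)
  switch(code + 1L, "unresolved",
         paste0(q[1], ",", q[2], "|", q[3], ",", q[4]),
         paste0(q[1], ",", q[3], "|", q[2], ",", q[4]),
         paste0(q[1], ",", q[4], "|", q[2], ",", q[3]))
}

# all quartet codes of a tree over a fixed taxon ordering; quartets =
# 4 x C(n,4) matrix of label indices into `taxa`
tree_quartet_codes <- function(tree, taxa, quartets) {
  D <- unit_cophenetic(tree)
  idx <- matrix(match(taxa, rownames(D))[quartets], nrow = 4)
  s1 <- D[cbind(idx[1, ], idx[2, ])] + D[cbind(idx[3, ], idx[4, ])]
  s2 <- D[cbind(idx[1, ], idx[3, ])] + D[cbind(idx[2, ], idx[4, ])]
  s3 <- D[cbind(idx[1, ], idx[4, ])] + D[cbind(idx[2, ], idx[3, ])]
  sm <- pmin(s1, s2, s3)
  code <- ifelse(s1 == sm, 1L, ifelse(s2 == sm, 2L, 3L))
  ties <- (s1 == sm) + (s2 == sm) + (s3 == sm)
  code[ties > 1] <- 0L
  code
}

#' Quartet agreement score of a species tree against gene trees
#'
#' Sum over genes and over all four-taxon subsets present in the gene of the
#' indicator that the gene tree and the species tree induce the same quartet
#' topology. Gene trees may miss taxa (those quartets are skipped);
#' unresolved gene quartets contribute 0.
#'
#' @param species a \code{phylo} over the full taxon set.
#' @param genes list of \code{phylo} gene trees (leaf sets may be subsets).
#' @return Integer score; \code{n_quartets_total} (genes x C(n,4)) is
#'   attached as an attribute.
#' @export
quartet_score <- function(species, genes) {
  taxa <- sort(species$tip.label)
  n <- length(taxa)
  quartets <- combn(n, 4)
  sp_codes <- tree_quartet_codes(species, taxa, quartets)
  score <- 0L
  for (g in genes) {
    present <- taxa %in% g$tip.label
    keep <- colSums(matrix(present[quartets], nrow = 4)) == 4L
    if (!any(keep)) next
    gcodes <- tree_quartet_codes(g, taxa, quartets[, keep, drop = FALSE])
    sp <- sp_codes[keep]
    score <- score + sum(gcodes != 0L & gcodes == sp)
  }
  structure(as.integer(score),
            n_quartets_total = length(genes) * ncol(quartets))
}

# per-quartet tally of gene codes: rows = quartets, cols = codes 1..3
gene_code_tally <- function(genes, taxa, quartets) {
  tal <- matrix(0L, ncol(quartets), 3)
  for (g in genes) {
    present <- taxa %in% g$tip.label
    keep <- which(colSums(matrix(present[quartets], nrow = 4)) == 4L)
    if (!length(keep)) next
    gcodes <- tree_quartet_codes(g, taxa, quartets[, keep, drop = FALSE])
    for (cc in 1:3) {
      hit <- keep[gcodes == cc]
      tal[hit, cc] <- tal[hit, cc] + 1L
    }
  }
  tal
}

tally_score <- function(tree, taxa, quartets, tally) {
  codes <- tree_quartet_codes(tree, taxa, quartets)
  ok <- codes != 0L
  sum(tally[cbind(which(ok), codes[ok])])
}

#' Exact quartet-agreement species tree (exhaustive search)
#'
#' Enumerates every unrooted binary topology over the union of the gene-tree
#' taxa and returns the maximizer of \code{\link{quartet_score}}; ties are
#' all reported.
#'
#' @param genes list of \code{phylo} gene trees.
#' @param max_taxa refuse larger problems (default 9).
#' @return list with \code{species_tree}, \code{score},
#'   \code{n_quartets_total}, \code{ties} (list of co-optimal trees),
#'   \code{search = "exact"}.
#' @export
exact_species_tree <- function(genes, max_taxa = 9) {
  taxa <- sort(unique(unlist(lapply(genes, function(g) g$tip.label))))
  n <- length(taxa)
  if (n > max_taxa) stop("refusing exhaustive search over ", n, " taxa")
  if (n < 4) stop("need >= 4 taxa")
  quartets <- combn(n, 4)
  tally <- gene_code_tally(genes, taxa, quartets)
  topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
  scores <- vapply(topos, tally_score, 1, taxa = taxa, quartets = quartets,
                   tally = tally)
  best <- max(scores)
  ties <- which(scores == best)
  list(species_tree = topos[[ties[1]]], score = as.integer(best),
       n_quartets_total = length(genes) * ncol(quartets),
       ties = if (length(ties) > 1) topos[ties] else list(),
       search = "exact")
}

# mean topological internode distance across genes (pairs never co-occurring
# in a gene are an error)
mean_gene_distance <- function(genes, taxa) {
  n <- length(taxa)
  acc <- cnt <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (g in genes) {
    D <- unit_cophenetic(g)
    tx <- intersect(taxa, rownames(D))
    acc[tx, tx] <- acc[tx, tx] + D[tx, tx]
    cnt[tx, tx] <- cnt[tx, tx] + 1
  }
  off <- upper.tri(cnt)
  if (any(cnt[off] == 0)) stop("taxon pair never co-occurs in any gene tree")
  out <- acc / pmax(cnt, 1)
  diag(out) <- 0
  out
}

#' Heuristic quartet-agreement species tree (NNI hill climbing)
#'
#' Starts from neighbor joining on the mean topological internode distance
#' across gene trees and accepts the best-scoring NNI neighbor until no
#' neighbor improves the quartet score. Deterministic given \code{seed}
#' (first-found tie-breaking).
#'
#' @param genes list of \code{phylo} gene trees.
#' @param seed integer seed.
#' @return list as in \code{\link{exact_species_tree}} with
#'   \code{search = "heuristic"}.
#' @export
heuristic_species_tree <- function(genes, seed = 1) {
  set.seed(seed)
  taxa <- sort(unique(unlist(lapply(genes, function(g) g$tip.label))))
  n <- length(taxa)
  if (n < 4) stop("need >= 4 taxa")
  quartets <- combn(n, 4)
  tally <- gene_code_tally(genes, taxa, quartets)
  cur <- ape::unroot(nj_tree(mean_gene_distance(genes, taxa)))
  cur$edge.length <- NULL
  cur_score <- tally_score(cur, taxa, quartets, tally)
  repeat {
    nbrs <- phangorn::nni(cur)
    sc <- vapply(nbrs, tally_score, 1, taxa = taxa, quartets = quartets,
                 tally = tally)
    if (max(sc) <= cur_score) break
    cur <- nbrs[[which.max(sc)]]
    cur_score <- max(sc)
  }
  list(species_tree = cur, score = as.integer(cur_score),
       n_quartets_total = length(genes) * ncol(quartets),
       ties = list(), search = "heuristic")
}
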