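# shared builders and independent oracles used across test files

aln_from_strings <- function(seqs, molecule = "nucleotide") {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- names(seqs)
  new_alignment(m, molecule)
}

random_nt_alignment <- function(n_taxa, n_cols, seed = 1, gap_frac = 0) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  m <- matrix(sample(pool, n_taxa * n_cols, replace = TRUE), n_taxa, n_cols,
              dimnames = list(sprintf("t%02d", seq_len(n_taxa)), NULL))
  if (gap_frac > 0)
    m[sample(length(m), round(gap_frac * length(m)))] <- "-"
  new_alignment(m, "nucleotide")
}

# --- independent oracles -------------------------------------------------

# TIGER by direct nested loops over ordered column pairs and blocks
tiger_brute <- function(aln) {
  enc <- lbalens:::encode_states(aln)
  L <- ncol(enc)
  pa <- function(i, j) {
    keep <- enc[, j] != 0L
    if (!any(keep)) return(NA_real_)
    blocks <- split(which(keep), enc[keep, j])
    ok <- 0
    for (b in blocks) {
      st <- enc[b, i]
      if (all(st != 0L) && length(unique(st)) == 1L) ok <- ok + 1
    }
    ok / length(blocks)
  }
  vapply(seq_len(L), function(i) {
    vals <- vapply(setdiff(seq_len(L), i), function(j) pa(i, j), 1)
    1 - mean(vals, na.rm = TRUE)
  }, 1)
}

# Fitch parsimony by minimizing over all internal-node state assignments
fitch_brute <- function(tree, aln) {
  stopifnot(!ape::is.rooted(tree) || TRUE)
  enc <- lbalens:::encode_states(aln)
  edges <- tree$edge
  ntip <- length(tree$tip.label)
  internal <- sort(unique(edges[edges > ntip]))
  tipidx <- match(tree$tip.label, rownames(enc))
  total <- 0L
  for (col in seq_len(ncol(enc))) {
    tipstates <- enc[tipidx, col]
    grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
    best <- Inf
    for (g in seq_len(nrow(grid))) {
      assign <- grid[g, ]
      state_of <- function(node) {
        if (node <= ntip) tipstates[node] else assign[match(node, internal)]
      }
      cost <- 0L
      for (e in seq_len(nrow(edges))) {
        a <- edges[e, 1]; b <- edges[e, 2]
        if (b <= ntip && tipstates[b] == 0L) next      # missing tip: free
        if (state_of(a) != state_of(b)) cost <- cost + 1L
      }
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}

# pruning likelihood by brute-force summation over internal states
loglik_brute <- function(tree, aln, params, k = 4) {
  bf <- params$bf / sum(params$bf)
  Q <- lbalens:::gtr_q_matrix(params$rates, bf)
  cats <- if (!is.null(params$shape)) phangorn::discrete.gamma(params$shape, k) else 1
  rt <- if (!ape::is.rooted(tree)) ape::root(tree, tree$tip.label[1],
                                             resolve.root = TRUE) else tree
  edges <- rt$edge; len <- rt$edge.length
  ntip <- length(rt$tip.label)
  internal <- sort(unique(edges[edges > ntip]))
  enc <- lbalens:::encode_states(aln)
  tipidx <- match(rt$tip.label, rownames(enc))
  root <- ntip + 1L
  ll <- 0
  for (col in seq_len(ncol(enc))) {
    site_lik <- 0
    for (r in cats) {
      P <- lapply(len, function(t) Matrix::expm(Q * t * r))
      grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign <- grid[g, ]
        state_of <- function(node)
          if (node <= ntip) enc[tipidx[node], col] else assign[match(node, internal)]
        pr <- bf[state_of(root)]
        for (e in seq_len(nrow(edges))) {
          a <- state_of(edges[e, 1]); b <- state_of(edges[e, 2])
          if (b == 0) next                              # missing tip
          pr <- pr * as.matrix(P[[e]])[a, b]
        }
        lik <- lik + pr
      }
      site_lik <- site_lik + lik / length(cats)
    }
    ll <- ll + log(site_lik)
  }
  ll
}

# quartet topology via repeated topology comparison (independent of the
# four-point-condition route used by the package)
induced_quartet_rf <- function(tree, q) {
  sub <- ape::unroot(ape::keep.tip(tree, q))
  refs <- lapply(list(c(q[1], q[2], q[3], q[4]),
                      c(q[1], q[3], q[2], q[4]),
                      c(q[1], q[4], q[2], q[3])),
                 function(p) ape::read.tree(text = sprintf("((%s,%s),%s,%s);",
                                                           p[1], p[2], p[3], p[4])))
  if (sub$Nnode < 2) return(0L)
  hits <- vapply(refs, function(r) phangorn::RF.dist(sub, r) == 0, logical(1))
  if (!any(hits)) 0L else which(hits)
}

quartet_score_brute <- function(species, genes) {
  taxa <- species$tip.label
  qs <- combn(taxa, 4)
  total <- 0L
  for (g in genes) for (j in seq_len(ncol(qs))) {
    q <- qs[, j]
    if (!all(q %in% g$tip.label)) next
    cg <- induced_quartet_rf(g, q)
    cs <- induced_quartet_rf(species, q)
    if (cg != 0L && cg == cs) total <- total + 1L
  }
  total
}
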