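# Substitution-saturation diagnostics: pairwise distances, entropy-based
# Iss with Monte Carlo critical values, patristic-vs-p regression and
# density-valley flagging of saturated genes.

#' Uncorrected p-distance matrix
#'
#' d(i, j) = mismatches / compared sites over the columns where both taxa
#' carry unambiguous characters. Pairs with zero comparable columns get
#' \code{NA} and are listed in the \code{"undefined_pairs"} attribute.
#'
#' @param aln an \code{lba_alignment} with >= 2 taxa.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  if (n_taxa(aln) < 2) stop("need >= 2 taxa")
  enc <- encode_states(aln)
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  undef <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- enc[i, ] != 0L & enc[j, ] != 0L
    m <- sum(ok)
    if (m == 0) {
      d[i, j] <- d[j, i] <- NA_real_
      undef <- c(undef, paste(rownames(enc)[c(i, j)], collapse = ":"))
    } else {
      d[i, j] <- d[j, i] <- sum(enc[i, ok] != enc[j, ok]) / m
    }
  }
  attr(d, "undefined_pairs") <- undef
  d
}

# 4x4 count matrix of aligned unambiguous state pairs for one taxon pair
pair_counts <- function(enc, i, j) {
  ok <- enc[i, ] != 0L & enc[j, ] != 0L
  if (!any(ok)) return(matrix(0, 4, 4))
  tab <- table(factor(enc[i, ok], levels = 1:4), factor(enc[j, ok], levels = 1:4))
  matrix(as.numeric(tab), 4, 4)
}

# GTR rate matrix from 6 exchangeabilities (AC, AG, AT, CG, CT, GT) and
# base frequencies, normalized to mean rate 1
gtr_q_matrix <- function(rates, bf) {
  stopifnot(length(rates) == 6, length(bf) == 4, all(rates > 0), all(bf > 0))
  bf <- bf / sum(bf)
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- rates[1]; Q[1, 3] <- rates[2]; Q[1, 4] <- rates[3]
  Q[2, 3] <- rates[4]; Q[2, 4] <- rates[5]; Q[3, 4] <- rates[6]
  Q <- Q + t(Q)
  Q <- Q %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(bf * diag(Q))
  Q / mu
}

# eigen machinery for P(t) = exp(Qt); GTR Q is diagonalizable via the
# symmetrizing transform diag(sqrt(bf)) Q diag(1/sqrt(bf))
gtr_eigen <- function(Q, bf) {
  s <- sqrt(bf)
  S <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(vals = e$values,
       right = diag(1 / s) %*% e$vectors,
       left = t(e$vectors) %*% diag(s))
}

gtr_pmat <- function(eig, t) {
  P <- eig$right %*% (exp(eig$vals * t) * eig$left)
  P[P < 1e-12] <- 1e-12
  P
}

#' Estimate GTR(+Gamma) model parameters from an alignment
#'
#' Fits GTR exchangeabilities, empirical base frequencies and (optionally) a
#' discrete-Gamma shape on a neighbor-joining starting tree by maximum
#' likelihood. Intended to be run once per supermatrix and reused wherever a
#' distance model is needed.
#'
#' @param aln nucleotide \code{lba_alignment}.
#' @param gamma logical; also estimate the Gamma shape (4 categories).
#' @return list with \code{rates}, \code{bf}, \code{shape} (NULL when
#'   \code{gamma = FALSE}), \code{k} and the fitted log-likelihood.
#' @export
estimate_gtr_params <- function(aln, gamma = TRUE) {
  dat <- as_phyDat(aln)
  dm <- ape::dist.dna(as_DNAbin(aln), model = "JC69", pairwise.deletion = TRUE)
  dm[!is.finite(dm)] <- max(dm[is.finite(dm)], 0.1) * 1.5
  tr <- ape::nj(dm)
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  fit <- phangorn::pml(tr, dat, k = if (gamma) 4L else 1L)
  fit <- phangorn::optim.pml(fit, optEdge = TRUE, optBf = TRUE, optQ = TRUE,
                             optGamma = gamma, model = "GTR",
                             control = phangorn::pml.control(trace = 0))
  list(rates = fit$Q, bf = fit$bf,
       shape = if (gamma) fit$shape else NULL,
       k = if (gamma) 4L else 1L, logLik = as.numeric(logLik(fit)))
}

# negative log-likelihood of one pair at distance t given counts N
pair_negll <- function(t, N, bf, eig, cat_rates) {
  P <- matrix(0, 4, 4)
  for (r in cat_rates) P <- P + gtr_pmat(eig, r * t) / length(cat_rates)
  -sum(N * log(bf * P))
}

#' Pairwise maximum-likelihood distance matrix
#'
#' JC69 and K80 use the closed forms (via \code{ape::dist.dna}); GTR and
#' GTR+G maximize the pairwise likelihood numerically under model parameters
#' estimated once on the whole matrix (or supplied). Pairs whose optimum hits
#' the ceiling are capped at \code{d_max} and flagged in the
#' \code{"capped_pairs"} attribute.
#'
#' @param aln nucleotide \code{lba_alignment}.
#' @param model one of \code{"JC69"}, \code{"K80"}, \code{"GTR"},
#'   \code{"GTR+G"}.
#' @param params optional list from \code{\link{estimate_gtr_params}}.
#' @param d_max saturation cap in substitutions/site (default 5).
#' @return Symmetric numeric matrix of ML distances.
#' @export
ml_distance_matrix <- function(aln, model = c("GTR+G", "GTR", "JC69", "K80"),
                               params = NULL, d_max = 5) {
  model <- match.arg(model)
  if (model %in% c("JC69", "K80")) {
    d <- as.matrix(ape::dist.dna(as_DNAbin(aln), model = model,
                                 pairwise.deletion = TRUE))
    capped <- which(!is.finite(d) | d > d_max, arr.ind = TRUE)
    d[!is.finite(d) | d > d_max] <- d_max
    attr(d, "capped_pairs") <- capped
    return(d)
  }
  if (is.null(params)) params <- estimate_gtr_params(aln, gamma = model == "GTR+G")
  bf <- params$bf / sum(params$bf)
  Q <- gtr_q_matrix(params$rates, bf)
  eig <- gtr_eigen(Q, bf)
  cat_rates <- if (model == "GTR+G" && !is.null(params$shape))
    phangorn::discrete.gamma(params$shape, params$k) else 1
  enc <- encode_states(aln)
  n <- nrow(enc)
  d <- matrix(0, n, n, dimnames = list(rownames(enc), rownames(enc)))
  capped <- character(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    N <- pair_counts(enc, i, j)
    if (sum(N) == 0) { d[i, j] <- d[j, i] <- NA_real_; next }
    if (sum(N) == sum(diag(N))) next   # identical where comparable -> 0
    opt <- optimize(pair_negll, c(1e-8, d_max), N = N, bf = bf, eig = eig,
                    cat_rates = cat_rates, tol = 1e-8)
    t_hat <- opt$minimum
    if (t_hat > d_max * 0.99) {
      t_hat <- d_max
      capped <- c(capped, paste(rownames(enc)[c(i, j)], collapse = ":"))
    }
    d[i, j] <- d[j, i] <- t_hat
  }
  attr(d, "capped_pairs") <- capped
  d
}

#' Patristic distance matrix of a tree
#'
#' d(i, j) is the sum of branch lengths along the unique path between leaves
#' i and j.
#'
#' @param tree a \code{phylo} with branch lengths on all edges.
#' @return Symmetric numeric matrix over the tree's tip labels.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("incomplete tree: branch lengths missing")
  as.matrix(stats::cophenetic(tree))
}

#' Saturation regression of p-distance on patristic distance
#'
#' Ordinary least squares of the uncorrected p-distance (response) on the
#' patristic distance (predictor) over all unordered taxon pairs. A shallow
#' slope and low R-squared indicate multiple substitutions: the observed
#' differences stop growing with the tree distance.
#'
#' @param patristic,p symmetric matrices over the same taxon set.
#' @return list with \code{slope}, \code{R2}, \code{intercept},
#'   \code{n_pairs}.
#' @export
saturation_regression <- function(patristic, p) {
  taxa <- rownames(patristic)
  if (!setequal(taxa, rownames(p))) stop("matrices over different taxon sets")
  p <- p[taxa, taxa]
  if (nrow(patristic) < 3) stop("need >= 3 taxa")
  ut <- upper.tri(patristic)
  x <- patristic[ut]; y <- p[ut]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0) stop("degenerate regression: zero variance in patristic distances")
  fit <- lm(y ~ x)
  r2 <- if (var(y) == 0) 0 else cor(x, y)^2
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       R2 = r2, n_pairs = length(x))
}

# exact expected per-site entropy of n i.i.d. draws from frequencies q:
# by linearity, E[H] = sum_s sum_c P(c_s = c) * (-(c/n) log2(c/n)) with
# c_s ~ Binomial(n, q_s). This is the full-saturation reference entropy for
# a finite number of sequences (the plug-in population entropy -sum q log2 q
# is only its n -> infinity limit).
expected_entropy_full_saturation <- function(q, n) {
  q <- q[q > 0]
  cs <- 1:n
  term <- -(cs / n) * log2(cs / n)
  sum(vapply(q, function(p) sum(stats::dbinom(cs, n, p) * term), 1))
}

#' Entropy-based substitution saturation index (Iss)
#'
#' Per-site entropy H_k = -sum f_ks log2 f_ks over the unambiguous state
#' frequencies of site k; H is the mean over sites. H_FSS is the expected
#' per-site entropy at full substitution saturation — sites i.i.d. from the
#' alignment-wide base frequencies — computed exactly for the alignment's
#' number of taxa (a finite-sample quantity below the population entropy of
#' the base frequencies). Iss = H / H_FSS, so fully randomized data score 1
#' regardless of taxon count. Degenerate single-state alignments report
#' Iss = 0 with \code{degenerate = TRUE}.
#'
#' @param aln nucleotide \code{lba_alignment}.
#' @return list with \code{H}, \code{H_FSS}, \code{Iss}, \code{n_taxa},
#'   \code{n_sites}, \code{degenerate}.
#' @export
iss_index <- function(aln) {
  counts <- state_counts(aln)
  n_un <- colSums(counts)
  keep <- n_un > 0
  f <- sweep(counts[, keep, drop = FALSE], 2, n_un[keep], "/")
  Hk <- -colSums(ifelse(f > 0, f * log2(f), 0))
  H <- if (any(keep)) mean(Hk) else 0
  q <- rowSums(counts) / sum(counts)
  degenerate <- sum(q > 0) <= 1
  H_FSS <- if (degenerate) 0 else expected_entropy_full_saturation(q, n_taxa(aln))
  list(H = H, H_FSS = H_FSS,
       Iss = if (degenerate) 0 else H / H_FSS,
       n_taxa = n_taxa(aln), n_sites = n_cols(aln), degenerate = degenerate)
}

# mean Iss over random 4-taxon subsamples (observed Iss at the 4-taxon scale
# the Monte Carlo critical values are simulated at)
iss_4taxon <- function(aln, n_subsamples) {
  n <- n_taxa(aln)
  if (n == 4) return(iss_index(aln)$Iss)
  mean(replicate(n_subsamples,
                 iss_index(select_rows(aln, sample.int(n, 4)))$Iss))
}

select_rows <- function(aln, idx) {
  structure(list(matrix = aln$matrix[idx, , drop = FALSE],
                 molecule = aln$molecule), class = "lba_alignment")
}

#' Monte Carlo substitution-saturation test
#'
#' Estimates the critical index Iss.c by simulation: alignments of the same
#' length and base composition are evolved on 4-taxon symmetric and
#' asymmetric (Felsenstein-zone-shaped) trees over a grid of tree depths;
#' Iss.c is the mean Iss at the depth where neighbor-joining stops recovering
#' the true topology in 95\% of replicates (linear interpolation between grid
#' points). The observed Iss (averaged over random 4-taxon subsamples when
#' the alignment has more than 4 taxa) is compared to Iss.c by a z-test with
#' a site-bootstrap standard error; a gene is flagged saturated when Iss is
#' significantly \emph{above} Iss.c.
#'
#' @param aln nucleotide \code{lba_alignment} with >= 4 taxa.
#' @param reps simulation replicates per grid depth (>= 100 recommended).
#' @param seed integer seed; fixes all randomness.
#' @param n_subsamples 4-taxon subsamples for the observed Iss (> 4 taxa).
#' @param n_boot site-bootstrap replicates for the standard error.
#' @param depths grid of tree depths (expected substitutions root-to-tip).
#' @param alpha significance level for the saturated flag.
#' @return list with the \code{iss_index} fields plus \code{Iss_obs} (4-taxon
#'   scale), \code{Iss_c_sym}, \code{Iss_c_asym}, \code{p_sym},
#'   \code{p_asym}, \code{se}, \code{saturated}.
#' @export
iss_test <- function(aln, reps = 200, seed = 1, n_subsamples = 20,
                     n_boot = 100, depths = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2),
                     alpha = 0.05) {
  if (n_taxa(aln) < 4) stop("Iss test needs >= 4 taxa")
  if (reps < 100) warning("unstable estimate: reps < 100")
  set.seed(seed)
  base <- iss_index(aln)
  bf <- rowSums(state_counts(aln))
  bf <- (bf + 0.5) / sum(bf + 0.5)   # pseudocount keeps the simulator valid
  L <- n_cols(aln)
  model <- list(rates = rep(1, 6), bf = bf, shape = NULL, k = 1L)

  run_grid <- function(shape_fun) {
    iss_mean <- recov <- numeric(length(depths))
    for (d in seq_along(depths)) {
      tr <- shape_fun(depths[d])
      iss_r <- rec_r <- numeric(reps)
      for (r in seq_len(reps)) {
        sim <- simulate_alignment(tr, model, L, seed = sample.int(2^31 - 1, 1))
        iss_r[r] <- iss_index(sim)$Iss
        dm <- ml_distance_matrix(sim, "JC69")
        est <- ape::nj(as.dist(dm))
        rec_r[r] <- as.integer(phangorn::RF.dist(ape::unroot(est), ape::unroot(tr)) == 0)
      }
      iss_mean[d] <- mean(iss_r); recov[d] <- mean(rec_r)
    }
    crossing <- which(recov < 0.95)
    if (length(crossing) == 0) return(list(iss_c = max(iss_mean), hit = FALSE))
    i <- crossing[1]
    if (i == 1) return(list(iss_c = iss_mean[1], hit = TRUE))
    w <- (0.95 - recov[i - 1]) / (recov[i] - recov[i - 1])
    list(iss_c = iss_mean[i - 1] + w * (iss_mean[i] - iss_mean[i - 1]), hit = TRUE)
  }

  sym <- run_grid(function(t) ape::read.tree(text = sprintf(
    "((A:%f,B:%f):%f,(C:%f,D:%f):%f);", t / 2, t / 2, t / 2, t / 2, t / 2, t / 2)))
  asym <- run_grid(function(t) felsenstein_zone_tree(t, t / 8))

  obs <- iss_4taxon(aln, n_subsamples)
  boot <- replicate(n_boot, {
    idx <- sample.int(L, L, replace = TRUE)
    iss_4taxon(select_columns(aln, idx), max(1, n_subsamples %/% 2))
  })
  se <- stats::sd(boot)
  zp <- function(iss_c) {
    if (se <= 0) return(if (obs > iss_c) 0 else 1)
    stats::pnorm((obs - iss_c) / se, lower.tail = FALSE)
  }
  p_sym <- zp(sym$iss_c); p_asym <- zp(asym$iss_c)
  c(base, list(Iss_obs = obs, Iss_c_sym = sym$iss_c, Iss_c_asym = asym$iss_c,
               p_sym = p_sym, p_asym = p_asym, se = se,
               saturated = (p_sym < alpha) && (p_asym < alpha)))
}

#' Flag saturated genes from per-gene slope or R-squared values
#'
#' Valley method: a Gaussian kernel density (Silverman bandwidth) is fitted
#' over the gene values; genes below the deepest density minimum (antimode)
#' left of the global mode are flagged — the "left shoulder" of the density.
#' When no antimode exists the percentile method is used with a message.
#'
#' @param values named numeric vector of per-gene statistics.
#' @param method \code{"valley"} or \code{"percentile"}.
#' @param param percentile (0-100) for the percentile method / fallback.
#' @return list with \code{flagged} (names), \code{cut}, \code{method}.
#' @export
flag_saturated_genes <- function(values, method = c("valley", "percentile"),
                                 param = 15) {
  method <- match.arg(method)
  if (length(values) < 5) stop("need >= 5 genes")
  if (is.null(names(values))) names(values) <- paste0("g", seq_along(values))
  percentile_cut <- function() {
    cut <- quantile(values, param / 100, names = FALSE)
    list(flagged = names(values)[values <= cut], cut = cut,
         method = "percentile")
  }
  if (method == "percentile") return(percentile_cut())
  den <- density(values, bw = "nrd0")
  mode_i <- which.max(den$y)
  y <- den$y
  is_min <- c(FALSE, y[2:(length(y) - 1)] < y[1:(length(y) - 2)] &
                y[2:(length(y) - 1)] <= y[3:length(y)], FALSE)
  left_min <- which(is_min & seq_along(y) < mode_i)
  if (length(left_min) == 0) {
    message("no antimode left of the mode; falling back to percentile ", param)
    return(percentile_cut())
  }
  cut <- den$x[left_min[which.min(y[left_min])]]
  flagged <- names(values)[values < cut]
  if (length(flagged) == 0) {
    message("no genes below the antimode; falling back to percentile ", param)
    return(percentile_cut())
  }
  list(flagged = flagged, cut = cut, method = "valley")
}

#' Per-gene saturation report
#'
#' For each gene of a supermatrix, computes the patristic-vs-p regression
#' (on a neighbor-joining tree built from that gene's ML distances) and
#' optionally the Iss test, mirroring a per-gene saturation screen.
#'
#' @param aln supermatrix \code{lba_alignment}.
#' @param pm its \code{lba_partition_map}.
#' @param params model parameters reused for all genes
#'   (\code{\link{estimate_gtr_params}}); \code{NULL} to estimate once here.
#' @param iss logical; also run \code{\link{iss_test}} per gene (slow).
#' @param ... passed to \code{\link{iss_test}}.
#' @return data frame with one row per gene: slope, R2, and when requested
#'   Iss, Iss.c values, p-values and the saturated flag.
#' @export
gene_saturation_report <- function(aln, pm, params = NULL, iss = FALSE, ...) {
  if (is.null(params)) params <- estimate_gtr_params(aln)
  rows <- lapply(seq_len(nrow(pm)), function(g) {
    sub <- subset_genes(aln, pm, pm$gene[g], "keep")$alignment
    dml <- ml_distance_matrix(sub, "GTR+G", params = params)
    dp <- p_distance_matrix(sub)
    dml_f <- dml; dml_f[!is.finite(dml_f)] <- max(dml_f[is.finite(dml_f)])
    tr <- nj_tree(dml_f)
    reg <- saturation_regression(patristic_matrix(tr), dp)
    row <- data.frame(gene = pm$gene[g], slope = reg$slope, R2 = reg$R2)
    if (iss) {
      it <- iss_test(sub, ...)
      row$Iss <- it$Iss; row$Iss_obs <- it$Iss_obs
      row$Iss_c_sym <- it$Iss_c_sym; row$Iss_c_asym <- it$Iss_c_asym
      row$p_sym <- it$p_sym; row$p_asym <- it$p_asym
      row$saturated <- it$saturated
    }
    row
  })
  do.call(rbind, rows)
}
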