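# Tree-independent per-column rate metrics and site classification.
#
# OV (observed variability) scores a column by the fraction of taxon pairs
# that differ; TIGER scores it by the average agreement between the set
# partitions of taxa that columns induce. Both treat gaps and ambiguity
# codes as missing: such taxa are excluded from pair counts and partitions.

# counts of unambiguous states per column: K x L matrix
state_counts <- function(aln) {
  enc <- encode_states(aln)
  K <- length(alphabet_for(aln$molecule)$unambig)
  L <- ncol(enc)
  counts <- matrix(0L, nrow = K, ncol = L)
  for (s in seq_len(K)) counts[s, ] <- colSums(enc == s)
  counts
}

#' Classify alignment columns by parsimony informativeness
#'
#' A column is \emph{parsimony-informative} iff at least two distinct
#' unambiguous states each occur in at least two taxa; \emph{constant} iff at
#' most one distinct unambiguous state occurs (empty columns count as
#' constant); otherwise \emph{variable-uninformative}. Gaps and ambiguity
#' codes are ignored for state counting.
#'
#' @param aln an \code{lba_alignment}.
#' @return A data frame (class \code{lba_site_table}) with columns
#'   \code{column} and \code{class}, carrying a \code{summary} attribute with
#'   total, variable and parsimony-informative counts.
#' @export
classify_sites <- function(aln) {
  if (n_cols(aln) == 0) stop("empty alignment")
  counts <- state_counts(aln)
  n_states <- colSums(counts > 0L)
  n_ge2 <- colSums(counts >= 2L)
  cls <- ifelse(n_states <= 1L, "constant",
                ifelse(n_ge2 >= 2L, "parsimony-informative",
                       "variable-uninformative"))
  out <- data.frame(column = seq_len(n_cols(aln)),
                    class = factor(cls, levels = c("constant",
                                                   "variable-uninformative",
                                                   "parsimony-informative")))
  attr(out, "summary") <- c(total = n_cols(aln),
                            variable = sum(cls != "constant"),
                            pis = sum(cls == "parsimony-informative"))
  class(out) <- c("lba_site_table", "data.frame")
  out
}

#' Observed variability (OV) per column
#'
#' For each column, OV is the number of unordered taxon pairs with differing
#' states divided by the number of comparable pairs; only pairs where both
#' characters are unambiguous enter numerator and denominator. Columns with
#' fewer than two unambiguous characters score 0 and are flagged in the
#' \code{"undefined"} attribute.
#'
#' @param aln an \code{lba_alignment} with at least 2 taxa.
#' @return Numeric vector in \code{[0, 1]}, one score per column.
#' @export
ov_scores <- function(aln) {
  if (n_taxa(aln) < 2) stop("OV needs at least 2 taxa")
  counts <- state_counts(aln)
  n_un <- colSums(counts)
  denom <- choose(n_un, 2)
  same <- colSums(choose(counts, 2))
  ov <- ifelse(denom > 0, (denom - same) / denom, 0)
  attr(ov, "undefined") <- which(n_un < 2)
  ov
}

# set partition of taxa induced by a column: integer state per taxon, 0 = missing
# pa(P_i, P_j) = fraction of blocks of P_j that lie inside one block of P_i
partition_agreement <- function(enc_i, enc_j) {
  in_j <- enc_j != 0L
  if (!any(in_j)) return(NA_real_)
  states_j <- enc_j[in_j]
  states_i <- enc_i[in_j]
  blocks <- split(states_i, states_j)
  nested <- vapply(blocks, function(b) all(b != 0L) && length(unique(b)) == 1L,
                   logical(1))
  mean(nested)
}

#' TIGER relative rates per column
#'
#' Each column induces a set partition of the taxa by unambiguous state
#' (taxa with gaps or ambiguity codes are excluded from the partition). The
#' agreement of column i with column j is the fraction of j's blocks nested
#' inside a single block of i; the TIGER rate of column i is one minus its
#' mean agreement with all other columns, so larger means faster. Exact
#' O(L^2 n) computation.
#'
#' @param aln an \code{lba_alignment} with >= 3 taxa and >= 2 columns.
#' @return Numeric vector of rates in \code{[0, 1]}.
#' @export
tiger_rates <- function(aln) {
  if (n_taxa(aln) < 3) stop("TIGER needs at least 3 taxa")
  L <- n_cols(aln)
  if (L < 2) stop("TIGER needs at least 2 columns")
  enc <- encode_states(aln)
  # deduplicate identical column patterns: agreement depends only on patterns
  key <- apply(enc, 2, paste, collapse = ",")
  uniq <- !duplicated(key)
  ucols <- which(uniq)
  uenc <- enc[, ucols, drop = FALSE]
  weight <- as.vector(table(key)[key[ucols]])
  U <- length(ucols)
  pa <- matrix(NA_real_, U, U)
  for (a in seq_len(U))
    for (b in seq_len(U))
      if (a != b) pa[a, b] <- partition_agreement(uenc[, a], uenc[, b])
  rate_u <- numeric(U)
  for (a in seq_len(U)) {
    w <- weight
    agr <- pa[a, ]
    # column a agrees with the other (weight-1) copies of its own pattern at 1
    own <- weight[a] - 1
    tot <- sum(w[-a] * agr[-a], na.rm = TRUE) + own
    nn <- sum(w[-a][!is.na(agr[-a])]) + own
    rate_u[a] <- 1 - tot / nn
  }
  rate_u[match(key, key[ucols])]
}

#' Rank alignment columns by a rate score
#'
#' Stable sort with ties broken by original column index (ascending).
#'
#' @param scores numeric vector of per-column scores.
#' @param order \code{"fastest-first"} (decreasing score) or
#'   \code{"slowest-first"}.
#' @return Integer permutation of column indices.
#' @export
rank_sites <- function(scores, order = c("fastest-first", "slowest-first")) {
  order <- match.arg(order)
  if (order == "fastest-first") order(-scores, seq_along(scores))
  else order(scores, seq_along(scores))
}

#' Per-column site-rate table
#'
#' Convenience wrapper assembling site classes, OV scores, optional TIGER
#' rates and the fastest-first rank into one table.
#'
#' @param aln an \code{lba_alignment}.
#' @param tiger logical; also compute TIGER rates (quadratic in width).
#' @return A data frame with columns \code{column}, \code{class}, \code{ov},
#'   optionally \code{tiger}, and \code{rank} (fastest-first OV rank order).
#' @export
site_rate_table <- function(aln, tiger = FALSE) {
  tab <- classify_sites(aln)
  tab$ov <- as.numeric(ov_scores(aln))
  if (tiger) tab$tiger <- tiger_rates(aln)
  perm <- rank_sites(tab$ov, "fastest-first")
  tab$rank <- order(perm)
  tab
}

#' Split parsimony-informative sites into three rate tertiles
#'
#' The parsimony-informative (PIS) columns, sorted slowest-first by the
#' chosen rate, are split into three contiguous groups of equal size (any
#' remainder goes to the slow, then the medium group). Each output partition
#' consists of its PIS tertile plus \emph{all} variable parsimony-uninformative
#' columns (and, when \code{include_constant = TRUE}, the constant columns
#' too), emitted in original column order.
#'
#' @param aln an \code{lba_alignment}.
#' @param table a table from \code{\link{site_rate_table}} (with the needed
#'   rate column), or \code{NULL} to compute it.
#' @param method \code{"ov"} or \code{"tiger"}: which rate orders the PIS.
#' @param include_constant logical; also place constant columns in every
#'   partition (off by default).
#' @return list with \code{slow}, \code{medium}, \code{fast} alignments and a
#'   \code{report} data frame of per-partition column and PIS counts.
#' @export
tertile_partition <- function(aln, table = NULL, method = c("ov", "tiger"),
                              include_constant = FALSE) {
  method <- match.arg(method)
  if (is.null(table)) table <- site_rate_table(aln, tiger = method == "tiger")
  if (!method %in% names(table)) stop("table lacks '", method, "' rates")
  pis <- table$column[table$class == "parsimony-informative"]
  if (length(pis) < 3) stop("insufficient data: need >= 3 parsimony-informative columns")
  rate <- table[[method]][pis]
  ord <- pis[order(rate, pis)]             # slowest first, ties by column index
  n <- length(ord)
  base <- n %/% 3L; rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)
  groups <- split(ord, rep(1:3, times = sizes))
  filler <- table$column[table$class == "variable-uninformative"]
  if (include_constant) filler <- c(filler, table$column[table$class == "constant"])
  build <- function(g) select_columns(aln, sort(c(g, filler)))
  out <- lapply(groups, build)
  names(out) <- c("slow", "medium", "fast")
  out$report <- data.frame(
    partition = c("slow", "medium", "fast"),
    n_columns = vapply(out[1:3], n_cols, 1L),
    n_pis = vapply(groups, length, 1L),
    row.names = NULL)
  out
}
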