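# Codon-level matrix transformations: codon-position extraction and
# translation to amino acids.

# Standard genetic code (NCBI table 1). Table 11 (bacterial/plastid), the
# default for plastid protein-coding genes, has identical amino-acid
# assignments; the two tables differ only in permitted initiation codons,
# which do not matter for translating aligned coding sequence.
codon_table <- local({
  b <- c("T", "C", "A", "G")
  # NCBI ordering TTT, TTC, TTA, TTG, TCT, ... (first base varies slowest)
  codons <- apply(expand.grid(b3 = b, b2 = b, b1 = b)[, 3:1], 1, paste0, collapse = "")
  aa <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]
  setNames(aa, codons)
})

gene_intervals <- function(pm, width) {
  if (is.null(pm)) return(list(c(0L, width)))
  if (pm_width(pm) != width || pm$start[1] != 0L ||
      any(pm$start[-1] != pm$end[-nrow(pm)]))
    stop("partition map does not contiguously cover the alignment")
  mapply(function(s, e) c(s, e), pm$start, pm$end, SIMPLIFY = FALSE)
}

#' Extract codon positions from a coding alignment
#'
#' Retains the requested within-codon positions (1, 2 and/or 3) of every
#' codon, preserving column order. The reading frame starts at the first
#' column of each gene; when a partition map is supplied the frame (width
#' divisible by 3) is enforced per gene, otherwise on the whole matrix.
#'
#' @param aln nucleotide \code{lba_alignment}.
#' @param keep integer subset of \code{c(1, 2, 3)}.
#' @param pm optional \code{lba_partition_map} giving gene boundaries.
#' @return An \code{lba_alignment} of width \code{length(keep)/3} times the
#'   input width.
#' @export
extract_codon_positions <- function(aln, keep = c(1, 2), pm = NULL) {
  stopifnot(aln$molecule == "nucleotide")
  keep <- sort(unique(as.integer(keep)))
  if (!all(keep %in% 1:3) || length(keep) == 0) stop("keep must be a subset of 1:3")
  ivs <- gene_intervals(pm, n_cols(aln))
  idx <- unlist(lapply(ivs, function(iv) {
    w <- iv[2] - iv[1]
    if (w %% 3L != 0L) stop("frame error: gene width ", w, " not divisible by 3")
    pos <- rep(1:3, length.out = w)
    iv[1] + which(pos %in% keep)
  }))
  select_columns(aln, idx)
}

#' Translate a codon alignment to amino acids
#'
#' Each codon becomes one amino-acid column. A codon containing any gap
#' translates to a gap (so amino-acid gap structure mirrors the nucleotide
#' indels); a codon containing an ambiguity code translates to \code{X};
#' internal stop codons translate to \code{*} and their count is reported
#' with a warning.
#'
#' @param aln nucleotide \code{lba_alignment}, width divisible by 3 per gene.
#' @param table_id genetic-code table: \code{"11"} (bacterial/plastid,
#'   default) or \code{"1"} (standard); both assign identical amino acids.
#' @param pm optional partition map for per-gene frame checking.
#' @return An amino-acid \code{lba_alignment} of width \code{n_cols(aln)/3}.
#' @export
translate_codon_alignment <- function(aln, table_id = "11", pm = NULL) {
  stopifnot(aln$molecule == "nucleotide")
  if (!as.character(table_id) %in% c("1", "11"))
    stop("unsupported genetic-code table: ", table_id)
  ivs <- gene_intervals(pm, n_cols(aln))
  for (iv in ivs)
    if ((iv[2] - iv[1]) %% 3L != 0L)
      stop("frame error: gene width ", iv[2] - iv[1], " not divisible by 3")
  m <- aln$matrix
  L <- ncol(m) %/% 3L
  p1 <- m[, seq(1L, by = 3L, length.out = L), drop = FALSE]
  p2 <- m[, seq(2L, by = 3L, length.out = L), drop = FALSE]
  p3 <- m[, seq(3L, by = 3L, length.out = L), drop = FALSE]
  cod <- matrix(paste0(p1, p2, p3), nrow = nrow(m))
  aa <- codon_table[cod]
  dim(aa) <- dim(cod)
  has_gap <- p1 == "-" | p2 == "-" | p3 == "-"
  aa[is.na(aa)] <- "X"      # any ambiguity code in the codon
  aa[has_gap] <- "-"
  n_stop <- sum(aa == "*")
  if (n_stop > 0) warning(n_stop, " internal stop codon(s) translated to '*'")
  rownames(aa) <- rownames(m)
  new_alignment(aa, "amino-acid")
}
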