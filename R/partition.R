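#' Construct a partition map
#'
#' A partition map assigns named genes to column intervals of a supermatrix.
#' Intervals are stored 0-based half-open, must be sorted, non-overlapping,
#' and gene names unique.
#'
#' @param gene character vector of gene names.
#' @param start,end integer vectors, 0-based half-open interval bounds.
#' @return An object of class \code{lba_partition_map} (a data frame with
#'   columns \code{gene}, \code{start}, \code{end}).
#' @export
new_partition_map <- function(gene, start, end) {
  stopifnot(length(gene) == length(start), length(start) == length(end))
  if (anyDuplicated(gene)) stop("duplicate gene names")
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) stop("range error: end < start")
  if (length(start) > 1) {
    if (is.unsorted(start)) stop("intervals must be sorted")
    if (any(start[-1] < end[-length(end)])) stop("overlapping intervals")
  }
  structure(data.frame(gene = as.character(gene), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("lba_partition_map", "data.frame"))
}

#' Read a RAxML-style partition file
#'
#' Lines of the form \code{"DNA, rbcL = 1-1428"} with 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path file path.
#' @return An \code{lba_partition_map}.
#' @export
read_partition_map <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  m <- regmatches(lines, regexec(
    "^[A-Za-z]+\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable partition line: ", lines[bad][1])
  gene <- vapply(m, `[`, "", 2L)
  start1 <- as.integer(vapply(m, `[`, "", 3L))
  end1 <- as.integer(vapply(m, `[`, "", 4L))
  if (any(end1 < start1)) stop("range error: end < start in partition file")
  new_partition_map(gene, start1 - 1L, end1)
}

#' Write a partition map in RAxML dialect
#' @param pm an \code{lba_partition_map}.
#' @param path output path.
#' @param datatype model keyword written before each gene (default "DNA").
#' @return \code{path}, invisibly.
#' @export
write_partition_map <- function(pm, path, datatype = "DNA") {
  writeLines(sprintf("%s, %s = %d-%d", datatype, pm$gene, pm$start + 1L, pm$end), path)
  invisible(path)
}

#' Total width covered by a partition map
#' @param pm an \code{lba_partition_map}.
#' @return integer number of columns.
#' @export
pm_width <- function(pm) sum(pm$end - pm$start)

#' Concatenate gene alignments into a supermatrix
#'
#' All alignments must share an identical taxon set (order taken from the
#' first) and molecule type. Columns are appended in the given order and a
#' partition map recording each gene's interval is returned alongside.
#'
#' @param alignments list of \code{lba_alignment} objects.
#' @param names character vector of gene names, one per alignment.
#' @return list with elements \code{alignment} and \code{map}.
#' @export
concatenate_alignments <- function(alignments, names) {
  stopifnot(length(alignments) == length(names), length(alignments) >= 1)
  tx <- taxa_labels(alignments[[1]])
  mol <- alignments[[1]]$molecule
  for (a in alignments) {
    if (a$molecule != mol) stop("incompatible molecule types")
    if (!setequal(taxa_labels(a), tx)) stop("incompatible taxa: taxon sets differ")
  }
  mats <- lapply(alignments, function(a) a$matrix[tx, , drop = FALSE])
  big <- do.call(cbind, mats)
  w <- vapply(alignments, n_cols, 1L)
  end <- cumsum(w)
  start <- c(0L, head(end, -1L))
  list(alignment = new_alignment(big, mol),
       map = new_partition_map(names, start, end))
}

#' Keep or drop named genes from a supermatrix
#'
#' Returns the concatenation of the selected genes' columns in their original
#' order together with a rebuilt partition map.
#'
#' @param aln supermatrix \code{lba_alignment}.
#' @param pm its \code{lba_partition_map}.
#' @param genes character vector of gene names.
#' @param mode \code{"keep"} or \code{"drop"}.
#' @return list with elements \code{alignment} and \code{map}.
#' @export
subset_genes <- function(aln, pm, genes, mode = c("keep", "drop")) {
  mode <- match.arg(mode)
  unknown <- setdiff(genes, pm$gene)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  sel <- if (mode == "keep") pm$gene %in% genes else !(pm$gene %in% genes)
  keep <- pm[sel, , drop = FALSE]
  idx <- unlist(mapply(function(s, e) if (e > s) (s + 1L):e else integer(0),
                       keep$start, keep$end, SIMPLIFY = FALSE))
  out <- select_columns(aln, if (length(idx)) idx else integer(0))
  w <- keep$end - keep$start
  end <- cumsum(w)
  start <- if (length(w)) c(0L, head(end, -1L)) else integer(0)
  list(alignment = out,
       map = new_partition_map(keep$gene, as.integer(start), as.integer(end)))
}
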