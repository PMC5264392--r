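#' @importFrom stats cophenetic cor density lm median optimize quantile rexp runif setNames var
#' @importFrom utils combn head tail write.table
NULL

NT_UNAMBIG <- c("A", "C", "G", "T")
NT_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
AA_UNAMBIG <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_AMBIG <- c("X", "B", "Z", "J", "*")

alphabet_for <- function(molecule) {
  if (molecule == "nucleotide") {
    list(unambig = NT_UNAMBIG, ambig = NT_AMBIG, gap = "-")
  } else {
    list(unambig = AA_UNAMBIG, ambig = AA_AMBIG, gap = "-")
  }
}

#' Construct an alignment object
#'
#' An alignment is a taxa-by-columns character matrix over the nucleotide
#' alphabet (A, C, G, T, IUPAC ambiguity codes, N, gap \code{"-"}) or the
#' amino-acid alphabet (20 residues, X, ambiguity codes, \code{"*"},
#' gap). All rows must have equal length and taxon labels must be unique.
#'
#' @param mat character matrix with taxon labels as row names.
#' @param molecule \code{"nucleotide"} or \code{"amino-acid"}.
#' @return An object of class \code{lba_alignment}.
#' @export
new_alignment <- function(mat, molecule = c("nucleotide", "amino-acid")) {
  molecule <- match.arg(molecule)
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat))) stop("alignment matrix must have taxon row names")
  if (anyDuplicated(rownames(mat))) stop("duplicate taxon labels")
  ab <- alphabet_for(molecule)
  allowed <- c(ab$unambig, ab$ambig, ab$gap, "?")
  bad <- !(mat %in% allowed)
  if (any(bad)) stop("characters outside the ", molecule, " alphabet: ",
                     paste(unique(mat[bad]), collapse = " "))
  mat[mat == "?"] <- if (molecule == "nucleotide") "N" else "X"
  structure(list(matrix = mat, molecule = molecule), class = "lba_alignment")
}

#' @export
print.lba_alignment <- function(x, ...) {
  cat(sprintf("<lba_alignment> %d taxa x %d columns (%s)\n",
              n_taxa(x), n_cols(x), x$molecule))
  invisible(x)
}

#' Number of taxa / columns of an alignment
#' @param aln an \code{lba_alignment}.
#' @return integer count.
#' @export
n_taxa <- function(aln) nrow(aln$matrix)

#' @rdname n_taxa
#' @export
n_cols <- function(aln) ncol(aln$matrix)

#' Taxon labels of an alignment
#' @param aln an \code{lba_alignment}.
#' @return character vector of labels.
#' @export
taxa_labels <- function(aln) rownames(aln$matrix)

#' Select columns of an alignment
#' @param aln an \code{lba_alignment}.
#' @param idx integer column indices (1-based), kept in the given order.
#' @return A new \code{lba_alignment}.
#' @export
select_columns <- function(aln, idx) {
  m <- aln$matrix[, idx, drop = FALSE]
  structure(list(matrix = m, molecule = aln$molecule), class = "lba_alignment")
}

normalize_chars <- function(mat, molecule) {
  mat <- toupper(mat)
  if (molecule == "nucleotide") mat[mat == "U"] <- "T"
  ab <- alphabet_for(molecule)
  allowed <- c(ab$unambig, ab$ambig, ab$gap, "?")
  unknown <- !(mat %in% allowed)
  if (any(unknown)) {
    message(sum(unknown), " unknown character(s) mapped to ",
            if (molecule == "nucleotide") "N" else "X")
    mat[unknown] <- if (molecule == "nucleotide") "N" else "X"
  }
  mat
}

#' Read an alignment from FASTA or relaxed PHYLIP
#'
#' Characters are uppercased, \code{U} is mapped to \code{T} and characters
#' outside the declared alphabet are mapped to \code{N} (nucleotide) or
#' \code{X} (amino acid) with a message reporting the count.
#'
#' @param path file path.
#' @param format \code{"fasta"} or \code{"phylip"} (relaxed, sequential).
#' @param molecule \code{"nucleotide"} or \code{"amino-acid"}.
#' @return An \code{lba_alignment}.
#' @export
read_alignment <- function(path, format = c("fasta", "phylip"),
                           molecule = c("nucleotide", "amino-acid")) {
  format <- match.arg(format)
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("malformed alignment: empty file")
  if (format == "fasta") {
    seqs <- tryCatch(
      seqinr::read.fasta(path, seqtype = if (molecule == "nucleotide") "DNA" else "AA",
                         forceDNAtolower = FALSE),
      error = function(e) stop("malformed alignment: ", conditionMessage(e)))
    if (length(seqs) == 0) stop("malformed alignment: no sequences in ", path)
    rows <- lapply(seqs, as.character)
  } else {
    # relaxed PHYLIP: header line, then whitespace-separated name + sequence
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2) stop("malformed alignment: no sequences in ", path)
    body <- lines[-1]
    parts <- strsplit(trimws(body), "\\s+")
    if (any(vapply(parts, length, 1L) < 2))
      stop("malformed alignment: PHYLIP line without sequence")
    rows <- lapply(parts, function(p) strsplit(paste(p[-1], collapse = ""), "")[[1]])
    names(rows) <- vapply(parts, `[`, "", 1L)
  }
  if (anyDuplicated(names(rows))) stop("duplicate taxon label in ", path)
  widths <- vapply(rows, length, 1L)
  if (length(unique(widths)) != 1)
    stop("malformed alignment: unequal row lengths")
  mat <- do.call(rbind, rows)
  mat <- normalize_chars(mat, molecule)
  new_alignment(mat, molecule)
}

#' Write an alignment to FASTA or relaxed PHYLIP
#' @param aln an \code{lba_alignment}.
#' @param path output file path.
#' @param format \code{"fasta"} or \code{"phylip"}.
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  m <- aln$matrix
  if (format == "fasta") {
    lines <- character(2L * nrow(m))
    lines[c(TRUE, FALSE)] <- paste0(">", rownames(m))
    lines[c(FALSE, TRUE)] <- apply(m, 1, paste, collapse = "")
    writeLines(lines, path)
  } else {
    lines <- c(sprintf("%d %d", nrow(m), ncol(m)),
               paste(rownames(m), apply(m, 1, paste, collapse = "")))
    writeLines(lines, path)
  }
  invisible(path)
}

# conversion helpers for ape / phangorn back-ends
as_phyDat <- function(aln) {
  type <- if (aln$molecule == "nucleotide") "DNA" else "AA"
  m <- aln$matrix
  if (aln$molecule == "amino-acid") {
    # phyDat AA contrast has no '*'; treat stops as fully ambiguous
    m[m == "*"] <- "X"
  }
  phangorn::phyDat(m, type = type)
}

as_DNAbin <- function(aln) {
  stopifnot(aln$molecule == "nucleotide")
  ape::as.DNAbin(tolower(aln$matrix))
}

# integer encoding: 0 = gap/ambiguity, 1..K = unambiguous state index
encode_states <- function(aln) {
  ab <- alphabet_for(aln$molecule)
  code <- setNames(seq_along(ab$unambig), ab$unambig)
  enc <- code[aln$matrix]
  enc[is.na(enc)] <- 0L
  matrix(as.integer(enc), nrow = nrow(aln$matrix),
         dimnames = dimnames(aln$matrix))
}

#' Read trees from a Newick file
#' @param path file with one Newick tree per line.
#' @return A list of \code{phylo} objects (even when the file holds one tree).
#' @export
read_trees <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  if (inherits(tr, "phylo")) list(tr) else unclass(tr)
}

#' Write a tree (or list of trees) to a Newick file
#' @param tree a \code{phylo} object or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trees <- function(tree, path) {
  if (inherits(tree, "phylo")) tree <- list(tree)
  class(tree) <- "multiPhylo"
  ape::write.tree(tree, file = path)
  invisible(path)
}
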