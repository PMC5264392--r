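# Removal of unreliable aligned regions: a re-implementation of the
# published Gblocks 0.91b semantics (conservation classes, nonconserved
# stretches, flank trimming, gap rejection, minimum block length).
# Bit-compatibility with the Gblocks binary is not promised: where its
# behavior is undocumented (ties among most frequent residues, ambiguity
# codes in identity counts) ambiguity codes count as non-matching and ties
# break by residue alphabetical order.

#' Block-filter parameter set
#'
#' @param min_seq_conserved b1: minimum number of sequences for a conserved
#'   position; must exceed half the taxon count.
#' @param min_seq_flank b2: minimum number of sequences for a flank (highly
#'   conserved) position; \code{b1 <= b2 <=} taxon count.
#' @param max_contig_nonconserved b3: maximum run of contiguous nonconserved
#'   positions tolerated inside a block.
#' @param min_block_length b4: minimum surviving block length (>= 2).
#' @param allowed_gaps b5: \code{"none"} (any gap rejects the column),
#'   \code{"with-half"} (rejected when >= 50\% of taxa have a gap) or
#'   \code{"all"}.
#' @return list of class \code{lba_block_params}.
#' @export
block_filter_params <- function(min_seq_conserved, min_seq_flank,
                                max_contig_nonconserved, min_block_length,
                                allowed_gaps = c("none", "with-half", "all")) {
  allowed_gaps <- match.arg(allowed_gaps)
  p <- list(b1 = as.integer(min_seq_conserved), b2 = as.integer(min_seq_flank),
            b3 = as.integer(max_contig_nonconserved),
            b4 = as.integer(min_block_length), b5 = allowed_gaps)
  if (p$b1 > p$b2) stop("invalid params: b1 > b2")
  if (p$b3 < 0) stop("invalid params: b3 < 0")
  if (p$b4 < 2) stop("invalid params: b4 < 2")
  class(p) <- "lba_block_params"
  p
}

#' Preset block-filter parameter sets
#'
#' The relaxed / default / strict presets are, for a 22-taxon matrix,
#' b1 = 11/11/21, b2 = 11/17/21, b3 = 10/8/5, b4 = 5/10/50 and allowed gaps
#' with-half/none/none. For other taxon counts b1 and b2 are rescaled:
#' b1 = floor(n/2) + 1 (relaxed, default) or ceiling(21 n / 22) (strict);
#' b2 = b1 (relaxed), ceiling(17 n / 22) (default) or b1 (strict).
#'
#' @param preset \code{"relaxed"}, \code{"default"} or \code{"strict"}.
#' @param n_taxa number of sequences the filter will be applied to.
#' @return An \code{lba_block_params}.
#' @export
gblocks_preset <- function(preset = c("relaxed", "default", "strict"), n_taxa = 22) {
  preset <- match.arg(preset)
  if (n_taxa == 22) {
    return(switch(preset,
      relaxed = block_filter_params(11, 11, 10, 5, "with-half"),
      default = block_filter_params(11, 17, 8, 10, "none"),
      strict = block_filter_params(21, 21, 5, 50, "none")))
  }
  half1 <- n_taxa %/% 2L + 1L
  switch(preset,
    relaxed = block_filter_params(half1, half1, 10, 5, "with-half"),
    default = block_filter_params(half1, max(half1, ceiling(17 * n_taxa / 22)),
                                  8, 10, "none"),
    strict = {
      b <- max(half1, ceiling(21 * n_taxa / 22))
      block_filter_params(b, b, 5, 50, "none")
    })
}

#' Classify columns by conservation status
#'
#' A column's identity count is the number of occurrences of its most
#' frequent unambiguous residue. Status: \code{nonconserved} when identity
#' < b1, \code{conserved} when b1 <= identity < b2 (boundary inclusive at
#' b1), \code{highly-conserved} when identity >= b2; \code{gap-rejected}
#' overrides when the column's gaps violate b5.
#'
#' @param aln an \code{lba_alignment}.
#' @param params an \code{lba_block_params}.
#' @return character vector of per-column statuses.
#' @export
classify_conservation <- function(aln, params) {
  n <- n_taxa(aln)
  # b1 may equal exactly half the taxa (the relaxed/default presets do at 22)
  if (params$b1 < n / 2) stop("invalid params: b1 below taxa/2")
  if (params$b2 > n) stop("invalid params: b2 > number of taxa")
  counts <- state_counts(aln)
  identity <- apply(counts, 2, max)
  status <- ifelse(identity >= params$b2, "highly-conserved",
                   ifelse(identity >= params$b1, "conserved", "nonconserved"))
  gaps <- colSums(aln$matrix == "-")
  gap_bad <- switch(params$b5,
                    none = gaps > 0,
                    `with-half` = gaps >= n / 2,
                    all = rep(FALSE, n_cols(aln)))
  status[gap_bad] <- "gap-rejected"
  status
}

# contiguous runs of TRUE in a logical vector -> matrix of (start, end)
runs_of <- function(x) {
  r <- rle(x)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  cbind(start = start[r$values], end = end[r$values])
}

# trim a block (vector of column indices into status) from both ends until
# the terminal columns are highly-conserved
trim_to_flanks <- function(block, status) {
  while (length(block) && status[block[1]] != "highly-conserved")
    block <- block[-1]
  while (length(block) && status[block[length(block)]] != "highly-conserved")
    block <- block[-length(block)]
  block
}

#' Filter unreliable aligned regions (Gblocks-style)
#'
#' Five-step procedure: (1) stretches of more than b3 contiguous
#' nonconserved columns are rejected; (2) each remaining block is trimmed
#' from both ends until its terminal columns are highly conserved; (3)
#' gap-rejected columns and the contiguous nonconserved columns adjacent to
#' them are rejected, then blocks are re-trimmed as in (2); (4) blocks
#' shorter than b4 are rejected; (5) surviving columns are emitted in
#' original order.
#'
#' @param aln an \code{lba_alignment}.
#' @param params an \code{lba_block_params}, or a preset name
#'   (\code{"relaxed"}, \code{"default"}, \code{"strict"}).
#' @return list with \code{alignment} (filtered) and \code{kept} (1-based
#'   column indices of the input that survived).
#' @export
gblocks_filter <- function(aln, params = "default") {
  if (is.character(params)) params <- gblocks_preset(params, n_taxa(aln))
  status <- classify_conservation(aln, params)
  L <- n_cols(aln)
  rejected <- rep(FALSE, L)

  # (1) long nonconserved stretches (gap-rejected columns are nonconserved too)
  noncons <- status %in% c("nonconserved", "gap-rejected")
  r <- runs_of(noncons)
  for (k in seq_len(nrow(r)))
    if (r[k, "end"] - r[k, "start"] + 1L > params$b3)
      rejected[r[k, "start"]:r[k, "end"]] <- TRUE

  blocks_from <- function(rej) {
    r <- runs_of(!rej)
    lapply(seq_len(nrow(r)), function(k) r[k, "start"]:r[k, "end"])
  }

  # (2) trim to highly-conserved flanks
  blocks <- lapply(blocks_from(rejected), trim_to_flanks, status = status)

  # (3) reject gap-rejected columns plus adjacent nonconserved runs; re-trim
  blocks <- unlist(lapply(blocks, function(b) {
    if (!length(b)) return(list())
    bad <- status[b] == "gap-rejected"
    if (any(bad)) {
      nc <- status[b] %in% c("nonconserved", "gap-rejected")
      r <- runs_of(nc)
      for (k in seq_len(nrow(r)))
        if (any(bad[r[k, "start"]:r[k, "end"]]))
          bad[r[k, "start"]:r[k, "end"]] <- TRUE
    }
    sub <- runs_of(!bad)
    lapply(seq_len(nrow(sub)),
           function(k) trim_to_flanks(b[sub[k, "start"]:sub[k, "end"]], status))
  }), recursive = FALSE)

  # (4) minimum block length
  blocks <- blocks[vapply(blocks, length, 1L) >= params$b4]

  # (5) emit in original order
  kept <- sort(unique(unlist(blocks)))
  list(alignment = select_columns(aln, kept), kept = kept)
}

#' Format kept columns as Gblocks-style flank ranges
#'
#' @param kept integer vector of kept 1-based column indices.
#' @return character scalar like \code{"[1 55]  [70 120]"}.
#' @export
kept_ranges <- function(kept) {
  if (!length(kept)) return("")
  r <- runs_of(seq(min(kept), max(kept)) %in% kept)
  off <- min(kept) - 1L
  paste(sprintf("[%d %d]", r[, "start"] + off, r[, "end"] + off), collapse = "  ")
}
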