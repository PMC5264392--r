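# Incremental removal of the most variable (OV-ranked) sites with the dual
# Pearson-correlation stopping rule: at each removal step the shortened
# matrix ("A") and the removed fast sites ("B") are compared through ML and
# p distances, and removal stops at the end of the sharp joint increase of
# the two correlations.

#' Sort alignment columns fastest-first by observed variability
#'
#' @param aln an \code{lba_alignment}.
#' @return list with \code{alignment} (columns reordered fastest-first,
#'   ties broken by original index) and \code{rank_map} (original 1-based
#'   column index of each sorted column, so
#'   \code{rank_map[i]} recovers where sorted column i came from).
#' @export
ov_sort <- function(aln) {
  perm <- rank_sites(ov_scores(aln), "fastest-first")
  list(alignment = select_columns(aln, perm), rank_map = perm)
}

#' Drop the k fastest columns of an OV-sorted alignment
#'
#' @param sorted the list returned by \code{\link{ov_sort}}.
#' @param k number of leading (fastest) columns to remove.
#' @return An \code{lba_alignment} holding the surviving columns restored to
#'   their original relative order; width = input width - k.
#' @export
apply_removal <- function(sorted, k) {
  aln <- sorted$alignment
  w <- n_cols(aln)
  if (k > w) stop("range error: k exceeds alignment width")
  if (k == w) return(select_columns(aln, integer(0)))
  keep_sorted <- (k + 1L):w
  orig <- sorted$rank_map[keep_sorted]
  select_columns(aln, keep_sorted[order(orig)])
}

#' Removal series with dual Pearson correlations
#'
#' For k = increment, 2 increment, ..., max_removed: partition A holds the
#' remaining (slower) columns, partition B the k removed fastest columns.
#' r_AB is the Pearson correlation over unordered taxon pairs between the ML
#' distances of A and of B; r_MLp correlates the ML and p distances of B.
#' The distance model is fit once on the full matrix and reused at every
#' step (pass \code{refit = TRUE} to refit per step).
#'
#' @param sorted list from \code{\link{ov_sort}}.
#' @param increment step size in sites (default 250).
#' @param max_removed largest k (must be below the width); default 20
#'   increments or half the width, whichever is smaller.
#' @param model distance model for the ML matrices.
#' @param params optional precomputed \code{\link{estimate_gtr_params}} fit.
#' @param refit logical; re-estimate model parameters on each partition.
#' @return data frame of class \code{lba_removal_trace} with columns
#'   \code{k}, \code{position} (remaining width), \code{r_AB}, \code{r_MLp}.
#' @export
removal_series <- function(sorted, increment = 250, max_removed = NULL,
                           model = "GTR+G", params = NULL, refit = FALSE) {
  aln <- sorted$alignment
  w <- n_cols(aln)
  if (is.null(max_removed)) max_removed <- min(20L * increment, w %/% 2L)
  if (max_removed >= w) stop("max_removed must be below the alignment width")
  if (!refit && model %in% c("GTR", "GTR+G") && is.null(params))
    params <- estimate_gtr_params(aln, gamma = model == "GTR+G")
  ks <- seq(increment, max_removed, by = increment)
  pair_cor <- function(m1, m2) {
    ut <- upper.tri(m1)
    x <- m1[ut]; y <- m2[ut]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || var(x[ok]) == 0 || var(y[ok]) == 0) return(NA_real_)
    cor(x[ok], y[ok])
  }
  rows <- lapply(ks, function(k) {
    A <- select_columns(aln, (k + 1L):w)
    B <- select_columns(aln, 1:k)
    pA <- if (refit) NULL else params
    mlA <- ml_distance_matrix(A, model, params = pA)
    mlB <- ml_distance_matrix(B, model, params = pA)
    pB <- p_distance_matrix(B)
    data.frame(k = k, position = w - k,
               r_AB = pair_cor(mlA, mlB[rownames(mlA), rownames(mlA)]),
               r_MLp = pair_cor(mlB, pB[rownames(mlB), rownames(mlB)]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lba_removal_trace", "data.frame")
  out
}

#' Detect the stopping point of the removal series
#'
#' A step is a "sharp increase" when its per-step delta exceeds
#' \code{jump_factor} times the median absolute delta of all prior steps, in
#' \emph{both} correlation series. The stopping point k* is the k at the end
#' of the maximal (longest, earliest on ties) run of consecutive
#' sharp-increase steps. When no step qualifies the sentinel
#' \code{"no-stopping-point"} is returned with diagnostics.
#'
#' @param trace an \code{lba_removal_trace} with >= 4 steps.
#' @param jump_factor multiplier on the median absolute prior delta.
#' @return list with \code{k_star} (integer or NA), \code{position},
#'   \code{status} (\code{"stopped"} or \code{"no-stopping-point"}),
#'   \code{run} (indices of the chosen sharp run), and the two delta series.
#' @export
detect_stopping_point <- function(trace, jump_factor = 3) {
  if (nrow(trace) < 4) stop("need >= 4 steps")
  d1 <- diff(trace$r_AB)
  d2 <- diff(trace$r_MLp)
  sharp <- rep(FALSE, length(d1))
  for (i in seq_along(d1)) {
    if (i < 2) next
    m1 <- median(abs(d1[1:(i - 1)]), na.rm = TRUE)
    m2 <- median(abs(d2[1:(i - 1)]), na.rm = TRUE)
    if (!is.na(d1[i]) && !is.na(d2[i]) &&
        d1[i] > jump_factor * m1 && d2[i] > jump_factor * m2)
      sharp[i] <- TRUE
  }
  if (!any(sharp))
    return(list(k_star = NA_integer_, position = NA_integer_,
                status = "no-stopping-point", run = integer(0),
                delta_AB = d1, delta_MLp = d2))
  r <- runs_of(sharp)
  len <- r[, "end"] - r[, "start"] + 1L
  best <- which.max(len)                      # longest run, earliest on ties
  run <- r[best, "start"]:r[best, "end"]
  # delta i sits between steps i and i+1: the run ends at step end+1
  k_star <- trace$k[r[best, "end"] + 1L]
  list(k_star = k_star, position = trace$position[r[best, "end"] + 1L],
       status = "stopped", run = run, delta_AB = d1, delta_MLp = d2)
}
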