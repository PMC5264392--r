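# Orchestration of the comparative battery: build the filtered/modified
# matrix variants, run inference and LBA diagnostics per variant, and render
# the variant-by-resolution report.

variant_names_all <- c("PCG", "PCG12", "AA", "GB-relaxed", "GB-default",
                       "GB-strict", "Iss-keep", "Iss-drop", "slope-drop",
                       "R2-drop", "OV-slow", "OV-medium", "OV-fast",
                       "TIGER-slow", "TIGER-medium", "TIGER-fast", "OV-sorted")

#' Build the filtered and modified matrix variants
#'
#' Each requested variant is produced by the corresponding operation:
#' \describe{
#'   \item{PCG}{the unmodified supermatrix.}
#'   \item{PCG12}{first and second codon positions only.}
#'   \item{AA}{amino-acid translation.}
#'   \item{GB-relaxed/default/strict}{block filtering presets.}
#'   \item{Iss-drop / Iss-keep}{drop the Iss-saturated genes / keep only them.}
#'   \item{slope-drop / R2-drop}{drop genes on the left shoulder of the
#'     regression slope / R-squared density.}
#'   \item{OV-slow/medium/fast, TIGER-slow/medium/fast}{rate tertile
#'     partitions.}
#'   \item{OV-sorted}{fast-site removal at the detected stopping point (or
#'     \code{config$ov_sorted_k} when the trace finds none).}
#' }
#'
#' @param aln supermatrix \code{lba_alignment} (nucleotide, codon-aligned).
#' @param pm its \code{lba_partition_map}.
#' @param config list: \code{variants} (names as above; default all),
#'   \code{iss_reps}, \code{iss_seed}, \code{increment},
#'   \code{ov_sorted_k}, \code{params} (precomputed model fit),
#'   \code{tiger} (logical; skip TIGER variants on wide matrices).
#' @return list with \code{variants} (named list of alignments) and
#'   \code{report} (name, width, variable and PIS counts per variant).
#' @export
build_variants <- function(aln, pm, config = list()) {
  wanted <- config$variants
  if (is.null(wanted)) wanted <- variant_names_all
  unknown <- setdiff(wanted, variant_names_all)
  if (length(unknown)) stop("unknown variant name(s): ",
                            paste(unknown, collapse = ", "))
  out <- list()
  need_rates <- any(wanted %in% c("OV-slow", "OV-medium", "OV-fast",
                                  "TIGER-slow", "TIGER-medium", "TIGER-fast"))
  need_tiger <- any(grepl("^TIGER", wanted))
  table <- if (need_rates) site_rate_table(aln, tiger = need_tiger) else NULL
  params <- config$params
  if (any(wanted %in% c("Iss-keep", "Iss-drop", "slope-drop", "R2-drop",
                        "OV-sorted")) && is.null(params))
    params <- estimate_gtr_params(aln)

  if ("PCG" %in% wanted) out$PCG <- aln
  if ("PCG12" %in% wanted) out$PCG12 <- extract_codon_positions(aln, c(1, 2), pm)
  if ("AA" %in% wanted) out$AA <- translate_codon_alignment(aln, pm = pm)
  for (p in c("relaxed", "default", "strict"))
    if (paste0("GB-", p) %in% wanted)
      out[[paste0("GB-", p)]] <- gblocks_filter(aln, p)$alignment
  if (any(c("Iss-keep", "Iss-drop") %in% wanted)) {
    reps <- if (is.null(config$iss_reps)) 100 else config$iss_reps
    seed <- if (is.null(config$iss_seed)) 1 else config$iss_seed
    rep_tab <- gene_saturation_report(aln, pm, params = params, iss = TRUE,
                                      reps = reps, seed = seed)
    sat <- rep_tab$gene[rep_tab$saturated]
    if ("Iss-keep" %in% wanted)
      out[["Iss-keep"]] <- subset_genes(aln, pm, sat, "keep")$alignment
    if ("Iss-drop" %in% wanted)
      out[["Iss-drop"]] <- subset_genes(aln, pm, sat, "drop")$alignment
  }
  if (any(c("slope-drop", "R2-drop") %in% wanted)) {
    rep_tab <- gene_saturation_report(aln, pm, params = params, iss = FALSE)
    if ("slope-drop" %in% wanted) {
      fl <- flag_saturated_genes(setNames(rep_tab$slope, rep_tab$gene))
      out[["slope-drop"]] <- subset_genes(aln, pm, fl$flagged, "drop")$alignment
    }
    if ("R2-drop" %in% wanted) {
      fl <- flag_saturated_genes(setNames(rep_tab$R2, rep_tab$gene))
      out[["R2-drop"]] <- subset_genes(aln, pm, fl$flagged, "drop")$alignment
    }
  }
  add_tertiles <- function(method, prefix) {
    tp <- tertile_partition(aln, table, method)
    for (p in c("slow", "medium", "fast")) {
      nm <- paste0(prefix, "-", p)
      if (nm %in% wanted) out[[nm]] <<- tp[[p]]
    }
  }
  if (any(grepl("^OV-(slow|medium|fast)$", wanted))) add_tertiles("ov", "OV")
  if (need_tiger) add_tertiles("tiger", "TIGER")
  if ("OV-sorted" %in% wanted) {
    sorted <- ov_sort(aln)
    inc <- if (is.null(config$increment)) 250 else config$increment
    k <- config$ov_sorted_k
    if (is.null(k)) {
      trace <- removal_series(sorted, increment = inc, params = params)
      sp <- detect_stopping_point(trace)
      k <- if (sp$status == "stopped") sp$k_star else inc
    }
    out[["OV-sorted"]] <- apply_removal(sorted, k)
  }
  out <- out[intersect(wanted, names(out))]
  report <- do.call(rbind, lapply(names(out), function(nm) {
    s <- attr(classify_sites(out[[nm]]), "summary")
    data.frame(variant = nm, width = s["total"], variable = s["variable"],
               pis = s["pis"], row.names = NULL)
  }))
  list(variants = out, report = report)
}

#' Run the comparative battery over matrix variants
#'
#' For each variant: infer a tree, classify the focal trichotomy, measure
#' bootstrap support for the rival resolutions and report stem-branch
#' lengths/ratios. Amino-acid variants are analyzed with p-distance
#' neighbor joining; variants too wide for the requested exact ML are
#' recorded as skipped.
#'
#' @param variants named list of alignments (from \code{\link{build_variants}}).
#' @param clades named list of three taxon sets (the focal trichotomy).
#' @param outgroup outgroup taxon labels.
#' @param config list: \code{infer} ("nj", "parsimony" or "ml"),
#'   \code{model} (distance model for nj), \code{n_boot} (bootstrap
#'   replicates; 0 disables), \code{reference} (clade name for stem ratios,
#'   default last clade).
#' @param seed integer seed driving all bootstrap resampling.
#' @return list of class \code{lba_battery_report}: \code{table} (one row
#'   per variant), \code{support} (per-variant proportions), \code{seed},
#'   \code{config}.
#' @export
run_battery <- function(variants, clades, outgroup, config = list(), seed = 1) {
  infer <- if (is.null(config$infer)) "nj" else config$infer
  model <- if (is.null(config$model)) "JC69" else config$model
  n_boot <- if (is.null(config$n_boot)) 0 else config$n_boot
  reference <- if (is.null(config$reference)) names(clades)[length(clades)]
               else config$reference
  support <- list()
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    aa <- v$molecule == "amino-acid"
    tr <- if (aa) {
      d <- p_distance_matrix(v)
      d[!is.finite(d)] <- max(d[is.finite(d)], 1)
      nj_tree(d)
    } else infer_tree(v, infer, model = model)
    lab <- classify_trichotomy(tr, clades, outgroup)
    stems <- stem_branch_report(tr, clades, reference, outgroup)
    row <- data.frame(variant = nm, width = n_cols(v), resolution = lab,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(stems)))
      row[[paste0("ratio_", stems$clade[i])]] <- stems$ratio[i]
    if (n_boot > 0 && !aa) {
      bs <- bootstrap_support(v, clades, outgroup, infer = infer,
                              n_reps = n_boot, seed = seed, model = model)
      support[[nm]] <<- bs$proportions
      row$boot_true <- unname(bs$proportions[lab])
    }
    row
  })
  structure(list(table = do.call(rbind, rows), support = support,
                 seed = seed, config = config),
            class = "lba_battery_report")
}

#' Render a battery report
#'
#' @param report an \code{lba_battery_report}.
#' @param path output file path.
#' @param format \code{"tsv"}, \code{"json"} or \code{"markdown"} (the
#'   markdown variant includes a two-topology summary table).
#' @return \code{path}, invisibly.
#' @export
render_report <- function(report, path, format = c("tsv", "json", "markdown")) {
  format <- match.arg(format)
  tab <- report$table
  if (format == "tsv") {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(list(table = tab, support = report$support,
                              seed = report$seed), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    lines <- c("# LBA battery report", "",
               paste0("| ", paste(names(tab), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
               apply(tab, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")),
               "", "## Resolutions", "")
    for (res in unique(tab$resolution))
      lines <- c(lines, sprintf("- **%s**: %s", res,
                 paste(tab$variant[tab$resolution == res], collapse = ", ")))
    writeLines(lines, path)
  }
  invisible(path)
}
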