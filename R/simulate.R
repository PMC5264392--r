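# Synthetic-data generation: GTR+Gamma sequence simulation on trees (with
# per-site rate scaling for codon structure), the canonical LBA testbeds
# (Felsenstein zone, long-stem three-clade shapes), multispecies-coalescent
# gene trees, and exact-count fixture alignments.

#' Default GTR model used by the simulators
#'
#' Mildly asymmetric exchangeabilities with a transition bias and unequal
#' base frequencies, plus a Gamma shape of 0.3 (strong rate heterogeneity,
#' typical of concatenated plastid coding matrices).
#'
#' @return list with \code{rates}, \code{bf}, \code{shape}, \code{k}.
#' @export
default_sim_model <- function() {
  list(rates = c(1.2, 3.8, 0.9, 1.1, 4.2, 1.0),
       bf = c(0.31, 0.19, 0.24, 0.26), shape = 0.3, k = 4L)
}

#' Simulate an alignment under GTR(+Gamma) on a tree
#'
#' Root states are drawn from the stationary frequencies and evolved along
#' the edges with transition probabilities exp(Qt); each site draws its
#' Gamma rate category once. An optional per-site rate multiplier pattern
#' (recycled over columns) superimposes codon-position structure.
#'
#' @param tree a \code{phylo} with branch lengths (substitutions/site).
#' @param model list with \code{rates} (6 GTR exchangeabilities), \code{bf},
#'   optional \code{shape} and \code{k} (Gamma categories; NULL shape = no
#'   Gamma).
#' @param length number of columns.
#' @param seed integer seed; \code{NULL} leaves the RNG state alone.
#' @param site_rates optional numeric multiplier pattern, e.g.
#'   \code{c(1, 1, 5)} to make every third position 5x faster.
#' @return An \code{lba_alignment}.
#' @export
simulate_alignment <- function(tree, model, length, seed = NULL,
                               site_rates = NULL) {
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  Q <- gtr_q_matrix(model$rates, model$bf)   # validates the model
  if (!is.null(seed)) set.seed(seed)
  k <- if (!is.null(model$shape)) (if (is.null(model$k)) 4L else model$k) else 1L
  cat_rates <- if (k > 1) phangorn::discrete.gamma(model$shape, k) else 1
  site_cat <- sample.int(k, length, replace = TRUE)
  mult <- if (is.null(site_rates)) rep(1, length)
          else rep_len(site_rates, length)
  rate <- cat_rates[site_cat] * mult
  out <- matrix("", nrow = length(tree$tip.label), ncol = length,
                dimnames = list(tree$tip.label, NULL))
  for (r in unique(rate)) {
    cols <- which(rate == r)
    sim <- phangorn::simSeq(tree, l = length(cols), Q = model$rates,
                            bf = model$bf, rate = r)
    m <- toupper(as.character(sim))
    out[rownames(m), cols] <- m
  }
  new_alignment(out, "nucleotide")
}

#' The four-taxon Felsenstein-zone tree
#'
#' Unrooted tree \code{((A:p, B:q):q, C:p, D:q)}: the two long branches (A
#' and C) are non-adjacent, separated by the short internal branch. With
#' p >> q this is the regime where parsimony is statistically inconsistent
#' and attracts the long branches.
#'
#' @param p long branch length (substitutions/site).
#' @param q short branch / internal length.
#' @return A \code{phylo}.
#' @export
felsenstein_zone_tree <- function(p, q) {
  stopifnot(p > 0, q > 0)
  if (p <= q) warning("p <= q: not in the Felsenstein zone")
  ape::read.tree(text = sprintf("((A:%.10f,B:%.10f):%.10f,C:%.10f,D:%.10f);",
                                p, q, q, p, q))
}

#' Three-clade long-stem LBA scenario
#'
#' Builds a 10-taxon species tree: an outgroup plus three 3-taxon crown
#' clades (named J, C and HCX after the focal trichotomy the shape
#' emulates) whose stem branches are long for J and C and short for HCX,
#' with short internal branches wiring the requested true resolution. In
#' the default regime (stem ratios about 2.3 : 1.5 : 1, internals 0.01)
#' homoplasy on the two long stems can attract them together.
#'
#' @param stem_J,stem_C,stem_HCX stem branch lengths (substitutions/site).
#' @param internal_1,internal_2 the two internal branches of the trichotomy.
#' @param crown_depth within-clade divergence.
#' @param outgroup_length branch to the outgroup.
#' @param true_resolution \code{"J(C,HCX)"}, \code{"C(J,HCX)"} or
#'   \code{"HCX(J,C)"}: which clade is sister to the other two.
#' @param model substitution model (see \code{\link{simulate_alignment}});
#'   the default is \code{\link{default_sim_model}} without the Gamma
#'   component, so that rate heterogeneity is purely positional (codon
#'   structure) and the fast/slow site classes the filtering strategies
#'   exploit stay cleanly separated.
#' @param n_genes,gene_length supermatrix dimensions (82 genes of 993
#'   codon-aligned columns mirror the emulated supermatrix scale; tests use
#'   smaller values).
#' @param pos3_rate rate multiplier for third codon positions.
#' @param heterotachy log-normal sd of per-gene rate multipliers (0 = off).
#' @return list of class \code{lba_scenario}: \code{species_tree},
#'   \code{clades}, \code{outgroup}, \code{model}, \code{n_genes},
#'   \code{gene_length}, \code{pos3_rate}, \code{heterotachy},
#'   \code{true_resolution}.
#' @export
jcx_scenario <- function(stem_J = 0.184, stem_C = 0.12, stem_HCX = 0.08,
                         internal_1 = 0.0075, internal_2 = 0.0075,
                         crown_depth = 0.02, outgroup_length = 0.05,
                         true_resolution = "J(C,HCX)",
                         model = NULL,
                         n_genes = 82, gene_length = 993,
                         pos3_rate = 8, heterotachy = 0) {
  if (is.null(model)) { model <- default_sim_model(); model$shape <- NULL }
  crown <- function(prefix) sprintf("((%s1:%.6f,%s2:%.6f):%.6f,%s3:%.6f)",
                                    prefix, crown_depth, prefix, crown_depth,
                                    crown_depth, prefix, 2 * crown_depth)
  sub <- function(prefix, stem) sprintf("%s:%.6f", crown(prefix), stem)
  parts <- switch(true_resolution,
    "J(C,HCX)" = sprintf("(%s,(%s,%s):%.6f)", sub("J", stem_J),
                         sub("C", stem_C), sub("H", stem_HCX), internal_2),
    "C(J,HCX)" = sprintf("(%s,(%s,%s):%.6f)", sub("C", stem_C),
                         sub("J", stem_J), sub("H", stem_HCX), internal_2),
    "HCX(J,C)" = sprintf("(%s,(%s,%s):%.6f)", sub("H", stem_HCX),
                         sub("J", stem_J), sub("C", stem_C), internal_2),
    stop("invalid resolution label: ", true_resolution))
  nwk <- sprintf("(%s:%.6f,OUT:%.6f);", parts, internal_1, outgroup_length)
  structure(list(
    species_tree = ape::read.tree(text = nwk),
    clades = list(J = paste0("J", 1:3), C = paste0("C", 1:3),
                  HCX = paste0("H", 1:3)),
    outgroup = "OUT", model = model, n_genes = n_genes,
    gene_length = gene_length, pos3_rate = pos3_rate,
    heterotachy = heterotachy, true_resolution = true_resolution),
    class = "lba_scenario")
}

#' Simulate the supermatrix of a scenario
#'
#' Simulates each gene on the scenario's species tree (per-gene rate
#' multipliers when heterotachy is on, third-position rate scaling for codon
#' structure) and concatenates them with a partition map.
#'
#' @param scenario an \code{lba_scenario}.
#' @param seed integer seed.
#' @return list with \code{alignment}, \code{map}, \code{scenario}.
#' @export
simulate_scenario <- function(scenario, seed = 1) {
  set.seed(seed)
  glen <- 3L * ceiling(scenario$gene_length / 3L)   # keep codon frame
  mult <- if (scenario$heterotachy > 0)
    exp(stats::rnorm(scenario$n_genes, -scenario$heterotachy^2 / 2,
                     scenario$heterotachy)) else rep(1, scenario$n_genes)
  genes <- lapply(seq_len(scenario$n_genes), function(g) {
    tr <- scenario$species_tree
    tr$edge.length <- tr$edge.length * mult[g]
    simulate_alignment(tr, scenario$model, glen,
                       site_rates = c(1, 1, scenario$pos3_rate))
  })
  out <- concatenate_alignments(genes, sprintf("gene%03d", seq_len(scenario$n_genes)))
  out$scenario <- scenario
  out
}

# ages of all nodes above the tips (0 at tips); requires a time-consistent
# (ultrametric) tree
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid sample per species; branch lengths of the species tree are in
#' coalescent units and the tree must be ultrametric. Within each species
#' branch, lineages coalesce at rate C(k, 2); lineages remaining at the root
#' coalesce without time limit. Gene-tree branch lengths are the coalescent
#' times multiplied by \code{scale} (topologies are what downstream quartet
#' methods consume).
#'
#' @param species rooted ultrametric \code{phylo}, lengths in coalescent
#'   units.
#' @param n_genes number of gene trees.
#' @param seed integer seed.
#' @param scale multiplier applied to gene-tree branch lengths.
#' @return list of \code{phylo} gene trees.
#' @export
simulate_msc_gene_trees <- function(species, n_genes, seed = 1, scale = 1) {
  if (is.null(species$edge.length) || anyNA(species$edge.length))
    stop("species tree needs (coalescent-unit) branch lengths")
  set.seed(seed)
  ages <- node_ages(species)
  ntip <- length(species$tip.label)
  root <- ntip + 1L
  children <- split(species$edge[, 2], species$edge[, 1])

  sim_one <- function() {
    # a lineage is a list(label = newick fragment, age)
    recurse <- function(node) {
      lin <- if (node <= ntip)
        list(list(lab = species$tip.label[node], age = 0))
      else unlist(lapply(children[[as.character(node)]], recurse),
                  recursive = FALSE)
      top <- if (node == root) Inf else ages[species$edge[species$edge[, 2] == node, 1]]
      now <- ages[node]
      while (length(lin) > 1) {
        k <- length(lin)
        wait <- rexp(1, k * (k - 1) / 2)
        if (now + wait > top) break
        now <- now + wait
        pair <- sample.int(k, 2)
        a <- lin[[pair[1]]]; b <- lin[[pair[2]]]
        merged <- list(lab = sprintf("(%s:%.8f,%s:%.8f)", a$lab,
                                     scale * (now - a$age), b$lab,
                                     scale * (now - b$age)),
                       age = now)
        lin <- c(lin[-pair], list(merged))
      }
      lin
    }
    out <- recurse(root)
    ape::read.tree(text = paste0(out[[1]]$lab, ";"))
  }
  lapply(seq_len(n_genes), function(i) sim_one())
}

#' Fixture alignment with exact site-class counts
#'
#' Emits exactly the requested numbers of constant, variable-uninformative
#' and parsimony-informative columns (constructed to the definitions used by
#' \code{\link{classify_sites}}), in an order shuffled by the seed. PIS
#' columns carry two states whose minor-state count varies between 2 and
#' half the taxa, so observed variability spreads across them.
#'
#' @param n_taxa number of taxa (>= 4 when PIS columns are requested).
#' @param n_constant,n_variable_uninformative,n_pis column counts.
#' @param seed integer seed.
#' @return An \code{lba_alignment}.
#' @export
fixture_alignment <- function(n_taxa, n_constant, n_variable_uninformative,
                              n_pis, seed = 1) {
  stopifnot(n_constant >= 0, n_variable_uninformative >= 0, n_pis >= 0)
  if (n_pis > 0 && n_taxa < 4) stop("parsimony-informative columns need >= 4 taxa")
  if ((n_variable_uninformative > 0 || n_constant > 0) && n_taxa < 1)
    stop("need at least one taxon")
  set.seed(seed)
  L <- n_constant + n_variable_uninformative + n_pis
  taxa <- sprintf("t%02d", seq_len(n_taxa))
  if (L == 0) return(new_alignment(
    matrix(character(0), nrow = n_taxa, ncol = 0, dimnames = list(taxa, NULL)),
    "nucleotide"))
  m <- matrix("A", nrow = n_taxa, ncol = L, dimnames = list(taxa, NULL))
  bases <- c("A", "C", "G", "T")
  col_i <- 0L
  for (i in seq_len(n_constant)) {
    col_i <- col_i + 1L
    m[, col_i] <- sample(bases, 1)
  }
  for (i in seq_len(n_variable_uninformative)) {
    col_i <- col_i + 1L
    two <- sample(bases, 2)
    m[, col_i] <- two[1]
    m[sample.int(n_taxa, 1), col_i] <- two[2]   # singleton second state
  }
  for (i in seq_len(n_pis)) {
    col_i <- col_i + 1L
    two <- sample(bases, 2)
    choices <- 2:(n_taxa %/% 2L)
    minor <- choices[sample.int(length(choices), 1)]
    m[, col_i] <- two[1]
    m[sample.int(n_taxa, minor), col_i] <- two[2]
  }
  new_alignment(m[, sample.int(L), drop = FALSE], "nucleotide")
}
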