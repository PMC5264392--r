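---
title: "Diagnosing and alleviating long-branch attraction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing and alleviating long-branch attraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbalens)
```

## The artifact and the battery

Long-branch attraction (LBA) is the systematic error in which two long,
non-sister branches are inferred as sisters because convergent changes along
them outnumber the true synapomorphies on the short internal branch that
separates them. Parsimony is statistically inconsistent in this regime (the
Felsenstein zone), and distance methods under an under-parameterized model
inherit the same bias through under-corrected distances.

`lbalens` implements a comparative battery for a concatenated, codon-aligned
nucleotide supermatrix: build many filtered or modified variants of the
matrix, run tree inference and support measurement on each, and compare how
a focal trichotomy (here named J, C and HCX, with J and C on long stems) is
resolved across variants. The working hypothesis of such a battery is that
variants purged of saturated, fast-evolving signal should agree on the true
resolution while unfiltered matrices analyzed with LBA-prone methods drift
toward the "long branches together" artifact.

## Site-rate metrics

**Observed variability (OV)** of a column is the fraction of unordered taxon
pairs that differ, counted over pairs where both characters are unambiguous.
It is a pure variability measure: no tree, no model.

**TIGER** scores a column by partition agreement. Each column induces a set
partition of the taxa by character state (taxa with gaps or ambiguity codes
are left out of the partition). Column *i* agrees with column *j* to degree
`pa(i, j)` = the fraction of *j*'s blocks nested inside a single block of
*i*; the TIGER rate of *i* is one minus its mean agreement with all other
columns. Constant columns agree with everything (rate minimal); columns
whose pattern conflicts with most others score high. The implementation is
the exact O(L²·n) computation with identical-pattern columns deduplicated;
tests verify it against a brute-force nested-loop oracle.

**Handling of missing characters** (gaps, ambiguity codes) is not specified
by either metric's original description; here they are excluded from pair
counts (OV) and partitions (TIGER) rather than treated as extra states, so
that indel-rich columns are not automatically "fast".

## Site classification and rate tertiles

A column is *parsimony-informative* (PIS) iff at least two unambiguous
states each occur in at least two taxa; *constant* iff at most one state
occurs; otherwise *variable-uninformative*. The tertile partitioning sorts
the PIS by rate (OV or TIGER), splits them into three equal groups —
any remainder goes to the slow, then the medium group — and pads **each**
partition with **all** variable parsimony-uninformative columns. With
11,394 PIS and 17,882 variable columns this yields three partitions of
3,798 PIS and 10,286 columns each, matching the documented bookkeeping.
Padding with the *constant* columns as well is available via
`include_constant = TRUE`; the default follows the documented column
counts, which include only the variable sites.

## Saturation diagnostics

**Iss.** Per-site entropy is averaged over sites (H) and compared with the
expected per-site entropy at full substitution saturation (H_FSS), giving
Iss = H / H_FSS. H_FSS is computed *exactly for the alignment's number of
taxa*: for n sequences drawn i.i.d. from the global base frequencies q, the
expected plug-in entropy is a binomial sum, strictly below the population
entropy −Σ q log₂ q and converging to it as n grows. With this finite-sample
reference, fully randomized data score Iss = 1 at any taxon count, which is
the property that makes the index interpretable as "how far toward complete
randomization".

**Iss.c.** The critical value is estimated by Monte Carlo rather than looked
up from precomputed tables: alignments of the same length and base
composition are simulated on 4-taxon symmetric and asymmetric
(Felsenstein-zone-shaped) trees over a grid of depths; Iss.c is the mean Iss
at the depth where neighbor joining stops recovering the true topology in
95% of replicates (linearly interpolated between grid points). Observed Iss
(averaged over random 4-taxon subsamples when the gene has more taxa, the
scale at which Iss.c is simulated) is compared to Iss.c with a z-test using
a site-bootstrap standard error; "saturated" means significantly *above*
both critical values at α = 0.05. The test statistic and α are stated
choices — the published procedure flags genes "significantly" saturated
without naming a test.

**Regression screening.** For each gene, uncorrected p-distances are
regressed on patristic distances from that gene's tree (neighbor joining on
GTR+Γ distances here). Saturation flattens the regression: multiple hits
stop p from growing with true distance. Genes on the "left shoulder" of the
per-gene slope or R² density are flagged by a valley rule: a Gaussian kernel
density (Silverman bandwidth) is fitted and genes below the deepest
antimode left of the global mode are flagged, with a percentile fallback
when the density is unimodal. We regress p on patristic (not the reverse)
so that saturation compresses the slope toward zero, which is what the
left-shoulder convention expects.

## Block filtering

`gblocks_filter` re-implements the published Gblocks 0.91b semantics:
conservation classes from per-column identity counts (b1, b2), rejection of
runs of more than b3 contiguous nonconserved columns, trimming of every
block to highly-conserved terminal columns, rejection of gap-violating
columns (b5) together with adjacent nonconserved runs followed by one
re-trim pass, and a minimum block length b4. Undocumented corner cases of
the binary are resolved explicitly: ambiguity codes never count toward
identity, and frequency ties break alphabetically. Bit-compatibility with
the binary is not promised. The relaxed / default / strict presets use the
published parameter triples at 22 taxa (11/11/21, 11/17/21, 10/8/5, 5/10/50,
with-half/none/none) and proportional rescaling at other taxon counts.
Note the presets' b1 equals exactly half the taxa; the validator therefore
accepts b1 ≥ n/2.

## OV-sorted removal and the stopping rule

Columns are sorted fastest-first by OV and removed in increments of 250
(default). At each step the remaining matrix A and the removed fast sites B
are compared: r_AB correlates ML distances of A and B, r_MLp correlates ML
and p distances of B, both over unordered taxon pairs. As long as B is
dominated by saturated noise both correlations are depressed; when removal
reaches the informative sites the correlations jump. The published stopping
criterion ("stop at the end of the sharp increase") is qualitative; the
operationalization here calls step *i* sharp when its delta exceeds
`jump_factor` (default 3) times the median absolute delta of all prior
steps, in **both** series, and stops at the end of the longest run of sharp
steps. A trace with no sharp step returns a sentinel rather than an error.
The distance model is fitted once on the full matrix and reused at every
step (`refit = TRUE` refits per partition at cost).

## Trees, support and stem branches

Neighbor joining (with negative branch estimates clamped to zero, deficit
moved to the sibling edge), Fitch parsimony, and GTR+Γ likelihood computed
by Felsenstein pruning with four equal-probability discrete-Γ categories
(category means) are the desk-scale inference engines; exhaustive ML search
scores all unrooted topologies up to 9 taxa. These deliberately stand in
for large-scale ML searches — the package's claims are about the *relative*
behavior of matrix variants, not about reproducing any specific large tree.
Bootstrap support for the three rival resolutions of the focal trichotomy
resamples columns, infers a tree per replicate, and classifies it by clade
monophyly (anything non-conforming counts as "other"). Stem lengths are
measured on the edge subtending each clade's MRCA after outgroup rooting,
and reported as ratios to a reference clade — the quantity that shrinks
when filtering removes homoplastic signal from long stems.

## Quartet-agreement species trees

The coalescent step scores a candidate species tree by the number of
gene-tree-induced quartet topologies that agree with it — the ASTRAL
objective. Quartet topologies are read off node-count (unit-branch-length)
path distances via the four-point condition; ties mean an unresolved
restriction, which never scores. The search is exhaustive up to 9 taxa
(exact optimum, ties reported) and NNI hill-climbing from a neighbor-joining
start on mean topological internode distances beyond; exactness dominance
(exact ≥ heuristic) is asserted in tests. ASTRAL's constrained dynamic
programming is intentionally not reproduced — at battery scale (≤ ~15 taxa)
the simple search keeps the objective faithful and the code small. Gene
trees contribute topology only; branch lengths and support are ignored.

## Synthetic data: what it emulates, and what it does not

`simulate_alignment` evolves sites under GTR(+Γ) with per-site rate
categories drawn once, plus an optional positional multiplier that gives
"genes" codon structure (third positions faster). `fixture_alignment`
constructs matrices with exact counts of constant / variable-uninformative /
parsimony-informative columns, used for the bookkeeping checks.
`simulate_msc_gene_trees` samples gene trees under the multispecies
coalescent (one haploid lineage per species, coalescence at rate C(k,2)
within branches measured in coalescent units); its discordance matches the
closed form (2/3)e⁻ᵗ in tests.

**The J-C-HCX scenario.** `jcx_scenario` builds a 10-taxon species tree —
an outgroup and three 3-taxon crowns with stems in ratio ~2.3 : 1.5 : 1 —
wired to a chosen true resolution. Its defaults place the shape firmly in
the attraction regime, and two design findings fixed them:

* **The outgroup branch must be short** (default 0.05 substitutions/site).
  A long outgroup branch is itself the longest branch in the tree and
  attracts the longest stem (J) toward the root, which *mimics* the true
  resolution J(C,HCX) and masks the J–C attraction the scenario exists to
  produce. The two long branches of interest must be the two longest
  branches in the tree.
* **Rate heterogeneity is positional, not Γ** (third positions ×8; stems
  0.184 / 0.12 / 0.08; internals 0.0075). Γ-distributed rates spread each
  codon class across the whole rate spectrum, so the fast, misleading site
  class and the slow, clean class overlap and no filtering strategy can
  separate them. With discrete positional classes, third positions sit in
  the attraction window (stem × rate ≈ 0.6–1.5, where convergent support —
  quadratic in rate — overwhelms true support, linear in rate) while
  first/second positions stay below it.

Under these defaults, unfiltered parsimony and JC-distance neighbor joining
select the wrong "long branches together" resolution in the large majority
of replicates, while first+second-position, OV-sorted-filtered and
quartet-coalescent analyses (gene trees from model-corrected distances)
recover the truth — the directional behavior the battery is designed to
exhibit. What the scenario does **not** emulate: indels and alignment error
(the block filter is exercised on simulated gaps, not real misalignment),
compositional heterogeneity across lineages (a real LBA factor, out of
scope), heterotachy by default (available via the `heterotachy` argument),
and real plastome gene content. Passing tests on this generator shows the
battery behaves as designed under a known generating process — not that any
particular empirical matrix is free of artifacts.

## Numerical choices and problem sizes

* GTR(+Γ) pairwise ML distances maximize the two-sequence likelihood from
  the 4×4 pair count matrix, with model parameters (exchangeabilities, base
  frequencies, shape) estimated once on the full matrix by `optim.pml` on a
  neighbor-joining start; distances are capped at 5 substitutions/site and
  capped pairs flagged. Model choice among JC69 / K80 / GTR / GTR+G, when
  wanted, is by BIC on that one fit rather than per-partition model testing.
* Branch-length optimization runs to the engine's default relative
  tolerance; exhaustive search breaks likelihood ties first-found and
  reports their count.
* Degenerate inputs are contracts, not crashes: empty columns are constant,
  a single-state alignment has Iss = 0 (degenerate flag), a flat removal
  trace returns the no-stopping-point sentinel, a non-monophyletic clade
  yields "other" / an NA stem with a flag.
* Tests and the acceptance script run at deliberately modest sizes — the
  tertile bookkeeping on a 22 × 17,882 fixture, the supermatrix arithmetic
  on an 82-gene, 81,423-column constant matrix, the directional contrast on
  50 replicates of a 40-gene × 300-column scenario, coalescent closed-form
  checks at 10,000 gene trees — sizes at which every quantity is exactly
  recomputable in seconds to minutes on one core.

## Known limitations

TIGER is quadratic in alignment width and meant for gene-scale or
fixture-scale matrices, not 80-kb supermatrices. The Iss.c construction is
an operationalization of the published procedure (simulation to the
95%-recovery breakpoint), not a reproduction of DAMBE's precomputed tables;
absolute Iss.c values will differ from DAMBE's, the saturated/unsaturated
call is the comparable output. The Gblocks re-implementation follows the
documented algorithm, not the binary's every quirk. The exhaustive ML and
quartet searches refuse beyond 9 taxa by design; the NNI heuristics that
take over are local searches with no optimality guarantee.
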