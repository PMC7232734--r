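---
title: "Cross-tissue coexpression networks, module overlap, and clique analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-tissue coexpression networks, module overlap, and clique analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexatlas)
```

## The model

`coexatlas` compares weighted gene coexpression networks across a panel of
tissues. The per-tissue model is the standard weighted-network construction:
for genes $m, n$ with expression profiles $x_m, x_n$ across that tissue's
samples,

$$S_{mn} = |\mathrm{cor}(x_m, x_n)|, \qquad a_{mn} = S_{mn}^{\beta},$$

an unsigned network (the graph is undirected, so the correlation sign is
dropped) with soft thresholding by the power $\beta$: weak correlations are
pushed toward zero smoothly rather than cut at a hard threshold, which keeps
the network weighted and makes module detection far less sensitive to the
exact threshold. Direct adjacency is then augmented with shared-neighbor
structure through the topological overlap

$$\omega_{mn} = \frac{l_{mn} + a_{mn}}{\min(k_m, k_n) + 1 - a_{mn}},
\qquad l_{mn} = \sum_{u \neq m,n} a_{mu} a_{un},
\qquad k_m = \sum_{u \neq m} a_{mu},$$

and $1 - \omega$ is the clustering dissimilarity. Connectivity $k$ excludes
the self term; with adjacencies in $[0,1]$ this keeps $\omega \in [0,1]$,
with $\omega = 1$ on the diagonal. Genes are clustered by average linkage
(UPGMA) on $1-\omega$ and modules are cut from the dendrogram (below).

Modules from *different* tissues are compared purely through their gene
sets: a $2\times 2$ contingency table over the common gene universe and a
one-sided Fisher exact test (upper tail: over-overlap). Module pairs with
$p < \alpha$ form the edges of a module overlap graph whose nodes are
(tissue, module) pairs; the exact maximum clique of that graph is the
largest set of modules that are all mutually related across tissues — the
cross-tissue "ubiquitous program" readout. Finally, clique members can be
tested for gene-set enrichment by the hypergeometric test against any GMT
collection.

### Assumptions

* Expression profiles are comparable across samples within a tissue after a
  per-gene rank-based inverse normal transform; no further between-sample
  normalization is attempted.
* Coexpression is adequately captured by (absolute) Pearson correlation on
  the rank-transformed data — i.e. by a rank statistic; outliers influence
  results only through ranks.
* Tissues share a meaningful common gene universe; genes absent from any
  tissue are dropped before any network is built, and the same universe is
  the Fisher-test background for every module pair.

## Normalization

Each gene's profile is mapped to standard normal quantiles of its ranks
with the Blom offset, $\Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$, ties
receiving average ranks. The offset choice is conventional; any
order-preserving offset would give identical downstream results because
every later step depends on the data only through ranks. The transform is
applied per gene across samples (not per sample across genes): the point is
that each gene's profile be marginally normal so Pearson correlation is
well behaved. Constant genes have no rank information and are rejected with
an error naming the gene rather than silently imputed.

## Soft power selection

The scale-free fit diagnostic bins the connectivities $k_m$ into 10
equal-width bins (empty bins dropped), takes per-bin mean connectivity and
empirical frequency, and reports the signed squared correlation of
$\log_{10}(\bar k)$ versus $\log_{10}(p(k))$. Binning is required because a
weighted network has continuous connectivities rather than integer degrees.
A regular network (all $k$ equal, a single usable bin) has no defined fit;
it is flagged `degenerate` rather than raised as an error, since it occurs
legitimately at $\beta = 1$ on homogeneous data.

Two selection modes are provided:

* **fixed** (default): $\beta = 6$ for every tissue, with the sweep
  reported for inspection. One common power is what makes networks
  comparable across tissues — a tissue-specific power would confound
  cross-tissue differences with threshold differences.
* **strict**: the smallest candidate power with $|R^2| \ge 0.8$. If no
  power qualifies, the best-fitting one is chosen and flagged
  (`criterion_met = FALSE`) instead of failing the run.

The 0.8 criterion is applied to the squared correlation; both the raw
correlation and the signed square are reported so either convention can be
read off.

## Dynamic tree cut

The branch-cutting algorithm is this package's own, specified at the level
of observable behavior rather than as a port of any existing code. It uses
two ideas:

1. **A merge-height ceiling.** Merges above `cut_frac * max(height)`
   (default `cut_frac = 0.99`) are ignored. On topological-overlap
   dissimilarities, background genes attach to the tree only just below the
   maximum height; the ceiling drops them into the unassigned class
   (`grey`) instead of letting them pool into a spurious module. This is
   what a fixed-height static cut cannot do well, because real modules can
   sit at quite different heights.
2. **Recursive gap splitting.** Within each remaining component, an
   internal merge is a split point when the height gap to its taller child
   is at least `g * cut_height`, with
   `g = (0.25, 0.20, 0.15, 0.10, 0.05)[deep_split + 1]`. `deep_split`
   (0–4, default 2) thus controls how small a height gap still counts as a
   real branch boundary: higher values split more aggressively. Branches
   smaller than `min_module_size` are never modules; if both branches of a
   split point are too small, the node is kept as a single module rather
   than discarded, so raising `min_module_size` coarsens but never
   fragments the partition.

Degenerate input — a tree whose merge heights are all equal, as from a
constant dissimilarity — carries no shape information and yields a single
module when the gene count meets `min_module_size` (all `grey` otherwise).
Detected modules are ordered by decreasing size (ties broken by smallest
member gene identifier) and named from a fixed color palette,
`turquoise, blue, brown, ...`, with `grey` reserved for unassigned genes,
so module names are reproducible across runs. No module-merging post-step
(by eigengene similarity) is applied: the overlap analysis downstream
operates on gene sets, and merging would only blur the planted-truth
evaluation; the static cut is also provided for comparison.

Average linkage itself is delegated to `stats::hclust`; exact UPGMA merge
heights are monotone, but floating-point averaging can leave
$\sim 10^{-16}$ inversions, which are clamped (and anything beyond
numerical noise is treated as an internal error).

## Module overlap testing

* **One-sided test.** "Related modules" means over-overlapping gene sets;
  a depletion signal has no interpretation here. This matters: two-sided
  Fisher p-values would differ.
* **Raw p < α edge rule.** Edges use unadjusted p-values at
  `alpha = 0.05` by default; a Bonferroni option exists but is off, and
  the full results table (every tested pair with its p-value, significant
  or not) is always retained so any other correction can be applied post
  hoc.
* **Log-space computation.** On realistic atlases the minimum overlap
  p-values underflow double precision by hundreds of orders of magnitude.
  All p-values are computed as log hypergeometric tails
  (`phyper(log.p = TRUE)`) and carried as `log10_p` alongside `p`;
  thresholding compares on the log scale, so a p-value that prints as `0`
  still forms an edge correctly.
* **Background.** The universe is the common gene set after intersection —
  the only background both tissues share. `grey` is a residual class, not
  a module, and is never tested.
* **Tissue similarity** is summarized per tissue pair as the minimum
  module-pair p-value (on the log10 scale) plus the count of significant
  pairs; "closest tissues" = smallest minimum. This module-level minimum is
  an interpretation choice: one could instead test whole-tissue gene sets,
  but module-pair tests are what the pipeline defines.

## Maximum clique

The module overlap graph has no intra-tissue edges, so clique members
automatically come from distinct tissues. Exact search (the default) uses
igraph's Bron–Kerbosch implementation with pivoting; among equal-size
maximum cliques the lexicographically smallest node-name set is returned,
making the result deterministic. A greedy-plus-local-search heuristic mode
exists for very large graphs and is flagged `exact = FALSE` in its output —
it is a lower bound, never silently substituted. Either way the returned
members are re-verified pairwise against the edge set, independently of the
search path.

## Enrichment

Hypergeometric upper-tail p-values with fold enrichment
$(k/q)\,/\,(K/N)$, Bonferroni and Benjamini–Hochberg columns; the `fdr`
column is a documented alias of Benjamini–Hochberg. The universe for module
enrichment is the tissue's network gene set — genes outside the network
could never have been module members, so a whole-genome background would
overstate significance. Corrections count every term tested against the
universe; zero-overlap terms (p = 1 by definition) are then omitted from
the returned table. GMT input is the standard dialect (term, description,
genes, tab-separated); malformed lines are reported with their line number.

## The synthetic atlas

The generator is a latent-factor model. For each tissue $t$ and each
planted module active in $t$, a latent eigengene $e \sim N(0, I)$ is drawn
over the samples and each member gene is
$x_g = \lambda e + \sqrt{1-\lambda^2}\,\varepsilon$, so member genes have
unit variance and expected pairwise correlation $\lambda^2$. Background
genes, and member genes of modules inactive in that tissue, are i.i.d.
normal. Two deliberate choices:

* A module shared across tissues reuses the *same member-gene block* in
  every active tissue, but its eigengenes are drawn *independently per
  tissue*: what is shared is coexpression structure, not expression values.
  This is exactly what the Fisher-overlap analysis can detect, and nothing
  more.
* Identifiers (`G000001`, `T01_S001`) and member blocks are deterministic
  given the spec, and all randomness flows from one seed, so every fixture
  is reproducible bit for bit.

The demonstration conditions (`demo_atlas_spec()`) are 4 tissues × 600
genes × 100 samples: one 50-gene module with $\lambda = 0.9$ in all
tissues, one 30-gene tissue-specific module per tissue, background noise
`noise_sd = 1`. 100 samples sits inside the 71–500 range typical of
multi-tissue expression panels while keeping a full pipeline run around
five seconds; $\lambda = 0.9$ gives within-module correlations (~0.81)
of the strength real tissue panels show in their strongest modules.

What the generator does **not** emulate: count-scale (FPKM-like) marginal
distributions, library-size or batch effects, correlated background,
overlapping module membership, or hub structure within modules. Passing the
recovery tests therefore shows the pipeline's machinery is correct and
calibrated on clean factor-model signal — it does not show how the pipeline
degrades on messy real data, where power selection and `deep_split` may
need tissue-specific judgment.

## Numerical and testing choices

* Tolerances: TOM is validated against a naive triple-loop evaluation to
  $10^{-12}$ on 30-gene matrices (20 seeds); Fisher p-values against a
  direct binomial-coefficient sum to $10^{-10}$ relative over every table
  with total count ≤ 30, plus underflow checks on tables with
  $p < 10^{-250}$; maximum cliques against $2^{15}$ subset enumeration on
  50 random 15-node graphs; UPGMA against a quadratic-time textbook
  re-implementation via cophenetic matrices.
* Calibration: on label-shuffled null partitions the fraction of module
  pairs with $p < 0.05$ is compared, within ±0.03, to the *exact* null
  rejection probability of the discrete one-sided test (which is below
  0.05 — the test is conservative on discrete tables).
* Recovery: across 10 generator seeds, detected modules match planted ones
  with Jaccard ≥ 0.8 (in practice ≥ 0.94); across 5 seeds the end-to-end
  clique has size 4 with every member matching the planted shared module.
* Test problem sizes (600 genes, ≤ 100 samples, 15-node clique graphs)
  were chosen so the full suite runs in well under a minute; the matrix
  algebra is dense and scales as $O(n^3)$ in gene count, so real atlases
  of ~20k genes are feasible but take hours per tissue.

## Limitations

* Unsigned networks and plain Pearson only — no signed variant, no robust
  correlation (biweight midcorrelation), no block-wise decomposition for
  very large gene sets.
* The dynamic cut is a deliberately simple two-rule algorithm; it does not
  implement the hybrid (PAM-like) variant that reassigns borderline genes
  using dissimilarity to module cores.
* A fixed common power keeps tissues comparable but can leave individual
  tissues short of the scale-free criterion; strict mode exists, at the
  cost of comparability.
* The tissue-similarity summary (minimum module-pair p) is one of several
  defensible definitions and is labeled as such.
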