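---
title: "Absolute UniFrac: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Absolute UniFrac: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(absunifrac)
```

## The problem

Sequencing-based community profiles are compositional: read counts carry
information about proportions, not about how many organisms were present.
β-diversity metrics computed from proportions therefore cannot see changes
in total microbial load, even when the ecological hypothesis is about
biomass (blooms, proliferation, antibiotic die-off). When an external
quantification of load is available — flow cytometry cell counts, qPCR or
ddPCR 16S copy numbers, spike-ins — each sample's proportions can be
rescaled to absolute abundances, and β-diversity can be made load-aware.

This package implements the phylogenetic version of that idea. Weighted
UniFrac sums, over every branch $i$ of a phylogeny relating the taxa, the
branch length $b_i$ times the difference in the cumulative abundance of
the leaves descending from that branch:

$$U \;=\; \frac{\sum_i b_i\,\lvert x_i^a - x_i^b\rvert}
              {\sum_i b_i\,(x_i^a + x_i^b)}.$$

With per-sample proportions ($x = p$) this is the conventional relative
form $U^R$. Evaluated instead on absolute descendant counts
($x = c$, proportions times the sample's total load $N_s$), the same
formula becomes absolute UniFrac $U^A$: two samples with identical
composition but a $k$-fold load difference, which are invisible to $U^R$,
sit at distance $(k-1)/(k+1)$.

The generalized family interpolates how much abundant lineages dominate:

$$GU(\alpha) \;=\;
  \frac{\sum_i b_i\,(x_i^a + x_i^b)^{\alpha}
        \left\lvert\frac{x_i^a - x_i^b}{x_i^a + x_i^b}\right\rvert}
       {\sum_i b_i\,(x_i^a + x_i^b)^{\alpha}},
  \qquad \alpha \in [0, 1],$$

with $GU(1) = U$ exactly and $\alpha \to 0$ approaching incidence-like
behavior. On absolute counts this is $GU^A$, the tunable load-aware
metric; $\alpha$ controls how strongly the distance tracks microbial load
versus fine compositional structure.

## Numerical and structural choices

**Branch enumeration.** Every profile and kernel indexes against a fixed
postorder enumeration of the tree's edges plus one entry for the root's
own edge, computed once per tree and cacheable (`cache_branches()`). All
cumulative descendant sums are obtained in a single postorder pass shared
by all samples; repeated rarefaction iterations reuse the cached
enumeration rather than re-deriving branch structure.

**The root edge.** A missing root edge is treated as length 0, and an
unrooted basal multifurcation is adopted as the root with a zero-length
root edge (recorded in a `rooting_note` attribute). Both samples' totals
sit on the root edge, so it contributes nothing when totals are equal but
does contribute to absolute-mode distances when they differ; published
UniFrac implementations do not document their handling of this edge, so
users comparing outputs across tools should check it. All distances here
are invariant to the convention whenever the root edge has length 0.

**Empty branches in $GU$.** Branches with $x_i^a + x_i^b = 0$ are
excluded from both sums (the abundance ratio is undefined there), rather
than defining $0^0 = 1$ at $\alpha = 0$. A corollary, tested as a
property: taxa absent from both samples — and hence entire pruned
subtrees — never affect any distance, so pruning the tree to the observed
taxa is an optimization, never a correctness requirement.

**No rounding.** Rarefied counts are divided by depth and multiplied by
load as real numbers; absolute tables are generally non-integer and only
raw read tables entering rarefaction are required to be integral.

**Mode pipeline.** `pairwise_distances()` normalizes raw reads to
proportions and, for absolute weighting, multiplies by $N_s$. When every
sample has the same load the absolute and relative matrices coincide to
floating-point accuracy (the $N$ factors cancel), which is tested.

## The rarefaction-averaging workflow

Read-depth variation biases both Bray-Curtis and UniFrac through
richness. The workflow implemented by `rarefied_distance()` is:
subsample every sample's reads to a common depth (default: the minimum
retained read total) **without replacement** (multivariate
hypergeometric, drawn by sequential conditional hypergeometric draws);
divide by depth; multiply by each sample's load for absolute metrics;
compute the distance matrix; repeat (default 100 iterations) and average
the matrices elementwise. Averaging happens on distance matrices, not on
tables — the order matters and is fixed. Iteration $k$ uses seed
$\mathrm{seed}+k$, so any single iteration is reproducible in isolation.
Whether subsampling is with or without replacement is a genuine free
choice in rarefaction; without-replacement is the standard reading of
"subsampling" and is documented here so users can compare against
multinomial implementations.

## What the generators emulate

`grid_communities()` builds the full-factorial four-taxon design (every
ASV at absolute abundance 1, 10 or 100: $3^4 = 81$ communities, 3240
unordered pairs) used to characterize how the metrics respond to
abundance, composition and phylogeny jointly. `grid_tree()` supplies the
companion balanced topology `((ASV_1,ASV_2),(ASV_3,ASV_4))` with **unit
branch lengths as an explicit placeholder**: cross-metric correlations on
the grid depend quantitatively on branch lengths, and the package does
not invent a particular phylogeny as ground truth. On the placeholder
tree the correlations of $U^A$ with the other metrics order as
$r(U^A, BC^A) > r(U^A, U^R) > r(U^A, BC^R)$, and that ordering — not any
specific value — is the tested claim; supply your own branch lengths via
`grid_tree(branch_lengths = ...)` to reproduce correlations for a
particular phylogeny.

`random_fixture()` draws seed-deterministic test data shaped like real
amplicon studies: random binary topologies with exponential branch
lengths (mean 0.1), Dirichlet compositions (concentration 0.5, skewed as
amplicon data are), lognormal read depths (median 20 000), and lognormal
loads spanning a configurable log10 range whose default covers the span
reported across published quantitative profiling systems (roughly
$4\times10^5$ cells/mL to $2\times10^{12}$ copies/g). What it does *not*
emulate: phylogenetic signal in abundances (abundance is independent of
the tree), overdispersion beyond multinomial sampling, contamination, or
taxon-specific copy-number bias. Passing tests on these fixtures
demonstrate algebraic and statistical correctness of the machinery, not
ecological realism of any particular dataset.

## Evaluation statistics

`mantel_test()` correlates the upper triangles of two label-aligned
distance matrices (Pearson) with simultaneous row/column permutation of
the second; `load_difference_matrix()` ($|N_a - N_b|$, optionally on
log10 loads) lets you quantify how strongly any metric is driven by load
alone — the recommended calibration is to pick $\alpha$ *before*
ordination or testing, such that $GU^A$'s correlation to load is
comparable to $BC^A$'s (typically $\alpha$ between 0.1 and 0.6).
`permanova()` is a one-way PERMANOVA on squared distances with the
pseudo-F permutation test. Both use the add-one p-value convention
$(1+\mathrm{hits})/(1+\mathrm{permutations})$, so p is never exactly 0,
and both reproduce exactly under a fixed seed. The raw-difference (not
log) load matrix is the default because the quantity of interest is the
absolute abundance difference itself; `log10 = TRUE` is available where
loads span many orders of magnitude.

`error_sensitivity()` emulates quantification noise: each sample's load
is multiplied by $1 + u$, $u \sim \mathrm{Uniform}(-e, +e)$ — a uniform
multiplicative model, the minimal reading of "random variation by a given
percentage in either direction" — and the distance matrix is recompared
to the unperturbed one. Error levels are proportions in $[0, 1)$; $e \ge
1$ is rejected because loads must stay positive. On fixtures with a
ten-fold or larger load range, mean deviation grows monotonically with
$e$ and is smaller at $\alpha = 0.2$ than at $\alpha = 1$ — moderate
$\alpha$ buys robustness to load noise.

## Problem sizes used in the test suite

The suite exercises: 500 random instances for the algebraic identities
(including $GU(1) \equiv U$ to $10^{-15}$ and the equal-totals collapse
to $10^{-12}$); 200 random trees (up to 50 leaves) for the
kernel-versus-leaf-set-oracle equivalence at $10^{-12}$; 1000 random
equal-depth trees for the equal-branch-length bound; exhaustive
permutation enumeration for Mantel (5 samples) and PERMANOVA (6 samples)
against from-scratch brute force; 500 exchangeable 8-sample matrices for
the PERMANOVA type-I calibration at nominal 0.05; and rarefaction checks
on tables of 15-25 taxa at depths of 100-250 reads. These sizes were
chosen to make the Monte-Carlo assertions statistically stable while the
full suite runs in well under a minute per file.

## Known limitations

- **The equal-branch-length bound is topology-dependent.** The statement
  "with all branch lengths equal, $U^A \le BC^A$" is exact whenever equal
  lengths place every leaf at the same depth (stars, balanced trees —
  including the four-taxon simulation tree), and the suite verifies it on
  1000 such random instances. It is *not* true on arbitrary topologies:
  on unbalanced trees, same-sign differences nested under a deep clade
  are counted once per ancestral branch, and a frozen 8-taxon
  counterexample in the suite exhibits $U^A > BC^A$. Treat the bound as a
  balanced-tree intuition, not a theorem about real phylogenies.
- At $\alpha = 1$, $GU^A$ can become a near-proxy for load differences
  alone and is the setting most sensitive to quantification error; use
  the Mantel-to-load calibration above.
- PERMANOVA is one-way only; no stratified/multi-factor designs, and no
  dispersion (PERMDISP-style) diagnostics.
- No ordination, tree inference, copy-number prediction, or HDF5 BIOM
  I/O; tables move as dense TSV.
- Generalized UniFrac is computed per pair in a loop over branches, so
  cost grows with (pairs x branches); the branch cache removes redundant
  tree work across rarefaction iterations, but very large trees (tens of
  thousands of ASVs) will still be slow in the multi-alpha rarefied
  setting.

## A worked example

```{r example}
fx <- random_fixture(n_taxa = 12, n_samples = 6, seed = 7)
spec <- metric_spec("unifrac_generalized", "absolute", alpha = c(0.5, 1))
d <- rarefied_distance(fx$table, fx$tree, fx$loads, spec,
                       rarefaction_config(iterations = 25, seed = 1))
round(d$alpha_0.5[1:4, 1:4], 3)

mantel_test(d$alpha_1, load_difference_matrix(fx$loads, log10 = TRUE),
            permutations = 199, seed = 1)
```
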