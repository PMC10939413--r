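---
title: "Aggregated coexpression networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregated coexpression networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggcoex)
```

## The problem

A gene coexpression network (GCN) connects genes whose expression profiles
covary across RNA-seq libraries; by the guilt-by-association principle,
neighbors in such a network tend to share function, which makes GCNs a
practical function-prediction tool in crops where transgenic validation is
hard. When libraries come from many independent studies (bioprojects),
pooling them into a single correlation analysis favors genes expressed
everywhere and dilutes interactions that exist only under particular
conditions. `aggcoex` implements both strategies so they can be compared:
a pooled, non-aggregated network, and an aggregated network that infers a
network per study and combines them.

## Network inference

**FPKM and filtering.** Counts are normalized once, from the raw matrix:
$\mathrm{FPKM}(g,s) = c_{gs} \cdot 10^9 / (L_g \cdot T_s)$ with $L_g$ the
transcript length in bp and $T_s$ the per-sample total over all ingested
genes. Genes below 0.5 FPKM in at least 50% of the libraries under
consideration are removed. The boundary at exactly 50% is not determined
by the definition "low in half the libraries"; we resolve it inclusively
(a gene must clear the floor in a strict majority to survive), which is
deterministic and conservative, and both the floor and the fraction are
arguments. Genes with identical expression in every library are also
removed at filter time, because their Pearson correlation is undefined;
deferring that check would poison the ranking step.

**HRR.** For the non-aggregated route, the Pearson correlation of every
gene pair is computed over the pooled filtered libraries. Each gene sorts
its partners by descending correlation; $\mathrm{rank}(x,y)$ is the
position of $y$ in $x$'s list, and the highest reciprocal rank is

$$\mathrm{HRR}(x,y) = \max\{\mathrm{rank}(x,y),\ \mathrm{rank}(y,x)\},$$

a symmetric score that is small only when the attraction is mutual, which
suppresses one-sided correlations with promiscuous hub genes. The network
at sparsity $k$ (100 stringent, 300 relaxed) is the undirected union of
every gene's $k$ best partners by ascending HRR. Under this union
semantics the minimum node degree equals $k$ (each gene contributes its
own list) while well-connected genes can be chosen by many others and
reach far higher degree — the degree profile characteristic of these
networks. The alternative reading of the threshold, keeping only pairs
with $\mathrm{HRR} \le k$, yields a strictly mutual network whose degrees
are bounded by $k$; it is available via `mutual = TRUE` but is not the
default because it cannot produce the observed hub structure.

**COO aggregation.** For the aggregated route, samples are grouped by
study id, groups with fewer than `min_libraries = 6` libraries are
dropped, the single FPKM matrix is sliced per group and re-filtered
within each group, and an HRR network is built per group at the same
$k$. The co-occurrence score of a gene pair is the number of group
networks containing that edge; each gene then keeps its $k$ partners with
the highest co-occurrence. The node universe is the union of the
per-group gene sets, so a gene robustly expressed in a single study still
enters the aggregated network — this is where the aggregated networks'
larger gene complement comes from, and per-group filtering is the
mechanism behind it.

Two ranking details are underdetermined by the construction and fixed
here once: equal correlations (and equal HRR values) are ordered by
lexicographic gene id, making results platform-independent; and
co-occurrence ties — frequent, since frequencies are small integers — are
broken by the lower mean HRR of the edge across the groups containing it,
i.e. by the method's own strength score, before falling back to gene id.
Whether per-group networks should use the final sparsity was likewise
open; we use the same $k$ throughout, and `build_coo_network()` refuses
mixed inputs.

## Evaluation by neighbor voting

Annotation terms are first intersected with the network's node set and
restricted to 20–1000 genes (inclusive); smaller terms give unstable
AUROCs and larger ones are uninformative. For each term, annotated genes
are split into `n_folds` cross-validation folds (default 3, the
convention of the neighbor-voting family of evaluators; the count is an
argument). With one fold hidden, every gene is scored by the fraction of
its neighbors carrying the annotation, the hidden positives are ranked
among all non-training genes, and the ROC area is computed exactly via
the rank-sum identity with mid-ranks for ties — so ties cost exactly half
a pairwise win and the statistic matches brute-force ROC integration to
machine precision (the test suite asserts this equivalence on small
networks). A term's AUROC is the unweighted mean over folds; a dataset's
score is the unweighted mean over terms; 0.5 is chance and 0.7 is the
conventional bar for an acceptable functional-annotation performance.
Votes are unweighted edge indicators: neither HRR values nor
co-occurrence frequencies enter the vote, since no weighting rule is part
of the method being reproduced.

Seeding is layered: each term's fold assignment derives from a hash of
the term id combined with the user seed, so a term's AUROC is independent
of which other terms are evaluated, and any run is reproducible from a
single integer. `bioproject_subset_curve()` grows, per replicate, a
seeded nested chain of study subsets (2 groups, then +1 per step),
rebuilding and re-scoring networks at each size; per-group HRR networks
are computed once and reused across subsets for the aggregated method.

## Subnetworks and enrichment

A gene-centered network is the focus gene's first-degree neighborhood;
the intersection of two such neighborhoods (the focus genes included only
when they are coexpressed with each other) defines shared-process gene
sets such as a melting-flesh-style module around two functionally
redundant genes. Enrichment of a gene set is the upper-tail
hypergeometric probability of its overlap with each term, with
Benjamini–Hochberg control applied within each annotation dataset
separately (each dataset is its own testing family) and a default call
threshold of q < 0.1. The default universe is the source network's node
set rather than the whole genome: the subnetworks are drawn from the
network, so the network is the sampling frame; a genome-wide universe can
be passed explicitly.

## The synthetic generator

`simulate_dataset()` emulates the structure the method needs to be tested
against: several study groups, planted coexpression modules active in
some groups and silent in others, and realistic count noise. Genes have
log-uniform baselines (1–100 FPKM) and lengths (500–5000 bp); genes of a
module active in a group share a per-sample latent factor on the
log-expression scale, with loadings chosen so the log-scale pairwise
correlation equals `within_module_correlation`; counts are negative
binomial (dispersion 0.05) with per-sample depths log-uniform over one
decade (2–20 M fragments), so FPKM normalization genuinely matters.
Annotations contain one term per module plus an equal number of random
decoy terms. Defaults — 2000 genes, 5 groups × 10 libraries, 10 modules
of 30 genes, correlation 0.8 — describe a modest but realistic
compendium. `module_presence_probability = 0.7` reflects that
condition-dependent modules are the phenomenon aggregation exists to
capture: most modules appear in most studies, none is guaranteed in all,
and every module is forced active somewhere so its term is learnable.

What the generator does *not* emulate: organ and developmental-stage
covariates, batch effects beyond depth variation, correlated background
genes, annotation noise (decoys are uniform, real annotation errors are
structured), and read-level artifacts. Passing tests on this generator
therefore demonstrates that the machinery is correct and that aggregation
recovers planted condition-specific signal; it does not certify
performance numbers on real compendia, whose AUROCs are reproducible only
in distribution.

## Numerical choices and degenerate inputs

* Undirected edges are stored once, lexicographically smaller gene first;
  files diff deterministically and round-trip through `write_network()` /
  `read_network()`.
* `k >= G` returns the complete graph with a warning rather than failing.
* Terms with fewer annotated network genes than folds are skipped with a
  warning; a fold left without positives or without training genes
  contributes `NA` and is dropped from the fold mean.
* A sample with zero total counts, a gene without a length entry, a
  duplicated id, a self-loop edge, or an annotation file with no usable
  term each fail fast with the offending entity named.
* AUROC is computed from ranks, not from a trapezoid over thresholds, so
  there is no curve-resolution parameter anywhere.

## Problem sizes

The shipped test suite works at sizes chosen to give the statistics room
without waste: structural checks at 600 retained genes (where the
degree-floor property is asserted for both k = 100 and k = 300),
permutation calibration with 200 random terms on a 300-gene network,
planted-signal recovery at 1000 genes, and the aggregation trend over 5
replicate chains on 6 groups of 8 libraries. The acceptance script runs
the full default configuration (2000 genes, 5 groups) end to end.

## Known limitations

Only Pearson correlation is offered (no Spearman or context-likelihood
variants); module discovery (WGCNA-style clustering) is out of scope, as
are degree-bias corrections to neighbor voting, GO-hierarchy-aware
enrichment, and any identifier translation between genome annotation
versions — gene ids are opaque strings throughout. Dense correlation and
rank matrices bound the practical size to a few tens of thousands of
genes, which matches the intended plant-genome scale.
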