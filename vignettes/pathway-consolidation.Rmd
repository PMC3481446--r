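---
title: "Consolidating multi-source pathway collections into pathway concepts"
author: "pathconsol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating multi-source pathway collections into pathway concepts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathconsol)
```

## The problem

Public pathway databases (KEGG, Reactome, WikiPathways, BioCarta, NCI
Nature, HumanCyc, ...) overlap heavily.  When several of them are merged
into one collection — reduced to the simplest common representation, the
gene-membership set — many entries are exact duplicates of each other,
strict subsets of a more general pathway, or near-copies with a handful of
genes swapped.  Running gene-set enrichment on such a collection returns
dozens of highly ranked pathways that are really the same biology repeated,
which skews interpretation and buries distinct signals.

`pathconsol` implements one-sided Fisher's exact enrichment for a resultant
gene set (the output of a genome-wide experiment, e.g. differentially
expressed genes) plus three complementary algorithms that consolidate a
merged collection into *pathway concepts*: disjoint clusters of pathways,
each labelled by its most enriched member and scored by the lowest
enrichment p-value among its members.

## Enrichment model

For a pathway with $K$ genes in the background universe of size $N$, a
resultant set with $n$ genes in the background, and observed overlap $x$,
the enrichment p-value is the upper hypergeometric tail

$$p = P(X \ge x) = \sum_{i \ge x} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

the one-sided Fisher's exact test on the 2×2 membership table.  Genes
outside the background are removed from both the resultant set and each
pathway before the table is built; this is the only way the margins are
coherent when the background is a measurement platform rather than the
whole genome.  When no background is supplied, the union of all pathway
genes is used as a genome proxy.  Raw p-values drive everything downstream
(threshold $\alpha = 0.05$ by default, compared as $\le \alpha$ /
$> \alpha$ exactly); a Benjamini–Hochberg column is emitted for users but
never consumed by the consolidation procedures.

## Enrichment Consolidation (EC)

EC consolidates only the enriched pathways, in a way that is specific to
the experiment.  Each round selects the currently most enriched pathway as
a concept representative, removes its genes from the working resultant set
*and* from every remaining pathway's effective gene set, recomputes the
p-values on the reduced sets, and absorbs into the new concept every
pathway that is no longer significant.  Because at least the representative
leaves the working set each round, the loop terminates within the initial
number of enriched pathways, and the concepts partition exactly the
initially enriched set.

Interpretive choices (the procedure's written form leaves them open):

* recomputed table margins use the reduced resultant set and reduced
  pathway sets but the **original background size** — shrinking the
  universe would inflate later p-values unpredictably;
* a pathway whose effective gene set (or effective overlap) drops to zero
  is absorbed into the current concept: an empty overlap is the limiting
  non-significant case;
* ties in the minimum p-value are broken by larger current overlap, then
  byte-lexicographic id, making the output independent of file order.

## Weighted Consolidation (WC)

WC clusters *all* pathways containing at least one resultant gene, enriched
or not.  Genes are first weighted per (gene, pathway) incidence by their
interaction excess: with $M$ the gene's degree in a genome-wide PPI
network, $K$ the pathway size and $N$ the genome size, the expected number
of within-pathway interactions under no specific association is
hypergeometric with mean $E(X) = MK/N$; the weight is $w = X - E(X)$
rescaled to $W = \log_2(w + 2)$ for $w > 0$ and $W = 1$ otherwise, so
$W \ge 1$ always.  Pathway pairs are scored by the weighted overlap of
their resultant genes — shared genes contribute the mean of their two
pathway-specific weights to the numerator; genes in exactly one pathway add
that pathway's weight to the denominator — giving a similarity in $[0,1]$
that reduces to the Jaccard index of the resultant-gene overlaps when all
weights are equal.  Pairs are then visited from highest to lowest
similarity (ties: lexicographic pair id) and greedily merged: an
unclustered pair opens a cluster, a half-clustered pair attaches the free
member, a fully clustered pair is skipped.  Concepts therefore always have
at least two members.

Two readings had to be fixed: the similarity uses the rescaled $W$ (the raw
$w$ can be negative, which would break the proportion), and zero-similarity
pairs are never processed (otherwise the first rule would chain unrelated
pathways).  Only interaction counts feed the weights — no co-expression or
annotation terms — and the genome size $N$ defaults to the union of the
network universe, all pathway genes and the resultant set, the smallest
universe under which the expectation is well-posed everywhere it is used.

## De novo consolidation (DC)

DC is independent of any experiment: pathways are compared through
attribute sets $A_i$ under three modes — `membership` (the gene set
itself), `goslim` ("guilt-by-function": the union of the member genes'
GO-Slim terms, a function vocabulary without gene ids), and `ppi`
("guilt-by-association": the member genes augmented with their interaction
partners).  The three modes are deliberately kept separate rather than
merged into one attribute union: each produces a distinct family of
clusterings with its own interpretation.  Pairwise distances are Jaccard,

$$J = \frac{|A_i \cap A_j|}{|A_i \cup A_j|}, \qquad d = 1 - J,$$

with $J$ defined as 0 for two empty sets (no attributes, no evidence of
relatedness).  Agglomerative hierarchical clustering (single linkage by
default, matching the horizontal-cut semantics of a dendrogram; average and
complete selectable) is cut either to a requested maximum number of
clusters or at a distance threshold.  The cuts are nested: the partition at
$k$ clusters refines the one at $k-1$, and lowering the distance cutoff
never increases the cluster count.  The standard menu crosses the three
modes with cluster counts 5, 10, 20, 40, 50, 100, 200 and 500 (capped at
the number of pathways), and can be precomputed once per collection.
A cutoff cut applies merges at distance $\le$ the threshold; Jaccard
distances are rational, so an exact tie with a user threshold is a
measure-zero event we do not special-case.

## Interaction-density validation

Whether a concept's genes actually belong together is checked by a
randomization test: count network edges with both endpoints in the
concept's gene union, then compare against the edge counts of draws of the
same number of genes taken uniformly from the network node set (1000 draws
by default).  The add-one empirical p-value
$(1 + \#\{\text{draws} \ge \text{obs}\})/(1 + \text{reps})$ never reaches
zero — its floor is $1/(\text{reps}+1)$ — so a normal-tail approximation
from the null mean and standard deviation is reported alongside, clamped at
$10^{-150}$ and printed as `< 1e-150` beyond that; genuinely extreme
concepts are far outside anything 1000 draws can represent.

## The synthetic benchmark generator

Real merged collections and PPI compendia are snapshots of external
databases; nothing in this package downloads them.  Instead,
`simulate_database()` plants the structure the algorithms are supposed to
recover: disjoint gene *pools* act as true concepts; each pathway samples a
uniform fraction (default 0.5–0.9) of its pool plus a couple of off-pool
noise genes, reproducing the heavy overlap and near-subset redundancy of
aggregated sources; exact-duplicate groups, strict subsets and empty
pathways can be injected at configured counts; the network is an
Erdős–Rényi two-level graph with within-pool edge probability `p_in = 0.3`
and between-pool `p_out = 0.005`; each pool carries its own annotation
terms (genes pick each pool term with probability 0.7, at least one);
and the resultant set includes enriched-pool genes with probability 0.6
versus 0.02 for everything else.  Defaults describe a small but
recoverable regime — 5 pools of 30 genes in a 1000-gene genome, 4 pathways
per pool — chosen so that planted membership is unambiguous at pool
granularity while single fixtures stay sub-second; tests use 20 seeds where
a distributional claim is made.  Every component (pathways, edges,
annotations, resultant set) draws from its own sub-stream of the master
seed, so changing one component's parameters never perturbs the others'
draws.

What the generator does **not** emulate: scale-free degree structure, the
correlated multi-database provenance of real collections, GO's DAG depth
(pool terms are flat), or expression-level noise.  Passing recovery tests
on planted pools therefore demonstrates algorithmic correctness, not
biological performance on real compendia.

## Calibration study design

One test checks that enrichment p-values are honest under a null resultant
set (inclusion probability identical inside and outside the "enriched"
pools).  Exact tests on discrete tables are conservative: with small
pathways or a tiny resultant set, the attainable p-value just below 0.05
sits well under it, and the rejection fraction would fall visibly short of
the nominal level.  The calibration fixture therefore uses one pathway per
pool (disjoint gene sets, hence independent tables), pools of 100 genes in
a 1000-gene genome, and inclusion rate 0.3, where the discreteness gap is
small; the pooled rejection fraction over 50 seeds is then required to
match 0.05 within three binomial standard errors.  This design was fixed
before the test was first run, on the analytic grounds above.

## Problem sizes and determinism

The test-suite fixtures run at deliberately desk-friendly sizes (hundreds
of genes, tens of pathways; the identical-set arithmetic check builds a
2,665-pathway collection once), keeping the full suite under a minute.
All tie-breaks use byte-order (`radix`) string comparison, never locale
collation, and every stochastic routine takes an explicit integer seed, so
identical inputs give byte-identical outputs across platforms.

## Known limitations

* EC consolidates only enriched pathways; everything else is reported
  unassigned.  WC covers non-enriched pathways but needs a PPI network
  that actually covers the genes at hand — pathways whose members have no
  recorded interactions fall back to uniform weights ($W = 1$), where the
  score degenerates to plain resultant-gene Jaccard.
* A resultant set of a single gene makes EC and WC group trivially; use DC
  in that regime.
* The OBO parser handles `is_a` and `part_of` only — standard GO-Slim
  mapping practice, but other relation types are ignored.  The two-column
  gene→slim TSV is the canonical input; the OBO/GAF route is a
  convenience.
* Name-based merging of same-named pathways across sources is available
  (`merge_named_pathways()`) but off by default: it changes gene-set
  contents and only exact case-insensitive name matches are merged;
  partial-name disambiguation is deliberately not guessed at.
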