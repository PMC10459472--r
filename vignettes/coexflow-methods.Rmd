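---
title: "coexflow methods: from counts to candidate hubs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coexflow methods: from counts to candidate hubs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexflow)
```

`coexflow` chains the standard count-based transcriptomics toolchain —
reliability filtering, TMM/CTF normalization, precision-weighted linear
models with two moderation schemes, multi-algorithm co-expression
clustering, and correlation networks — into one seeded, fully scripted
workflow for ordered multi-group designs. This vignette explains the
model behind each stage, the tunable parameters and their defaults, the
numerical choices, what the synthetic generator does and does not
emulate, and the known limitations.

## The design and its contrasts

The workflow assumes an ordered categorical design: groups are stages
(e.g. `0h < 1h < 3h < 6h`), each with a small number of replicates
(the reference design is 4 × 3). All pairwise contrasts are formed as
*later minus earlier*, so a positive log2 fold-change always means
expression rises along the series; adjacent transitions are listed
first, then pairs of increasing span (`1v0, 3v1, 6v3, 3v0, 6v1, 6v0`
for four stages). Group order comes from an explicit order column in
the groups file, never from lexical sorting, because labels like `10h`
sort wrongly as text.

## Filtering and normalization

A gene is *reliable* when its CPM strictly exceeds `cpm_threshold`
(default 1) in at least `min_samples` samples (default 3, the
replicate count per group). The count is taken over all samples by
default; a `reliable_within_group` switch restricts it to a single
group, since with triplicates one cannot tell from the phraseology
"three replicates" alone whether the three must be co-located — both
readings are exposed and the permissive one is the default. The filter
report splits the input three ways (never expressed / expressed but
unreliable / reliable), which is the shape of the first summary a
practitioner inspects.

TMM factors are computed by the canonical trimmed-mean-of-M-values
procedure via `edgeR::calcNormFactors`: reference sample = closest
upper-quartile CPM to the mean; per sample, gene-wise log2 ratios (M)
and mean abundances (A) against the reference over genes nonzero in
both; double trimming (30% of the M tails, 5% of the A tails);
factor = 2 to the inverse-variance-weighted mean of the surviving M
values; factors rescaled to geometric mean 1. The test suite checks the
factors against an independent, explicitly enumerated trim-and-weight
oracle to 1e-10.

CTF ("count adjustment with TMM factors") divides counts by the
sample's TMM factor *only* — deliberately not by library size — which
is the adjustment recommended for correlation analyses, where dividing
by a noisy per-sample total would itself induce spurious covariance.
With unit factors CTF leaves counts untouched. The artifact file keeps
the conventional name `CTFnormalisedCPMs-` even though the values are
factor-adjusted counts, not per-million values; this is flagged here
because the two are easy to conflate.

Dispersion is summarized as a single common negative-binomial
dispersion φ maximizing the adjusted profile likelihood given the
group-means design (`edgeR::estimateGLMCommonDisp`), reported as
BCV = √φ. A BCV drop after filtering/normalization is the usual sanity
signal. Sample similarity is displayed two ways: classical scaling of
pairwise leading-fold-change distances (root-mean-square of the top 500
absolute log fold-changes per sample pair — the conventional RNA-seq
MDS; 500 is configurable) and PCA on the gene-standardized log-CPM.

## Differential expression

The mean–variance relationship of counts is removed with precision
weights (`limma::voom`): log2-CPM with a 0.5 count offset and a +1
library offset, per-gene linear fits, a locally weighted regression
(span 0.5) of the square-root residual standard deviation on average
log count, and per-observation weights `predicted-sd^-4`. The weighted
least-squares fit on the group-means design is re-parametrized to all
later-vs-earlier contrasts.

Two moderation schemes are run side by side:

* **Empirical Bayes** (`limma::eBayes`): per-gene variances are
  squeezed toward a prior estimated by moment matching on the
  log-variances; moderated t with pooled degrees of freedom.
* **Fold-change threshold** (`limma::treat`, default
  `fc_threshold = 1.2`): tests the composite null |log2FC| ≤ log2(1.2),
  with p = P(T > (|β|−τ)/se) + P(T > (|β|+τ)/se). At threshold 1 this
  reduces *exactly* to the empirical-Bayes two-sided p — a reduction the
  tests assert at 1e-12 — and for τ > 0 it is uniformly more
  conservative, which is why it is the primary DEG caller for designs
  with few replicates.

DEGs are genes with Benjamini–Hochberg adjusted p strictly below
`p_cutoff` (default 0.1 — chosen to avoid treating 0.05 as a bright
line, with the conservativeness delegated to the fold-change
threshold). The per-contrast summary table reports totals and up/down
splits for both methods plus their ratio. *Ubiquitous* DEGs are the
intersection of DEG sets over all contrasts under the threshold test,
falling back to empirical Bayes when that intersection is empty (a
common outcome: a single quiet adjacent transition empties the
intersection), with the method recorded.

## Co-expression clustering

Only DEGs are clustered. Because genes far outnumber samples, DEGs with
coefficient of variation (sd/mean of CTF values across all samples)
at or below `cv_threshold` (default 0.2) are dropped first: a flat
profile carries no shape to cluster. CV is computed on the CTF scale
*before* standardization, since the CV of a scaled row (mean 0) is
undefined. Profiles are then row-standardized and the dissimilarity is
d = 1 − r on Pearson correlation. (A `sqrt(2(1−r))` variant — the true
Euclidean embedding of standardized profiles — is available behind a
flag; 1 − r is the default because it is the quantity practitioners
quote, and the two are monotonically equivalent so rankings and
dendrogram topologies agree.)

Three algorithms are run on the same genes:

* **AHC** — the linkage among average/single/complete/Ward with the
  highest agglomerative coefficient (`cluster::agnes`) builds the
  dendrogram. The cut adapts to the tree rather than using a fixed
  height: candidate branch counts are scored by average silhouette
  width and the best is kept; when even the best cut has average
  silhouette ≤ 0.25 (the usual "no substantial structure" rule of
  thumb) everything collapses to one cluster. Clusters under
  `min_cluster_size` dissolve to the unassigned label 0.
* **k-means** — 25 random restarts per candidate k (seeded) over
  `k_min..k_max` (clamped so k·min_cluster_size ≤ n). Ten validity
  indices — Calinski–Harabasz, average silhouette, Davies–Bouldin,
  Dunn, C-index, McClain–Rao, Ratkowsky–Lance, Hartigan's rule,
  Krzanowski–Lai, and the gap statistic (20 uniform reference
  bootstraps) — each vote for their preferred k; the mode wins, ties
  break toward the smaller k (parsimony), and the full tally is kept in
  the solution's selection evidence so the vote can be audited.
* **MBC** — Gaussian mixtures by EM over k and six covariance families
  (spherical/diagonal/full × shared/varying; the full-covariance pair
  is dropped when genes ≤ dimensions), selected by BIC
  (`mclust::Mclust`), assignment by maximum posterior responsibility.

`enforce_min_size` dissolves undersized clusters (default minimum 10
genes, chosen so downstream functional readings have material) and
reassigns their genes to the nearest retained centroid. Cluster
profiles are per-cluster per-sample medians with standard deviations as
error bars, on both the scaled and the CTF scale. Solutions are
compared on average silhouette width, Calinski–Harabasz and the
within/between sum-of-squares ratio, plus pairwise Rand indices, and
ranked by silhouette — the practical answer to "which clustering should
I read first".

## Networks and hub genes

For each cluster of each solution, all pairwise Pearson correlations of
the scaled CTF profiles are tested with the t transform
(t = r·√((n−2)/(1−r²)), n−2 df) and BH-adjusted within the cluster's
pair family. An edge requires |r| strictly above `r_cutoff` (default
0.75, so shared variance r² = 0.5625 > 50%, leaving 44% to chance) and
adjusted p below `edge_alpha` (default 0.05; a level had to be fixed
and the conventional one is used). Pairs are processed in blocks so the
full pair matrix is never materialized beyond the CV-filtered set.

Node metrics: degree; shortest-path betweenness on the unweighted graph
(a |r|-weighted variant is available); Louvain communities (seeded);
and the Kleinberg hub score, computed as the principal eigenvector of
the symmetric adjacency matrix, sign-fixed to non-negative entries,
entries below 1e-10 clamped to zero, max-normalized to 1. On an
undirected graph the hub and authority scores of the HITS algorithm
coincide, and the eigen route is both deterministic and exactly the
definition; the tests cross-check it against an independent power
iteration to 1e-8. Isolated nodes score 0.

*Outstanding* genes satisfy score > `hub_score_min` (0.9) **and**
degree > `hub_degree_min` (10), both strict, evaluated within each
cluster's network and unioned with per-cluster provenance — per-cluster
rather than on a merged graph, because each cluster's network is also
the unit the artifacts are written by; a merged "global" scope is
available. Ubiquitous DEGs join the hub table under their own flag, and
per-algorithm hub sets plus their intersection are reported.

## The synthetic generator

`simulate_counts` draws counts as NB(mean = lib_s · q_g,group ·
2^(module effect), dispersion φ), with variance μ + φμ² so BCV = √φ.
Defaults emulate the reference study conditions: 4 stages × 3
replicates, 2000 genes at desk scale, log-normal baseline means
(meanlog 4, sdlog 1.5 — median ~55 counts with a long right tail),
φ = 0.05 (BCV ≈ 0.22, typical for controlled biological replicates),
10% DE genes with |log2FC| = 2 switching on at a random stage (so the
planted effect is present in every contrast that spans the switch), and
a log-normal library-size spread (sdlog 0.2). Planted modules share a
per-sample Gaussian latent factor on the log2-mean scale, scaled by a
per-gene loading — this preserves count marginals while controlling
correlation; a hub module gives its hub a larger loading than its
satellites, so hub–satellite correlation provably exceeds
satellite–satellite correlation whenever residual noise is non-zero.
Module genes are flagged DE so the DEG-restricted clustering can see
them.

What the generator does *not* emulate: batch effects, sample swaps,
isoform structure, zero inflation beyond the NB, and outlier libraries.
Passing tests therefore demonstrate correctness of the machinery and
recoverability under clean planted conditions, not robustness to every
real-data pathology.

Two fixture choices deserve a note. First, the dedicated clustering
fixtures orthogonalize the module latent factors: with only a dozen
samples, two independently drawn factors can correlate above 0.5 by
chance, silently merging "separate" modules — orthogonalization is what
"well-separated planted modules" actually means at this sample size.
Second, the star-module network fixtures give module genes a high,
narrow baseline (meanlog 6, sdlog 0.5): correlation estimates for
low-count genes are dominated by shot noise, which would probe the
generator's noise floor rather than the centrality behaviour under
test.

## Numerical choices and degenerate inputs

* Strict inequalities everywhere a threshold is named (CPM, p, CV, r,
  score, degree), so boundary values are excluded — asserted by
  boundary tests.
* Constant gene profiles scale to all-zero with a warning; zero-variance
  genes must be removed before correlation distances (error).
* An empty DEG set short-circuits clustering and networking with a
  clear message rather than erroring.
* k-means vote ties break toward the smaller k; the cluster-count vote
  and BIC table are preserved in the solution for audit.
* All stochastic steps (k-means restarts, gap-statistic bootstraps,
  Louvain, simulation) derive from the single config seed; identical
  seed + config reproduce byte-identical artifacts apart from the
  timestamp in file names.
* Cluster labels are always relabeled 1..k by decreasing size, with 0
  reserved for unassigned genes.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so
statistical behaviour is measurable yet a full run stays interactive:
2000 genes × 12 samples for pipeline-level checks (a complete run takes
a few seconds), 1000–2000 genes for seeded simulation batteries,
60-gene 3-module designs for clustering recovery, and 16-gene star
modules for hub scoring. Study-scale figures quoted in the literature
(tens of thousands of transcripts) depend on raw sequencing data and
are outside what synthetic desk-scale runs can or should reproduce.

## Known limitations

* Only the common dispersion is estimated; gene-wise/tagwise shrinkage
  is out of scope, so BCV is a summary, not a per-gene model.
* The adaptive dendrogram cut is silhouette-guided; it is not the
  published dynamic hybrid tree-cut algorithm, and on dendrograms with
  nested fine structure the two can cut differently.
* The treat-style test uses the standard composite two-tail formulation;
  robust empirical-Bayes variants are not implemented.
* Correlation networks are marginal (no partial correlations), so hub
  scores measure connectivity, not causality.
* P-values for correlation edges assume approximately jointly normal
  scaled profiles; for heavy-tailed count-scale profiles they are
  approximate, which is why the |r| cutoff, not the p-value, is the
  primary edge filter.
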