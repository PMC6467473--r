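---
title: "Methods: modelling the capacitation transcriptome trajectory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the capacitation transcriptome trajectory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capacitrack)
```

## The scientific problem

Naïve human pluripotent stem cells must undergo *capacitation* — a
progression over roughly ten days toward formative/primed pluripotency —
before they respond productively to germ-layer induction cues. Bulk RNA-seq
time courses of this transition (e.g. days 0, 1, 2, 3, 7, 10 in biological
triplicate, in more than one cell line) raise four recurring analysis
questions that this package answers as a single tested pipeline:

1. **Which genes move?** Highly variable genes from the mean-CV²
   relationship, and a differential-expression union across all timepoint
   pairs.
2. **How do they move?** Soft (fuzzy c-means) clustering of standardized
   temporal profiles into the five canonical dynamic archetypes: early
   down, late down, up-and-down, early up, late up.
3. **Do two datasets move the same way?** Cluster correspondence between
   cell lines or species (through 1-to-1 orthologs), reported as the
   fraction of genes in the *same* cluster and in *same-or-similar*
   (same-direction) clusters.
4. **Where along embryonic development is each sample?** Fractional
   identity of each sample relative to embryonic epiblast stage signatures
   (pre-implantation EPI, early and late post-implantation, "post-E" and
   "post-L"), by simplex-constrained least squares.

Every stage is exercised on synthetic data with planted ground truth, so
the package's guarantees are stated — and tested — as recovery properties.

## Variable-gene detection

For gene $g$ with linear-FPKM mean $\mu_g$ and squared coefficient of
variation $\mathrm{CV}^2_g = \sigma^2_g/\mu_g^2$ across samples, the
technical expectation is the standard mean-variability trend
$$\log \mathrm{CV}^2 = \log\!\left(\frac{a_1}{\mu} + a_0\right),$$
fitted by bounded nonlinear least squares (`minpack.lm::nlsLM`,
$a_0, a_1 \ge 0$, initialized at $a_0 = \mathrm{median}\,\mathrm{CV}^2$,
$a_1 = \mathrm{median}(\mathrm{CV}^2\mu)$). A gene's **excess** is its
observed $\log \mathrm{CV}^2$ minus the fitted value. Selection applies
thresholds on both axes of the CV²-vs-mean plot: mean $\log_2$(FPKM+1)
$\ge$ 1 and excess $\ge$ 1 (natural-log units, i.e. CV² at least $e$-fold
above the trend) by default. The excess threshold of 1 sits several
standard errors above the sampling noise of a per-gene CV² estimated from
$\sim$36 samples, which is what makes precision high without sacrificing
recall on genuinely variable genes; both thresholds are configuration keys,
since studies differ in depth and replication. FPKM values are floored at
$10^{-6}$ before any log or ratio.

The differential-expression stage is deliberately a fully specified
stand-in: Welch's t-test on $\log_2$(FPKM+1), Benjamini–Hochberg adjustment,
and the filter padj < 0.01 with linear fold change > 2 computed on group
means with pseudocount 1. The scientific content carried forward is the
*filter and the union over all timepoint pairs per cell line*, not the test
engine; a `p_values` hook accepts per-gene p-values from any external
count-model engine. Degenerate genes are handled explicitly: zero variance
in both groups with equal means gives p = 1; unequal means with zero
variance give the smallest representable positive p.

## Soft clustering of temporal dynamics

Replicates are averaged per timepoint *within each cell line* (the
clusterings are derived separately per dataset and compared afterwards),
then each gene's profile is standardized to mean 0, SD 1 across timepoints;
flat genes are dropped with a reported count. Fuzzy c-means alternates the
classic updates
$$u_{gc} = \Big(\sum_j (d_{gc}/d_{gj})^{2/(m-1)}\Big)^{-1},\qquad
  \mathbf{c}_c = \frac{\sum_g u_{gc}^m \mathbf{x}_g}{\sum_g u_{gc}^m},$$
with Euclidean distance, until the largest centroid shift is below `tol`
(default $10^{-9}$). The objective $J=\sum u^m d^2$ is non-increasing per
iteration and is recorded per iteration for audit. Membership ratios are
computed relative to the per-gene minimum distance before exponentiation,
so small fuzzifiers underflow far clusters instead of overflowing near
ones — this is what keeps $m \to 1^+$ (near k-means) numerically exact. A
point coinciding with a centroid takes membership 1 there, by the limit
convention.

Defaults: fuzzifier $m = 1.25$ (soft-clustering practice for standardized
expression profiles; larger $m$ blurs the five archetypes together), 10
random restarts (initial centroids are $k$ genes sampled without
replacement under the given seed) with best-final-objective selection, and
hard assignments by membership argmax with ties to the lowest cluster
index.

### Choosing k: the elbow, operationalized

"Elbow method" is not an algorithm until one fixes the curve and the bend
criterion. We record, for each candidate $k$, the hard within-cluster sum
of squares $J(k)$ (mean over restarts and best restart) and select the $k$
maximizing the second difference of $\log J$ on the best-restart curve.
The log scale matters: for any steeply decreasing convex $J(k)$ the *raw*
second difference peaks at the smallest $k$ whatever the data structure,
whereas relative curvature peaks where the proportional gain collapses —
the actual elbow. On planted five-archetype data the log-scale criterion
selects $k=5$ essentially always. Results with maximum log-scale second
difference below 0.25 carry a low-confidence flag: planted cluster
structure sits an order of magnitude above this threshold and structureless
single-archetype noise an order of magnitude below it, and the test suite
exercises both regimes.

### Semantic labels

With $k=5$ the centroids are named by geometry. The transient (`up_n_dn`)
centroid is the one whose largest excursion from the midpoint of its
endpoints is interior *and* whose net start-to-end change is under half its
range. (An excursion, not a peak: this keeps the rule symmetric under sign
flips, where the transient cluster shows an interior trough.) The four
monotone centroids split by the sign of the net change, and within each
pair the one reaching half of its total change earlier is `early`.
Ambiguous geometries (two transient candidates, or not a 2+2 monotone
split) raise an error with diagnostics rather than guessing. In the
synthetic generator, "early" means $\ge$90% of the change is complete by
the 2nd of 6 timepoints and "late" means $\le$10% before the 4th; these
operationalize the archetype names and are configurable.

## Cluster correspondence

Two clusterings are compared over the genes clustered in both datasets
(intersection; asymmetric genes are tallied, not silently dropped). Cluster
identities are aligned either by semantic labels (when both sides have
them — then the published numbering 1..5 is used on both sides) or by the
assignment-problem optimum on centroid Pearson correlations, solved exactly
by permutation search for $k \le 9$; centroids over different time axes are
linearly interpolated onto a common normalized axis. A mean matched-centroid
correlation below 0.5 flags the mapping as low-confidence.

A gene is **same** when its mapped cluster ids agree, **similar** when both
clusters fall into the same direction group of the active scheme. Two
schemes ship as presets, because the published within-hPSC and
embryo-vs-hPSC comparisons group clusters differently: within-hPSC puts
clusters {1,2} down and {4,5} up (the transient cluster 3 belongs to no
group); embryo-vs-hPSC groups embryo {1,2} with hPSC {1,2} down and embryo
{3,4,5} with hPSC {4,5} up, since embryo cluster-3 genes end above their
starting level while in-vitro cluster-3 genes return to baseline.
Transient-cluster genes that the scheme places in no group count as
*neither*.

## Fractional stage identity

Stage signatures are arithmetic means of the reference cells of each stage
(EPI, post-E, post-L; ICM is shown in PCA overlays but excluded from the
deconvolution basis), restricted to the harmonized gene set. Each sample
$\mathbf{x}$ is decomposed by the quadratic program
$$\min_{\mathbf f} \|S\mathbf f - \mathbf x\|_2^2 \quad \text{s.t.}\quad
  \mathbf f \ge 0,\ \textstyle\sum_s f_s = 1,$$
solved with a primal active-set method in which the sum-to-one constraint
is an exact equality in the KKT system (never a penalty): the
equality-constrained subproblem on the current free set is solved exactly,
blocking bounds are added at the minimum feasible step, and bounds are
released by the most negative multiplier. Rank-deficient signature sets are
ridge-stabilized and flagged non-unique rather than fatal. Deconvolution
operates on linear-scale FPKM (the mixture model $S\mathbf f$ is additive
on the linear scale) over the harmonized variable-gene set by default; gene
set and scale are configurable since conventions differ. Replicate
fractions are averaged per timepoint with their SD.

The test suite cross-checks the solver against three independent oracles:
an exhaustive $10^{-4}$-step grid on the 1-simplex, Monte-Carlo sampling of
$10^5$ random feasible points, and a penalty-plus-renormalization solver
(nonnegative least squares on the penalty-augmented system).

## Sample-level summaries

Pearson correlation between samples is computed on log2 values over
expressed genes ("expressed" defaults to FPKM $\ge$ 1 in $\ge$ 1 sample, a
convention exposed in the configuration); zero-variance samples are flagged
NA. PCA mean-centers each gene and decomposes by SVD, with the sign of each
component fixed so its largest-magnitude loading is positive (determinism
across platforms). Joint projections of a time course with a reference
dataset concatenate samples over harmonized genes; no batch correction is
applied — dataset-of-origin separation (typically the leading component
when mixing bulk and single-cell data) is reported, not removed.

## What the synthetic data emulates — and what it does not

The generator plants: five archetype mean trajectories plus flat background
on the log2 scale (per-gene baselines 3–7 log2 units, swings 2–4),
multiplicative log-normal noise with exact target CV (default replicate CV
0.1–0.2, chosen as a plausible bulk-RNA-seq replicate dispersion; the
original study does not report one), stage references with marker-block
signatures, mixtures with known simplex weights, ortholog tables with
many-to-one decoys, and GMT gene sets with one set enriched ($\ge$80%) in a
chosen archetype. A negative-binomial count mode backs the DE stand-in
tests.

Passing tests on these data demonstrate *algorithmic correctness and
recoverability under the planted model*: clean archetypes, homoskedastic
log-scale noise, no batch effects, no dropout, no isoform or length biases,
no correlated genes. They do not certify performance on real libraries,
where the mean-variance relationship is heavier-tailed and cluster
boundaries are genuinely fuzzy. The published headline correspondence
figures (61.7%/83.9% between cell lines; 28.9%/66.3% versus mouse;
39.0%/83.1% versus macaque) depend on the original sequencing data, which
has no printed accession; they are therefore not reproduction targets here
— the pipeline reproduces their *arithmetic* exactly on hand-counted
examples and their *qualitative structure* on planted fixtures.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately modest sizes that still separate
signal from noise decisively: 1000 genes for cluster recovery, 20 seeds ×
k in 2..9 for the elbow study, 500 genes / 100 mixtures for deconvolution,
5200 genes for variable-gene selection, and a 2000-gene two-line demo for
the end-to-end pipeline. Convergence tolerances: centroid shift $10^{-9}$
($10^{-7}$ inside the elbow scan, where only $J$ differences matter);
active-set tolerance $10^{-10}$; simplex feasibility validated to $10^{-9}$
on input and $10^{-6}$ on output. Ties are broken deterministically
throughout (lowest cluster index; gene id order), and all stochastic steps
consume an explicit integer seed, restoring the caller's RNG state.

## Known limitations

- The DE stand-in is a Welch test, not a count model; with very low counts
  or two replicates its power differs from negative-binomial engines. Use
  the `p_values` hook to substitute one.
- Semantic labelling assumes the five-archetype geometry; other k values
  return unlabelled clusters.
- Cluster-id matching is exact only for $k \le 9$ (permutation search).
- Fractional identity inherits the usual deconvolution caveats: signatures
  must be linearly independent on the active set, and fractions are
  relative similarities, not physical proportions of cell types.
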