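# capacitrack

Transcriptome-trajectory analysis of pluripotent stem cell **capacitation**
— the multi-day progression of naïve human pluripotent stem cells toward
formative/primed pluripotency — built for bulk RNA-seq time courses
(e.g. days 0–10, several replicates, several cell lines) compared against
embryonic epiblast references.

The package is aimed at computational biologists who need the four standard
questions about such a time course answered reproducibly:

1. **Variable genes.** Per gene, the squared coefficient of variation
   CV² = σ²/μ² is regressed on mean expression via the trend
   log CV² = log(a₁/μ + a₀); genes are selected by thresholds on mean
   log₂FPKM (x axis) and residual log CV² above the trend (y axis). A
   Welch-test stand-in with Benjamini–Hochberg adjustment implements the
   differential-expression filter (padj < 0.01, fold change > 2) and its
   union over all timepoint pairs per cell line.
2. **Temporal clusters.** Fuzzy c-means (memberships
   u = (Σⱼ(d_c/d_j)^{2/(m−1)})⁻¹, fuzzifier m = 1.25, multi-start) on
   standardized per-timepoint profiles, with the cluster number chosen by an
   elbow criterion on the within-cluster sum of squares and k = 5 clusters
   labelled semantically: early_down, late_down, up_n_dn, early_up, late_up.
3. **Cluster correspondence.** Between cell lines or species (through
   strictly 1-to-1 orthologs): fraction of shared genes in the *same*
   cluster and in *same-or-similar* (same direction group) clusters, with
   the two published grouping schemes shipped as presets. Per-cluster
   gene-set enrichment by exact hypergeometric upper-tail tests.
4. **Fractional stage identity.** Each sample is decomposed onto embryonic
   epiblast stage signatures (EPI, post-E, post-L) by the quadratic program
   min ‖S f − x‖² subject to f ≥ 0, Σf = 1, solved with an exact
   active-set method.

A synthetic-data module generates every input with planted ground truth
(archetype trajectories, stage signatures, known mixtures, ortholog decoys,
enriched gene sets), so the whole pipeline is testable without downloads.

## Worked example

```r
library(capacitrack)

# a synthetic two-cell-line time course with 300 planted variable genes
tc <- generate_timecourse(n_genes = 2000, n_variable = 300,
                          noise_cv = 0.15, seed = 7)

fit <- fit_cv2_trend(tc$matrix)
fit
#> <cv2_fit> log CV2 = log(0/mu + 0.04022), 2000 genes in fit
hvg <- select_variable_genes(fit)          # 300 genes

prof <- standardize_profiles(to_log2(tc$matrix)[hvg, ], tc$sheet,
                             cell_line = "line1")
mm <- label_clusters(fuzzy_cmeans(prof, k = 5, m = 1.25, seed = 1))
mm
#> <membership_matrix> 300 genes, k = 5, m = 1.25, J = 14.1777
#> cluster sizes (hard): 60 60 60 60 60
#> labels: 1=late_down 2=late_up 3=early_up 4=up_n_dn 5=early_down

# same genes clustered independently in the second cell line, then compared
prof2 <- standardize_profiles(to_log2(tc$matrix)[hvg, ], tc$sheet,
                              cell_line = "line2")
mm2 <- label_clusters(fuzzy_cmeans(prof2, k = 5, m = 1.25, seed = 1))
correspondence_fractions(canonical_assignments(mm),
                         canonical_assignments(mm2),
                         cluster_scheme("hpsc_vs_hpsc"), shared_genes = hvg)
#> <correspondence_result> scheme = hpsc_vs_hpsc, n = 300
#>   same: 300 (100.0%)   same-or-similar: 300 (100.0%)   neither: 0

# fractional identity of known mixtures against stage signatures
ref <- generate_stage_reference(1000, stages = c("EPI", "postE", "postL"),
                                cells_per_stage = 15, seed = 8)
sig <- build_signatures(ref$matrix, ref$sheet, c("EPI", "postE", "postL"))
mix <- generate_mixtures(ref$signatures,
                         rbind(c(0.9, 0.1, 0), c(0.3, 0.6, 0.1),
                               c(0.05, 0.35, 0.6)),
                         noise_cv = 0.1, seed = 9)
solve_fractions(sig, unclass(mix$matrix)[, 2])
#> <fraction_profile> EPI=0.3090 postE=0.5858 postL=0.1052  (residual 303.7)
```

The fuzzy clustering recovers the five planted archetypes in equal groups
of 60; both cell lines share every archetype, so 100% of genes land in the
same (semantically numbered) cluster. The recovered stage fractions track
the planted mixing weights (0.3/0.6/0.1) to within the noise level; the
residual is the Euclidean misfit of the mixture model on linear FPKM.

The full pipeline — filtering, variable genes, clustering, labelling,
correspondence, enrichment, signatures, fractions, PCA, correlation, with
TSV intermediates and a JSON run manifest — runs from one call:

```r
make_demo("demo_in", seed = 7)
run_pipeline("demo_in", "demo_out", default_config(list(seed = 7)))
```

or from the shell via `inst/scripts/capacitrack` (`demo` and `run`
subcommands).

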