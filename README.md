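# kitlink

Links T cell **clonal expansion** to **phenotypic cluster membership** in
paired single-cell RNA-seq + TCR-seq experiments, with the statistics used in
studies of kidney-infiltrating T cells (KITs) in murine lupus nephritis. The
package is aimed at immunologists analyzing 10x Genomics 5' gene expression +
V(D)J data with cell hashing: it reproduces, as tested reusable functions, the
full path from raw count tables to the headline result that high-frequency
T cell clones are enriched in exhausted phenotypic clusters.

## What it computes

**Preprocessing.** Hashtag (HTO) demultiplexing calls a cell a singlet when a
single hashtag carries strictly more than 70% of its HTO UMIs (raw fractions;
CLR values are computed for reporting). QC removes cells with < 200 detected
genes or a mitochondrial UMI fraction > 0.10. Expression is log-normalized,
x(g,c) = log2(1 + n(g,c) / N(c) * 10^4); variable genes are selected by
z-scored dispersion log(var/mean) within 20 equal-frequency mean-expression
bins; total UMI, mitochondrial, ribosomal and hemoglobin content are regressed
out per gene (OLS) and residuals z-scored and clipped; PCA feeds a shared
nearest-neighbor (SNN) graph (k-NN, Jaccard edge weights, pruned at 1/15) that
seeded Louvain clustering partitions across a 0.1-2.0 resolution sweep.
One-vs-rest Wilcoxon rank-sum marker detection applies the usual
10% detection / 0.25 average logFC / 0.01 Bonferroni thresholds.

**Scoring.** A per-cell signature score is the within-cell one-sided Wilcoxon
rank-sum of signature genes against all other measured genes, reported as
-log10(p) (exact, tie-aware mid-p for small universes). Cell-cycle phases are
assigned Tirosh-style: phase-set mean minus an expression-matched control-set
mean; G1 iff both S and G2/M scores are non-positive.

**Clonotypes and linkage.** Cells with exactly one productive TRA and one
productive TRB are clonotyped by exact nucleotide CDR3 pair identity. Clones
are tiered unique (1 cell) / shared (2-4) / moderate (> 4) / high-frequency
(top quartile by cell-weighted cumulation over descending clone sizes). The
tier x cluster contingency is tested per cluster by 2x2 Pearson chi-square
(1 df, no continuity correction; exact hypergeometric fallback for sparse
tables), Bonferroni-corrected over 9 comparison groups; exhaustion score by
tier is tested by one-way ANOVA with Tukey HSD and Kruskal-Wallis.

**Synthetic cohorts.** `simulate_cohort()` generates all four inputs (counts,
HTO table, contig table, signatures are shipped) with ground-truth labels:
negative-binomial counts with planted cluster/signature/phase programs,
hashtags with doublets and ambient background, and a clone-size law with
tier-conditional cluster assignment. `preset_mrl()` and `preset_yaa()` are
calibrated so the pipeline reproduces published aggregate proportions
(e.g. P(exhausted | high tier) = 0.79 and 0.344, the 0.231 all-cells exhausted
marginal, and top-quartile thresholds of 13 and 40 cells).

## Worked example

```r
library(kitlink)

sc     <- preset_yaa(n_cells = 10000, seed = 1)   # Yaa-calibrated scenario
cohort <- simulate_cohort(sc)

pairs  <- filter_productive_pairs(cohort$contigs)
clones <- call_clonotypes(pairs)
clones <- assign_tiers(clones, compute_high_threshold(clones))
clones
#> <clonotype_set> 4676 clonotypes over 8075 cells (largest 59)

tiers <- clones$cells$tier[match(cohort$truth$barcode, clones$cells$barcode)]
rep   <- linkage_report(tier_cluster_table(tiers, cohort$truth$cluster))
rep
#> <linkage_report> 8075 cells
#> cluster-group percentages by tier:
#>          exhausted
#> unique       21.05
#> shared       19.26
#> moderate     18.57
#> high         34.67
#> all          23.83

enr <- rep$enrichment_vs_unique
enr[enr$cluster %in% c("early_T_EX", "terminal_T_EX", "transitional"),
    c("cluster", "obs_prop", "ref_prop", "chi_sq", "p_adj")]
#>         cluster obs_prop ref_prop  chi_sq    p_adj
#> 2    early_T_EX    0.176   0.1831   0.457 1.00e+00
#> 8 terminal_T_EX    0.171   0.0274 399.251 7.21e-88
#> 9  transitional    0.239   0.1686  42.203 7.41e-10
```

Reading: of the 8,075 cells with an intact TCR, 34.7% of high-frequency-clone
cells sit in the two exhausted clusters versus 23.8% of all cells; the
terminal exhaustion cluster holds 17.1% of high-frequency cells but only 2.7%
of unique-TCR cells — a chi-square of 399 on 1 df, overwhelmingly significant
after Bonferroni correction over the 9 clusters. The expression side of the
pipeline (`qc_filter`, `log_normalize`, `select_variable_genes`,
`regress_and_scale`, `run_pca`, `build_snn_graph`, `louvain_cluster`,
`find_markers`, `score_signature_per_cell`, `score_cell_cycle`) runs the same
way; see the methods vignette.

## Acceptance script

`scripts/acceptance.R` regenerates both calibrated cohorts from scratch at
n = 10,000 cells, runs clonotype calling, tiering and the linkage report
against the ground-truth cluster labels, and writes the recovered percentages
(high-tier exhausted mass for both models; all-cells exhausted marginal;
unique- and high-tier occupancy of the terminal-exhaustion and transitional
clusters) as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
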