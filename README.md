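# orscreen

Screening a gene family for over-expressed members in a tumor cohort.

Large gene families that are normally silent in a tissue — the ~408-member
olfactory receptor (OR) family is the motivating case — are sometimes
ectopically expressed in tumors. `orscreen` implements a reference-anchored
screen that asks, for every family gene, whether a cohort of tumors shows
upregulation that is simultaneously **significant**, **prevalent** and
backed by **high-level DNA amplification**, and then characterizes the
genes and patients that drive the signal.

## The screen

Expression is taken from raw read counts to
FPKM = count · 10⁹ / (length_bp · total mapped reads), log2-transformed
with a pseudocount, and converted to z-scores against a small panel of
normal reference tissues:

```
Z_ij = (X_ij − X̄_i) / σ_i
```

where `X_ij` is the log2 FPKM of gene *i* in tumor *j* and `X̄_i`, `σ_i`
are the mean and sample SD over the reference panel. Over the cohort of
*m* tumors with at least one family gene at `Z ≥ 2`, each gene gets:

- **sum of upregulation**  `S_i = Σ_j Z_ij`
- **upregulated-case count**  `n_i = Σ_j 1[Z_ij ≥ 2]`
- **weighted upregulation**  `W_i = n_i · S_i`
- **prevalence**  `n_i / N` over the full study population

Each statistic is thresholded at the one-sided normal upper 95% point of
its cross-gene distribution (mean + 1.6449 · SD). Part 1 of the selection
keeps genes with `S` and `W` above threshold; part 2 keeps genes with
`n` and `W` above threshold; their intersection, further intersected with
genes carrying a GISTIC call of 2 (high-level amplification) in at least
one case, is the **over-expressed set**. A mirror screen with `Z ≤ −2`
covers downregulation. Downstream tools cluster the over-expressed genes
and the positive cases (Euclidean/Ward, or dominant-gene assignment),
tabulate clinical composition, compare Oncotype DX / PAM50 panel genes
across patient sub-populations by one-way ANOVA, and compare survival
between carriers and non-carriers by Kaplan–Meier curves and the
log-rank test.

A synthetic-cohort generator (`cohort_config()` / `generate_cohort()`)
produces count, copy-number, clinical, annotation and mutation tables
with recorded ground truth, and is the basis of the package's validation
suite.

## Worked example

Generate a cohort of 960 tumors and 4 normal references in which three of
408 family genes are planted with a 6-SD shift in disjoint 20% carrier
groups (plus amplified decoy genes), then run the full funnel:

```r
library(orscreen)

cfg <- cohort_config(planted_genes = data.frame(
  gene = c(10L, 150L, 300L), delta = 6, carrier_fraction = 0.2))
bundle <- generate_cohort(cfg, seed = 7)
res <- screen_bundle(bundle)
res
#> Over-expression screen (direction: up )
#>   part 1 (sum & weighted):    3 genes
#>   part 2 (count & weighted):  3 genes
#>   shared:                     3 genes
#>   highly amplified:           11 genes
#>   over-expressed:             3 genes
#>   flagged cases:              580 of 960
sort(res$overexpressed)
#> [1] "ORsim0010" "ORsim0150" "ORsim0300"
```

The three planted genes are recovered exactly: 11 genes carry a
high-level amplification call (the 3 planted plus 8 decoys), but only
the planted ones also pass both expression thresholds. 580 of 960 cases
have `Z ≥ 2` in at least one over-expressed gene (the 576 planted
carriers plus a few chance exceedances). Clustering those positive cases
by their dominant gene recovers the three planted sub-populations, each
defined by one gene:

```r
pos <- names(res$case_flags)[res$case_flags]
subpops <- cluster_cases(res$z[sort(res$overexpressed), pos], mode = "argmax")
subpops$defining_genes
#>   subpop   gene_id contrast        F             p
#> 1      I ORsim0010 5.890011 2003.901 2.033489e-260
#> 2     II ORsim0150 4.386925 2353.470 3.356498e-278
#> 3    III ORsim0300 4.434481 2198.339 1.281498e-270
```

Survival stratification by one gene (no hazard link was planted here, so
the curves do not separate):

```r
stratify_by_gene(res$z, "ORsim0300", bundle$clinical)
#> Survival stratified by ORsim0300 upregulation
#>   n = 960 ( 192 upregulated )
#>   log-rank chi-square = 0.046, p = 0.83
```

The prevalence histogram shows the expected structure — most family genes
upregulated in under 5% of the population, the planted genes in over 12%:

```r
prevalence_summary(res$stats)
#>   [0,0.05) [0.05,0.1) [0.1,0.12)   [0.12,1]
#>        384         20          1          3
```

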