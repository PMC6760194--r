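---
title: "Methods: reference-anchored screening for over-expressed gene-family members"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-anchored screening for over-expressed gene-family members}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orscreen)
```

## The model

`orscreen` screens a gene family — by default a 408-member family such as
the olfactory receptors, normally near-silent outside their home tissue —
for members that are over-expressed in a tumor cohort. The screen rests
on three ideas:

1. **Reference-anchored z-scores.** Expression is quantified as
   log2(FPKM + pseudocount) and compared to a small panel of normal
   tissues: `Z_ij = (X_ij − X̄_i)/σ_i`, with `X̄_i` and `σ_i` the mean
   and sample SD (n − 1 denominator) of gene *i* over the reference
   columns. `Z_ij ≥ 2` counts a case as significantly upregulated; the
   boundary is inclusive because the indicator is defined as
   `1 if Z ≥ 2`. The implicit assumptions are that log2 FPKM is roughly
   Gaussian around its tissue baseline and that the reference panel's
   dispersion is representative of null (non-upregulated) variation.
   Both matter: the panel is small (four samples in the motivating
   design), so a panel whose SD badly underestimates cohort dispersion
   makes every case of that gene look extreme.

2. **Cohort burden statistics.** Over the *m*-patient cohort (tumors
   with at least one family gene at `Z ≥ 2`), each gene accumulates a
   sum of upregulation `S_i = Σ_j Z_ij`, an upregulated-case count
   `n_i`, a weighted upregulation `W_i = n_i · S_i` (exact product, by
   construction), and a prevalence `n_i / N` over the full population.
   The definition of `S_i` is ambiguous in the source formulation — it
   may include every z-score of the cohort or only positive or
   above-cut values — so `burden_stats()` exposes `sum_mode =
   c("all", "positive", "above_cut")` with `"all"` as the literal
   default, and `screen_diagnostics()` reports every funnel set size
   under all three definitions.

3. **Upper-tail thresholds and the two-part funnel.** Each statistic is
   thresholded at the one-sided normal upper `1 − α` point of its
   *cross-gene* distribution: `mean + z₁₋α · SD` (1.6449 at α = 0.05).
   This treats the family's statistic distribution as the null and asks
   which genes are outliers within their own family. Part 1 requires
   `S` and `W` above threshold, part 2 requires `n` and `W`; the shared
   set, intersected with genes carrying a high-level amplification call
   (GISTIC 2) in at least one case, is the over-expressed set. The
   amplification intersection is gene-level: amplification and
   upregulation need not occur in the same patient. A mirror screen on
   −Z covers downregulation with the same machinery.

No multiple-testing correction is applied beyond the threshold rule
itself; the rule is a family-internal outlier criterion, not a per-gene
hypothesis test.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `pseudocount` | 1 | FPKM | keeps log2 finite at zero counts |
| `z_cut` | 2 | reference SDs | upregulation cut (magnitude; the mirror screen uses −2) |
| `alpha` | 0.05 | — | upper-tail probability of the threshold rule |
| `multiplier` | `qnorm(1 − alpha)` | SDs | overridable threshold multiplier |
| `sd_floor` | 1e-8 | log2 FPKM | genes with smaller reference SD are unscreenable |
| `sum_mode` | `"all"` | — | which z-scores enter `S_i` |
| `k` (genes, cases) | 3 | clusters | tree-cut count; an empirical choice, not a constant |

Totals for FPKM default to the column sums of the supplied count matrix
(overridable per sample); a zero-total sample yields an all-zero column
with a warning rather than an error, since drop-out samples occur in
real exports.

## Clustering and group comparisons

Gene groups and patient sub-populations use agglomerative clustering
with Euclidean distance and Ward linkage (`hclust`, `ward.D2`), on
z-scores by default so gene scales are comparable. Rows are sorted
lexicographically before clustering, which makes results independent of
input order; exact-tie merges are then resolved deterministically.
`cluster_cases()` offers two modes, because "supervised clustering" of
cases admits two readings: `"tree"` (cut the Ward tree at k) and
`"argmax"` (label each positive case by the gene with its maximal
z-score). The argmax reading matches the structure in which each
sub-population is defined by one dominantly upregulated gene, and it is
the mode the package's own recovery checks use: a case that exceeds the
cut in two over-expressed genes at once — which happens at roughly the
alpha level among hundreds of positive cases — has a genuinely ambiguous
dominant gene, and is excluded from label-agreement measures for that
reason. Each sub-population's defining gene is the gene maximizing the
within-minus-outside mean z contrast.

Group comparisons (burden statistics across gene groups, panel genes
across sub-populations) use one-way ANOVA. A zero within-group variance
with distinct means reports `F = Inf, p = 0`; all-equal values report
`F = 0, p = 1`. Panel genes come from the packaged 21-gene Oncotype DX
and 50-gene PAM50 symbol lists (`oncotypedx_genes`, `pam50_genes`),
overridable via an explicit gene list or annotation tags. No
multiplicity correction is applied by default, matching per-gene
p ≤ 0.05 reporting; Benjamini–Hochberg is available (`adjust = "BH"`).

Survival uses the product-limit estimator and the two-group log-rank
test with hypergeometric variance and no continuity correction (via the
`survival` package), with the standard events-before-censorings
convention at ties. The "upregulated" stratum reuses the screen's
`z_cut`; for a gene group, a case is upregulated if any member gene
exceeds the cut.

## The synthetic-cohort generator

`generate_cohort()` emulates the *structure* the screen assumes, with
ground truth recorded for every planted feature:

- **Gene space.** 408 family genes with low-to-moderate baselines
  (log2 FPKM mean U(4, 6), SD U(0.5, 1)) among 2000 background genes
  (mean U(4, 9), SD U(0.5, 1.5)) plus the clinical panel symbols. The
  family's low baseline reflects ectopic expression of a normally
  near-silent family and keeps planted carriers from dominating a
  sample's library size, which would distort every other gene's FPKM in
  that sample. Transcript lengths are U(500, 4000) bp and per-sample
  depths U(10⁶, 3×10⁷), so the FPKM conversion is exercised
  non-trivially; counts are integers obtained through the FPKM inverse.
- **Reference panel.** Reference columns are stratified normal scores —
  the expected order statistics of a standard normal sample of the
  panel size, rescaled to unit SD, plus 25% jitter — permuted
  independently per gene. This makes the panel SD a representative,
  low-variance estimate of each gene's true dispersion, which is
  exactly the assumption the z-score model makes. With a fully i.i.d.
  four-sample panel, a predictable few percent of genes draw a panel SD
  far below their cohort dispersion and acquire enormous spurious
  burden statistics; those heavy tails reflect a real fragility of
  tiny reference panels, but they are a property the screening model
  assumes away, so the generator does not produce them. The per-gene
  permutation matters: a pattern shared across genes would cancel
  through library-size normalization and collapse the estimated SDs.
- **Planted effects.** Each planted gene shifts its disjoint carrier
  group by Δ reference SDs in log2 space, mapping one-to-one onto
  z-scores. Carrier-linked amplification places GISTIC calls of 2 in
  ~30% of carriers; decoy genes (2% of the family by default) get
  amplification without any expression shift. Background calls are
  drawn from {−2, −1, 0, 1} only, so high-level amplification stays
  sparse and planted/decoy-specific.
- **Clinical and survival layers.** Stage, receptor status, morphology
  and intrinsic-subtype labels follow breast-carcinoma-like frequencies
  (stage ii majority, ~75% ER-positive, ~12% triple-negative), with
  optional enrichment of a label among a planted gene's carriers.
  Survival is exponential with a median of 130 months, an optional
  hazard ratio on one planted gene's carriers, and independent
  exponential censoring calibrated to a target censoring fraction.

What the generator does **not** emulate: empirical TCGA expression
distributions gene-by-gene, zero inflation, gene–gene correlation,
batch effects, read-level noise, or patient-matched
amplification-expression coupling beyond the carrier link. Passing the
recovery tests therefore shows the pipeline is correct under its own
model, not that real cohorts satisfy that model — in real data the
reference-panel fragility above is live, and the funnel's output should
be read with `screen_diagnostics()` alongside.

## Numerical choices and degenerate inputs

- Thresholds on a constant statistic equal that constant (warning), so
  strict `>` selection returns nothing — an all-null screen degrades to
  an empty result rather than an error; a z-matrix with no columns is an
  error.
- Reference SDs below 1e-8 mark a gene unscreenable; requesting such a
  gene explicitly is an error, and bulk screens simply drop them with a
  message.
- `weighted = n × sum` is an exact product of the already-computed
  values, never recomputed another way, so the identity is
  machine-exact.
- Prevalence bins are right-open with a closed last bin, so a
  prevalence exactly at an edge falls upward.
- All-identical case profiles cluster deterministically (with a
  warning) thanks to the lexicographic pre-sort.

## Validation problem sizes

The test suite validates the funnel against a brute-force oracle on 50
random instances (up to 20 genes × 30 samples), threshold calibration
on 200 simulated families of 400 genes, planted recovery and
sub-population recovery on 20 replicates of the 960-tumor cohort,
log-rank size and power on 200 replicates of n = 200 with ~20%
censoring at hazard ratios 1 and 4, and ANOVA against a sum-of-squares
oracle at 1e-9 relative tolerance. The same quantities are recomputed
from scratch by `scripts/acceptance.R`.

## Known limitations

- The threshold rule assumes the cross-gene statistic distribution is
  roughly normal; with heavy-tailed real data the effective alpha can
  be well below nominal.
- The gene-level amplification intersection cannot distinguish a gene
  amplified in the same patients that upregulate it from one amplified
  elsewhere.
- With a four-sample reference panel, per-gene SD estimates are noisy;
  results for genes flagged near the screenability floor deserve
  caution.
- The two-part funnel reuses the weighted statistic in both parts, so
  parts 1 and 2 are strongly dependent; their intersection is not an
  independent confirmation.
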