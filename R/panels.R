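#' @title Clinical panel-gene comparisons across sub-populations
#' @name panels
NULL

#' Canonical clinical panel gene lists
#'
#' `oncotypedx_genes`: the 21-gene recurrence panel (16 cancer-related plus
#' 5 reference genes). `pam50_genes`: the 50-gene intrinsic-subtype panel.
#' Used as default panel definitions; any user-supplied list can override
#' them.
#'
#' @format Character vectors of HGNC symbols.
#' @export
oncotypedx_genes <- c(
  "MKI67", "AURKA", "BIRC5", "CCNB1", "MYBL2",        # proliferation
  "ESR1", "PGR", "BCL2", "SCUBE2",                    # estrogen
  "ERBB2", "GRB7",                                    # HER2
  "MMP11", "CTSV",                                    # invasion
  "GSTM1", "CD68", "BAG1",
  "ACTB", "GAPDH", "RPLP0", "GUSB", "TFRC")           # reference

#' @rdname oncotypedx_genes
#' @export
pam50_genes <- c(
  "ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
  "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2",
  "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C",
  "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67",
  "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6",
  "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B", "TYMS",
  "UBE2C", "UBE2T")

#' Compare panel-gene abundance across sub-populations
#'
#' One-way ANOVA per panel gene across the patient sub-populations, on
#' z-scores by default (comparable across genes) or on any supplied
#' expression matrix. A gene whose test would involve a sub-population
#' with fewer than 2 usable samples is skipped with a warning. No
#' multiplicity correction is applied by default; `adjust = "BH"` turns
#' on Benjamini-Hochberg.
#'
#' @param x numeric matrix genes x cases (z-scores or expression).
#' @param subpops a `subpopulations` object or its assignment data frame.
#' @param panel `"oncotypedx"` or `"pam50"`; selects genes by the
#'   packaged symbol lists intersected with `rownames(x)`.
#' @param genes explicit gene ids overriding `panel`.
#' @param annotation optional [gene_annotation()]; when given and `genes`
#'   is NULL, panel membership comes from its `family` tags instead of
#'   the packaged lists.
#' @param alpha significance level for the flag.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame of class `panel_comparison`: one row per tested
#'   gene with per-sub-population means, `F`, `p`, `p_adj`,
#'   `significant`.
#' @export
panel_compare <- function(x, subpops, panel = c("oncotypedx", "pam50"),
                          genes = NULL, annotation = NULL, alpha = 0.05,
                          adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  asg <- if (inherits(subpops, "subpopulations")) subpops$assignment
         else subpops
  if (length(unique(asg$subpop)) < 2L)
    stop("need at least 2 sub-populations", call. = FALSE)
  if (is.null(genes)) {
    panel <- match.arg(panel)
    genes <- if (!is.null(annotation))
      annotation$gene_id[!is.na(annotation$family) &
                         annotation$family == panel]
    else if (panel == "oncotypedx") oncotypedx_genes else pam50_genes
  }
  genes <- intersect(genes, rownames(x))
  if (!length(genes)) stop("no panel genes present in the matrix",
                           call. = FALSE)
  cases <- intersect(asg$sample_id, colnames(x))
  grp <- asg$subpop[match(cases, asg$sample_id)]
  levels_ <- sort(unique(grp))
  rows <- lapply(genes, function(g) {
    v <- x[g, cases]
    ok <- is.finite(v)
    sizes <- table(factor(grp[ok], levels = levels_))
    if (any(sizes < 2L)) {
      warning("gene ", g, " skipped: sub-population(s) with < 2 samples",
              call. = FALSE)
      return(NULL)
    }
    av <- oneway_anova(v[ok], grp[ok])
    means <- tapply(v[ok], factor(grp[ok], levels = levels_), mean)
    out <- data.frame(gene_id = g, t(means), F = av$F, p = av$p,
                      stringsAsFactors = FALSE)
    colnames(out)[2:(1 + length(levels_))] <- paste0("mean_", levels_)
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("every panel gene was skipped", call. = FALSE)
  res$p_adj <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$significant <- res$p_adj <= alpha
  rownames(res) <- NULL
  class(res) <- c("panel_comparison", "data.frame")
  res
}

#' Receptor-phenotype composition of groups
#'
#' Mutually exclusive phenotype per sample: `TNBC` (triple-negative),
#' else `HER2` (HER2-positive), else `ER` (ER-positive), else `other`;
#' samples with no usable labels are `NA`. Percentages within each group
#' sum to 100.
#'
#' @param groups a `subpopulations` object, a `gene_groups`-style
#'   assignment, or any data frame with `sample_id` and a grouping
#'   column (second column used).
#' @param clinical a [clinical_table()].
#' @return List with `counts` and `percent` matrices (groups x
#'   phenotype).
#' @export
phenotype_composition <- function(groups, clinical) {
  asg <- if (inherits(groups, "subpopulations")) groups$assignment
         else groups
  grp <- asg[[setdiff(colnames(asg), "sample_id")[1L]]]
  idx <- match(asg$sample_id, clinical$sample_id)
  cl <- clinical[idx, , drop = FALSE]
  pheno <- ifelse(!is.na(cl$tnbc) & cl$tnbc, "TNBC",
           ifelse(!is.na(cl$her2_status) & cl$her2_status == "pos", "HER2",
           ifelse(!is.na(cl$er_status) & cl$er_status == "pos", "ER",
           ifelse(is.na(cl$tnbc) & is.na(cl$her2_status) &
                  is.na(cl$er_status), NA, "other"))))
  counts <- table(group = grp,
                  factor(pheno, levels = c("TNBC", "HER2", "ER", "other")),
                  useNA = "always")
  counts <- unclass(counts)
  counts <- counts[!is.na(rownames(counts)), , drop = FALSE]
  colnames(counts)[is.na(colnames(counts))] <- "NA"
  list(counts = counts, percent = 100 * counts / rowSums(counts))
}
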