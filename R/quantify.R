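#' @title Expression quantification: FPKM and log2 transform
#' @name quantify
NULL

#' Construct an expression matrix with a processing-stage tag
#'
#' @param values numeric genes x samples matrix.
#' @param stage one of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @param sample_role optional named role vector (tumor/reference).
#' @param pseudocount pseudocount recorded when `stage = "log2fpkm"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, stage = c("counts", "fpkm", "log2fpkm"),
                              sample_role = NULL, pseudocount = NULL) {
  stage <- match.arg(stage)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  if (stage == "fpkm" && any(values < 0, na.rm = TRUE))
    stop("FPKM values must be >= 0", call. = FALSE)
  if (stage == "log2fpkm" && !is.null(pseudocount) && pseudocount > 0 &&
      any(!is.finite(values)))
    stop("log2 FPKM must be finite when pseudocount > 0", call. = FALSE)
  if (!is.null(sample_role)) sample_role <- sample_role[colnames(values)]
  structure(list(values = values, stage = stage, sample_role = sample_role,
                 pseudocount = pseudocount),
            class = "expression_matrix")
}

#' Convert raw counts to FPKM
#'
#' FPKM(g, s) = count(g, s) * 1e9 / (length_bp(g) * total(s)), with the
#' per-sample total mapped reads taken as the column sum of the supplied
#' count matrix unless overridden. Genes without annotation (hence without
#' a transcript length) are dropped with a warning; a sample with zero
#' total yields an all-zero column with a warning.
#'
#' @param counts a [count_matrix()].
#' @param annotation a [gene_annotation()] providing `length_bp`.
#' @param totals optional named numeric vector of per-sample total mapped
#'   reads overriding the column sums.
#' @return An `expression_matrix` at stage `"fpkm"`, carrying attribute
#'   `dropped_genes`.
#' @export
compute_fpkm <- function(counts, annotation, totals = NULL) {
  if (!inherits(counts, "count_matrix")) stop("counts must be a count_matrix",
                                              call. = FALSE)
  if (nrow(counts$values) == 0L || ncol(counts$values) == 0L)
    stop("empty count matrix", call. = FALSE)
  if (is.null(totals)) {
    totals <- colSums(counts$values)
  } else {
    miss <- setdiff(colnames(counts$values), names(totals))
    if (length(miss)) stop("totals missing for sample(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    totals <- totals[colnames(counts$values)]
  }
  aligned <- align_gene_space(counts, annotation)
  lens <- annotation$length_bp[match(rownames(aligned$values),
                                     annotation$gene_id)]
  zero_tot <- totals == 0
  if (any(zero_tot)) {
    warning("sample(s) with zero total mapped reads set to all-zero FPKM: ",
            paste(colnames(aligned$values)[zero_tot], collapse = ", "),
            call. = FALSE)
    totals[zero_tot] <- 1 # numerator is zero for these columns anyway
  }
  fpkm <- sweep(aligned$values * 1e9 / lens, 2L, totals, "/")
  out <- expression_matrix(fpkm, "fpkm", sample_role = aligned$sample_role)
  attr(out, "dropped_genes") <- attr(aligned, "dropped_genes")
  out
}

#' Log2-transform an FPKM matrix
#'
#' Computes `log2(FPKM + pseudocount)`. The transform is monotone in FPKM;
#' with the default pseudocount of 1 a zero FPKM maps to exactly 0.
#'
#' @param expr an `expression_matrix` at stage `"fpkm"`.
#' @param pseudocount non-negative offset; 0 is rejected whenever the
#'   matrix contains zero FPKM values (log2 of 0 is -Inf).
#' @return An `expression_matrix` at stage `"log2fpkm"`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  if (!inherits(expr, "expression_matrix") || expr$stage != "fpkm")
    stop("expr must be an expression_matrix at stage 'fpkm'", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (pseudocount == 0 && any(expr$values == 0))
    stop("zero FPKM present: use a positive pseudocount (e.g. 1) to keep ",
         "log2 values finite", call. = FALSE)
  expression_matrix(log2(expr$values + pseudocount), "log2fpkm",
                    sample_role = expr$sample_role, pseudocount = pseudocount)
}
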