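#' @title The over-expression screen
#' @description Per-gene burden statistics against a normal reference
#'   panel, two-part upper-tail threshold selection, amplification
#'   intersection, downregulation mirror, mutation overlap and prevalence
#'   summary.
#' @name screen
NULL

#' Per-gene reference statistics
#'
#' Mean and sample standard deviation (n - 1 denominator) of log2 FPKM
#' over the normal reference samples. Genes whose reference SD falls below
#' `sd_floor` cannot be z-scored and are flagged unscreenable.
#'
#' @param expr an `expression_matrix` at stage `"log2fpkm"`.
#' @param reference_ids sample ids of the reference panel; defaults to the
#'   samples tagged `"reference"` in `expr$sample_role`.
#' @param sd_floor minimum reference SD for a gene to be screenable.
#' @return Data frame with columns `gene_id`, `mean_ref`, `sd_ref`,
#'   `n_ref`, `screenable`.
#' @export
reference_stats <- function(expr, reference_ids = NULL, sd_floor = 1e-8) {
  if (!inherits(expr, "expression_matrix") || expr$stage != "log2fpkm")
    stop("expr must be an expression_matrix at stage 'log2fpkm'", call. = FALSE)
  if (is.null(reference_ids)) {
    if (is.null(expr$sample_role))
      stop("no reference_ids given and expr carries no sample roles",
           call. = FALSE)
    reference_ids <- names(expr$sample_role)[expr$sample_role == "reference"]
  }
  miss <- setdiff(reference_ids, colnames(expr$values))
  if (length(miss)) stop("reference sample(s) not in matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (length(reference_ids) < 2L)
    stop("need at least 2 reference samples to estimate a reference SD",
         call. = FALSE)
  ref <- expr$values[, reference_ids, drop = FALSE]
  out <- data.frame(gene_id = rownames(ref),
                    mean_ref = rowMeans(ref),
                    sd_ref = apply(ref, 1L, stats::sd),
                    n_ref = length(reference_ids),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$screenable <- out$sd_ref >= sd_floor
  if (any(!out$screenable))
    message(sum(!out$screenable), " gene(s) flagged unscreenable (reference ",
            "SD < ", format(sd_floor), ")")
  out
}

#' Z-scores of tumor samples against the reference panel
#'
#' Z_ij = (X_ij - mean_ref_i) / sd_ref_i, where X_ij is the log2 FPKM of
#' gene i in tumor j. Only screenable genes are returned; requesting an
#' unscreenable gene explicitly is an error.
#'
#' @param expr an `expression_matrix` at stage `"log2fpkm"`.
#' @param ref output of [reference_stats()].
#' @param genes optional gene ids to score (default: all screenable).
#' @param tumor_ids tumor sample ids; defaults to samples tagged
#'   `"tumor"`, else all non-reference columns.
#' @return Numeric matrix, genes x tumor samples.
#' @export
zscores <- function(expr, ref, genes = NULL, tumor_ids = NULL) {
  if (is.null(genes)) {
    genes <- ref$gene_id[ref$screenable]
  } else {
    miss <- setdiff(genes, ref$gene_id)
    if (length(miss)) stop("gene(s) without reference stats: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    bad <- genes[!ref$screenable[match(genes, ref$gene_id)]]
    if (length(bad)) stop("unscreenable gene(s) (zero reference SD): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(tumor_ids)) {
    tumor_ids <- if (!is.null(expr$sample_role))
      names(expr$sample_role)[expr$sample_role == "tumor"]
    else colnames(expr$values)
  }
  idx <- match(genes, ref$gene_id)
  x <- expr$values[genes, tumor_ids, drop = FALSE]
  (x - ref$mean_ref[idx]) / ref$sd_ref[idx]
}

#' Per-gene burden statistics over the tumor cohort
#'
#' Over the m-patient cohort (tumors with at least one screened gene at
#' Z >= `z_cut`), computes for each gene i: the sum of upregulation
#' (sum of Z_ij over the cohort), the upregulated-case count n_i
#' (indicator Z_ij >= z_cut, boundary inclusive), the weighted
#' upregulation n_i x sum_i, and the prevalence n_i / population size.
#'
#' @param z z-score matrix from [zscores()].
#' @param z_cut upregulation cut-off in reference-SD units (default 2).
#' @param sum_mode what enters the sum of upregulation: `"all"` (every
#'   z-score of the cohort, the default literal reading), `"positive"`
#'   (positive z-scores only), `"above_cut"` (z-scores >= z_cut only).
#' @param population_size denominator of prevalence; defaults to the
#'   number of tumor columns.
#' @return Data frame with columns `gene_id`, `sum_upreg`, `n_upreg`,
#'   `weighted_upreg`, `prevalence`; attributes `m` (cohort size),
#'   `z_cut`, `sum_mode`, `population_size`.
#' @export
burden_stats <- function(z, z_cut = 2,
                         sum_mode = c("all", "positive", "above_cut"),
                         population_size = ncol(z)) {
  sum_mode <- match.arg(sum_mode)
  if (!is.matrix(z) || ncol(z) == 0L)
    stop("empty cohort: z must have at least one tumor column", call. = FALSE)
  if (any(!is.finite(z))) stop("z-scores must be finite", call. = FALSE)
  up <- z >= z_cut
  cohort <- colSums(up) > 0L
  m <- sum(cohort)
  zm <- z[, cohort, drop = FALSE]
  upm <- up[, cohort, drop = FALSE]
  n_upreg <- as.integer(rowSums(upm))
  sum_upreg <- switch(sum_mode,
    all       = rowSums(zm),
    positive  = rowSums(zm * (zm > 0)),
    above_cut = rowSums(zm * upm))
  if (m == 0L) sum_upreg <- rep(0, nrow(z)) # no upregulated case anywhere
  out <- data.frame(gene_id = rownames(z),
                    sum_upreg = sum_upreg,
                    n_upreg = n_upreg,
                    weighted_upreg = n_upreg * sum_upreg,
                    prevalence = n_upreg / population_size,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "m") <- m
  attr(out, "z_cut") <- z_cut
  attr(out, "sum_mode") <- sum_mode
  attr(out, "population_size") <- population_size
  out
}

#' Upper-tail significance thresholds for the burden statistics
#'
#' For each of the sum, count and weighted statistics, the threshold is
#' the one-sided upper (1 - alpha) normal point of the statistic's
#' cross-gene distribution: mean + z_(1-alpha) x SD (z_0.95 = 1.6449).
#' A degenerate (constant) statistic yields a threshold equal to that
#' constant, with a warning.
#'
#' @param stats output of [burden_stats()] over all screened family genes.
#' @param alpha upper-tail probability (default 0.05).
#' @param multiplier optional override of z_(1-alpha).
#' @return List of class `significance_thresholds` with elements
#'   `sum_threshold`, `count_threshold`, `weighted_threshold`, `alpha`,
#'   `multiplier`, `method`.
#' @export
significance_thresholds <- function(stats, alpha = 0.05, multiplier = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  ok <- is.finite(stats$sum_upreg) & is.finite(stats$weighted_upreg)
  if (sum(ok) < 3L)
    stop("need at least 3 genes with finite statistics", call. = FALSE)
  if (is.null(multiplier)) multiplier <- stats::qnorm(1 - alpha)
  one <- function(v, what) {
    s <- stats::sd(v)
    if (s == 0) {
      warning("degenerate (constant) ", what, " statistic: threshold equals ",
              "the common value", call. = FALSE)
      return(v[1L])
    }
    mean(v) + multiplier * s
  }
  structure(list(
    sum_threshold      = one(stats$sum_upreg[ok], "sum"),
    count_threshold    = one(stats$n_upreg[ok], "count"),
    weighted_threshold = one(stats$weighted_upreg[ok], "weighted"),
    alpha = alpha, multiplier = multiplier,
    method = "one-sided normal upper tail over family genes"),
    class = "significance_thresholds")
}

#' Two-part gene selection
#'
#' Part 1 keeps genes whose sum of upregulation and weighted upregulation
#' both strictly exceed their thresholds; part 2 keeps genes whose
#' upregulated-case count and weighted upregulation both exceed theirs;
#' the shared set is the intersection.
#'
#' @param stats output of [burden_stats()].
#' @param thr output of [significance_thresholds()].
#' @return List with character-vector elements `part1`, `part2`, `shared`.
#' @export
select_two_part <- function(stats, thr) {
  w <- stats$weighted_upreg > thr$weighted_threshold
  part1 <- stats$gene_id[stats$sum_upreg > thr$sum_threshold & w]
  part2 <- stats$gene_id[stats$n_upreg > thr$count_threshold & w]
  list(part1 = part1, part2 = part2, shared = intersect(part1, part2))
}

#' Genes with a high-level amplification call
#'
#' @param cna a [cna_matrix()].
#' @param level call value counted as high-level amplification (GISTIC 2).
#' @return Character vector of genes with `call == level` in at least one
#'   sample.
#' @export
high_amplification_genes <- function(cna, level = 2L) {
  rownames(cna)[apply(unclass(cna) == level, 1L, any)]
}

#' Final over-expressed set and per-case flags
#'
#' The over-expressed set is the intersection of the shared two-part
#' selection with the highly amplified genes. When a z-score matrix is
#' supplied, each tumor is flagged if it has Z >= `z_cut` in at least one
#' over-expressed gene.
#'
#' @param sel output of [select_two_part()] (or a list with `part1`,
#'   `part2`, `shared`).
#' @param amplified character vector from [high_amplification_genes()].
#' @param z optional z-score matrix for per-case flags.
#' @param z_cut upregulation cut-off used for the flags.
#' @param direction `"up"` or `"down"` tag carried on the result.
#' @return Object of class `screen_result`: list with `part1`, `part2`,
#'   `shared`, `amplified`, `overexpressed`, `case_flags` (named logical
#'   or NULL), `direction`.
#' @export
overexpressed_set <- function(sel, amplified, z = NULL, z_cut = 2,
                              direction = "up") {
  over <- intersect(sel$shared, amplified)
  flags <- NULL
  if (!is.null(z)) {
    flags <- if (length(over))
      apply(z[over, , drop = FALSE] >= z_cut, 2L, any)
    else stats::setNames(rep(FALSE, ncol(z)), colnames(z))
  }
  structure(list(part1 = sel$part1, part2 = sel$part2, shared = sel$shared,
                 amplified = amplified, overexpressed = over,
                 case_flags = flags, direction = direction),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Over-expression screen (direction:", x$direction, ")\n")
  cat("  part 1 (sum & weighted):   ", length(x$part1), "genes\n")
  cat("  part 2 (count & weighted): ", length(x$part2), "genes\n")
  cat("  shared:                    ", length(x$shared), "genes\n")
  cat("  highly amplified:          ", length(x$amplified), "genes\n")
  cat("  over-expressed:            ", length(x$overexpressed), "genes\n")
  if (!is.null(x$case_flags))
    cat("  flagged cases:             ", sum(x$case_flags), "of",
        length(x$case_flags), "\n")
  invisible(x)
}

#' Run the full screening funnel
#'
#' Orchestrates [reference_stats()], [zscores()], [burden_stats()],
#' [significance_thresholds()], [select_two_part()],
#' [high_amplification_genes()] and [overexpressed_set()] for one gene
#' family. With `direction = "down"` the whole machinery runs on -Z
#' (indicator Z <= -z_cut, sums of negated z-scores), so thresholds act
#' on downregulation magnitudes.
#'
#' @param expr an `expression_matrix` at stage `"log2fpkm"`.
#' @param cna optional [cna_matrix()]; without it the amplified set is
#'   taken as empty.
#' @param annotation optional [gene_annotation()] used to restrict the
#'   screen to `family` genes.
#' @param family family tag to screen (default `"OR"`); ignored when
#'   `annotation` is NULL, in which case all genes are screened.
#' @param reference_ids,z_cut,alpha,sum_mode,population_size see the
#'   component functions. `z_cut` is a magnitude (2 screens Z >= 2 going
#'   up, Z <= -2 going down).
#' @param direction `"up"` (default) or `"down"`.
#' @return A `screen_result` with additional elements `stats`,
#'   `thresholds`, `reference`, `z`.
#' @export
run_screen <- function(expr, cna = NULL, annotation = NULL, family = "OR",
                       reference_ids = NULL, z_cut = 2, alpha = 0.05,
                       sum_mode = "all", population_size = NULL,
                       direction = c("up", "down")) {
  direction <- match.arg(direction)
  ref <- reference_stats(expr, reference_ids)
  genes <- ref$gene_id[ref$screenable]
  if (!is.null(annotation))
    genes <- intersect(genes,
                       annotation$gene_id[!is.na(annotation$family) &
                                          annotation$family == family])
  if (!length(genes)) stop("no screenable family genes", call. = FALSE)
  z <- zscores(expr, ref, genes = genes)
  zeff <- if (direction == "down") -z else z
  if (is.null(population_size)) population_size <- ncol(z)
  stats <- burden_stats(zeff, z_cut = z_cut, sum_mode = sum_mode,
                        population_size = population_size)
  thr <- significance_thresholds(stats, alpha = alpha)
  sel <- select_two_part(stats, thr)
  amplified <- if (is.null(cna)) character(0)
    else intersect(high_amplification_genes(cna), genes)
  res <- overexpressed_set(sel, amplified, z = zeff, z_cut = z_cut,
                           direction = direction)
  res$stats <- stats
  res$thresholds <- thr
  res$reference <- ref
  res$z <- z
  res
}

#' Downregulation mirror screen
#'
#' Convenience wrapper: [run_screen()] with `direction = "down"`, so a
#' case counts as downregulated at Z <= -z_cut and the burden statistics
#' are magnitudes of negative z-scores.
#'
#' @inheritParams run_screen
#' @return A `screen_result` with `direction = "down"`.
#' @export
downregulation_screen <- function(expr, cna = NULL, annotation = NULL,
                                  family = "OR", reference_ids = NULL,
                                  z_cut = 2, alpha = 0.05, sum_mode = "all",
                                  population_size = NULL) {
  run_screen(expr, cna, annotation, family, reference_ids, z_cut, alpha,
             sum_mode, population_size, direction = "down")
}

#' Overlap of the over-expressed set with mutated genes
#'
#' @param result a `screen_result`.
#' @param mutations a [mutation_table()].
#' @return Character vector: over-expressed genes with at least one
#'   recorded mutation.
#' @export
mutation_overlap <- function(result, mutations) {
  mutated <- mutations$gene_id[mutations$n_mutations > 0]
  intersect(result$overexpressed, mutated)
}

#' Histogram of genes per prevalence bin
#'
#' Bins are right-open except the last: with edges (0.05, 0.10, 0.12) the
#' bins are [0, 0.05), [0.05, 0.10), [0.10, 0.12), [0.12, 1].
#'
#' @param stats output of [burden_stats()].
#' @param edges increasing prevalence bin edges in (0, 1).
#' @return Named integer vector of gene counts per bin.
#' @export
prevalence_summary <- function(stats, edges = c(0.05, 0.10, 0.12)) {
  stopifnot(all(diff(edges) > 0), all(edges > 0 & edges < 1))
  breaks <- c(0, edges, 1 + 1e-12)
  counts <- table(cut(stats$prevalence, breaks = breaks, right = FALSE,
                      include.lowest = TRUE))
  lab <- c(sprintf("[0,%g)", edges[1L]),
           if (length(edges) > 1L)
             sprintf("[%g,%g)", edges[-length(edges)], edges[-1L]),
           sprintf("[%g,1]", edges[length(edges)]))
  stats::setNames(as.integer(counts), lab)
}

#' Funnel sizes under every sum mode
#'
#' Near-miss diagnostic: re-runs the screen under each definition of the
#' sum of upregulation and reports every funnel set size plus the three
#' thresholds, so the sensitivity of the gene sets to the sum definition
#' is visible at a glance.
#'
#' @inheritParams run_screen
#' @return Data frame, one row per sum mode.
#' @export
screen_diagnostics <- function(expr, cna = NULL, annotation = NULL,
                               family = "OR", reference_ids = NULL,
                               z_cut = 2, alpha = 0.05,
                               population_size = NULL) {
  do.call(rbind, lapply(c("all", "positive", "above_cut"), function(mode) {
    r <- run_screen(expr, cna, annotation, family, reference_ids, z_cut,
                    alpha, sum_mode = mode,
                    population_size = population_size)
    data.frame(sum_mode = mode,
               n_part1 = length(r$part1), n_part2 = length(r$part2),
               n_shared = length(r$shared),
               n_amplified = length(r$amplified),
               n_overexpressed = length(r$overexpressed),
               sum_threshold = r$thresholds$sum_threshold,
               count_threshold = r$thresholds$count_threshold,
               weighted_threshold = r$thresholds$weighted_threshold,
               stringsAsFactors = FALSE)
  }))
}
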