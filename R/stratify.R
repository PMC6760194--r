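#' @title Gene-group and patient sub-population stratification
#' @name stratify
NULL

# One-way ANOVA with a zero-within-variance guard. Returns F and p.
# When every group mean is equal F = 0; when the within-group variance is
# exactly zero but means differ, F = Inf with p = 0.
oneway_anova <- function(values, groups) {
  keep <- stats::complete.cases(values, groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L)
    stop("one-way ANOVA needs at least 2 groups (no between-group variance ",
         "with a single group)", call. = FALSE)
  if (any(tabulate(groups) < 1L)) stop("empty group", call. = FALSE)
  n <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(tabulate(groups) * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (df2 < 1L) stop("need more observations than groups", call. = FALSE)
  msb <- ssb / df1
  mse <- ssw / df2
  if (mse <= .Machine$double.eps * max(1, msb)) {
    if (msb <= .Machine$double.eps) return(list(F = 0, p = 1, df1 = df1,
                                                df2 = df2))
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  f <- msb / mse
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

# Canonical hierarchical clustering: rows sorted lexicographically (the
# tie-break and the guarantee of permutation equivariance), Euclidean
# distance, Ward linkage.
ward_cluster <- function(x, k) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > nrow(x))
    stop("k (", k, ") exceeds the number of items (", nrow(x), ")",
         call. = FALSE)
  x <- x[order(rownames(x)), , drop = FALSE]
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  membership <- stats::cutree(hc, k = k)
  list(membership = membership, hclust = hc)
}

#' Cluster over-expressed genes into groups
#'
#' Agglomerative clustering of per-gene abundance vectors (Euclidean
#' distance, Ward linkage), cut at `k` groups. Deterministic for a given
#' gene set: rows are ordered lexicographically by gene id before
#' clustering, so input order is irrelevant.
#'
#' @param x numeric matrix, over-expressed genes x tumor samples (z-scores
#'   by default in the pipeline; log2 FPKM also works).
#' @param k number of gene groups (default 3).
#' @return List of class `gene_groups`: `assignment` (data frame gene_id,
#'   group "Group1"... ordered by id), `hclust` (the dendrogram), `k`.
#' @export
cluster_genes <- function(x, k = 3) {
  wc <- ward_cluster(x, k)
  structure(list(
    assignment = data.frame(gene_id = names(wc$membership),
                            group = paste0("Group", wc$membership),
                            stringsAsFactors = FALSE, row.names = NULL),
    hclust = wc$hclust, k = k), class = "gene_groups")
}

#' Cluster positive cases into sub-populations
#'
#' Clusters the tumors that carry at least one over-expressed gene at
#' Z >= z_cut ("positive cases"), using their z-score vectors over the
#' over-expressed genes. Two modes: `"tree"` (Ward/Euclidean tree cut at
#' `k`, as for genes) and `"argmax"` (each case labelled by the gene with
#' its maximal z-score, one sub-population per gene attaining a maximum).
#' Each sub-population's defining gene is the gene with the largest
#' within-cluster mean z minus out-of-cluster mean z contrast; a one-way
#' ANOVA F statistic of each defining gene across sub-populations is
#' reported.
#'
#' @param z z-score matrix restricted to the over-expressed genes; columns
#'   are the positive cases.
#' @param k number of sub-populations (default 3; ignored for `"argmax"`).
#' @param mode `"tree"` or `"argmax"`.
#' @return List of class `subpopulations`: `assignment` (data frame
#'   sample_id, subpop "I"/"II"/...), `defining_genes` (data frame
#'   subpop, gene_id, contrast, F, p), `k`, `mode`, and `hclust` for tree
#'   mode.
#' @export
cluster_cases <- function(z, k = 3, mode = c("tree", "argmax")) {
  mode <- match.arg(mode)
  if (ncol(z) < 1L) stop("no positive cases to cluster", call. = FALSE)
  x <- t(z)
  if (nrow(x) > 1L && max(stats::dist(x)) == 0)
    warning("all cases have identical profiles: split is arbitrary but ",
            "deterministic", call. = FALSE)
  hc <- NULL
  if (mode == "tree") {
    wc <- ward_cluster(x, k)
    membership <- wc$membership
    hc <- wc$hclust
  } else {
    ids <- sort(rownames(x))
    top <- apply(x[ids, , drop = FALSE], 1L, function(v)
      colnames(x)[which.max(v)])
    membership <- stats::setNames(match(top, sort(unique(top))), ids)
    k <- length(unique(top))
  }
  labels <- as.character(utils::as.roman(membership))
  assignment <- data.frame(sample_id = names(membership), subpop = labels,
                           stringsAsFactors = FALSE, row.names = NULL)
  defining <- do.call(rbind, lapply(sort(unique(membership)), function(g) {
    inside <- names(membership)[membership == g]
    outside <- setdiff(colnames(z), inside)
    contrast <- rowMeans(z[, inside, drop = FALSE]) -
      (if (length(outside)) rowMeans(z[, outside, drop = FALSE]) else 0)
    best <- sort(names(contrast)[contrast == max(contrast)])[1L]
    av <- if (k >= 2L)
      oneway_anova(z[best, assignment$sample_id],
                   assignment$subpop)
    else list(F = NA_real_, p = NA_real_)
    data.frame(subpop = as.character(utils::as.roman(g)), gene_id = best,
               contrast = max(contrast), F = av$F, p = av$p,
               stringsAsFactors = FALSE)
  }))
  if (k == 1L) # single sub-population: defining gene is the global max mean z
    defining$gene_id <- names(which.max(rowMeans(z)))[1L]
  structure(list(assignment = assignment, defining_genes = defining,
                 k = k, mode = mode, hclust = hc),
            class = "subpopulations")
}

#' Per-group burden summaries with one-way ANOVA
#'
#' For each of the upregulated-case count and the sum of upregulation,
#' reports group means over the gene groups and a one-way ANOVA across
#' groups.
#'
#' @param groups a `gene_groups` object (or its `assignment` data frame).
#' @param stats output of [burden_stats()].
#' @return List with `means` (data frame group, mean_n_upreg,
#'   mean_sum_upreg, n_genes) and `anova` (data frame statistic, F, p).
#' @export
group_summaries <- function(groups, stats) {
  asg <- if (inherits(groups, "gene_groups")) groups$assignment else groups
  merged <- merge(asg, stats, by = "gene_id")
  if (!nrow(merged)) stop("groups and stats share no genes", call. = FALSE)
  if (length(unique(merged$group)) < 2L)
    stop("one-way ANOVA needs at least 2 groups (no between-group variance ",
         "with a single group)", call. = FALSE)
  means <- do.call(rbind, lapply(split(merged, merged$group), function(d)
    data.frame(group = d$group[1L], n_genes = nrow(d),
               mean_n_upreg = mean(d$n_upreg),
               mean_sum_upreg = mean(d$sum_upreg),
               stringsAsFactors = FALSE)))
  rownames(means) <- NULL
  an <- rbind(
    data.frame(statistic = "n_upreg",
               as.data.frame(oneway_anova(merged$n_upreg, merged$group))),
    data.frame(statistic = "sum_upreg",
               as.data.frame(oneway_anova(merged$sum_upreg, merged$group))))
  list(means = means, anova = an)
}

#' Clinical composition of each sub-population
#'
#' Contingency tables (counts and within-sub-population percentages) of
#' stage, receptor status, morphology and intrinsic-subtype label per
#' sub-population. The NA category is retained.
#'
#' @param subpops a `subpopulations` object (or its assignment data
#'   frame).
#' @param clinical a [clinical_table()].
#' @param variables clinical columns to tabulate.
#' @return Named list, one element per variable, each a list with
#'   `counts` and `percent` matrices (sub-populations x categories).
#' @export
composition_tables <- function(subpops, clinical,
                               variables = c("stage", "er_status",
                                             "her2_status", "tnbc",
                                             "morphology", "subtype_label")) {
  asg <- if (inherits(subpops, "subpopulations")) subpops$assignment
         else subpops
  idx <- match(asg$sample_id, clinical$sample_id)
  if (anyNA(idx))
    stop("clinical rows missing for assigned sample(s): ",
         paste(asg$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
  cl <- clinical[idx, , drop = FALSE]
  out <- lapply(variables, function(v) {
    counts <- table(subpop = asg$subpop, addNA(factor(cl[[v]])),
                    useNA = "no")
    counts <- unclass(counts)
    colnames(counts)[is.na(colnames(counts))] <- "NA"
    percent <- 100 * counts / rowSums(counts)
    list(counts = counts, percent = percent)
  })
  stats::setNames(out, variables)
}

#' Heatmap-ready matrix ordered by dendrogram and sub-population
#'
#' @param x numeric matrix genes x cases.
#' @param genes a `gene_groups` object giving the gene (row) order; NULL
#'   keeps lexicographic order.
#' @param subpops a `subpopulations` object giving the case (column)
#'   order (grouped by sub-population); NULL keeps lexicographic order.
#' @return The reordered matrix.
#' @export
ordered_matrix <- function(x, genes = NULL, subpops = NULL) {
  ridx <- if (!is.null(genes))
    genes$hclust$labels[genes$hclust$order] else sort(rownames(x))
  cidx <- if (!is.null(subpops)) {
    asg <- subpops$assignment
    asg$sample_id[order(asg$subpop, asg$sample_id)]
  } else sort(colnames(x))
  x[intersect(ridx, rownames(x)), intersect(cidx, colnames(x)), drop = FALSE]
}
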