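#' @title Synthetic cohort generator with recorded ground truth
#' @description Generates tumor cohorts with the statistical structure the
#'   screen assumes: a gene family among a larger background, a small
#'   normal reference panel, a minority of patients carrying large
#'   planted expression shifts in a few family genes, sparse high-level
#'   amplification calls, clinical labels and exponential survival with
#'   censoring. Every planted feature is recorded in a truth object for
#'   parameter-recovery testing.
#' @name synthetic_data
NULL

#' Synthetic cohort configuration
#'
#' Defaults emulate the structure of a large breast-carcinoma cohort: 960
#' tumors, a 4-sample normal reference panel, 408 screened family genes
#' among 2000 background genes (plus the clinical panel genes). Planted
#' effects are expressed in log2 space in units of the gene's reference
#' SD, so they map one-to-one onto the screen's z-scores.
#'
#' @param n_tumors,n_reference,n_family_genes,n_background_genes cohort
#'   dimensions.
#' @param planted_genes data frame (or list of lists) with columns
#'   `gene` (index into the family genes), `delta` (effect in
#'   reference-SD units, >= 0) and `carrier_fraction` (in (0, 1]).
#'   Carriers of distinct planted genes are disjoint.
#' @param decoy_amplified_fraction fraction of non-planted family genes
#'   receiving a high-level amplification call with no expression shift.
#' @param amplified_carrier_link when TRUE, planted genes get CNA = 2 in
#'   a subset of their carriers.
#' @param mutation_spec data frame `gene_id`, `n_mutations`; NULL gives a
#'   default 15-gene table with counts 6-8 among non-planted family
#'   genes.
#' @param baseline_log2fpkm_mean_range,baseline_log2fpkm_sd_range per-gene
#'   baseline ranges for the log2(FPKM + 1) mean and SD of background and
#'   panel genes, which carry the bulk of the library.
#' @param family_log2fpkm_mean_range,family_log2fpkm_sd_range baseline
#'   ranges for the screened family genes: low to moderate, emulating
#'   ectopic expression of a normally near-silent family, and keeping
#'   planted carriers from dominating a sample's library size.
#' @param ref_jitter reference-panel jitter as a fraction of the gene SD.
#'   Reference columns are stratified normal scores (rescaled expected
#'   order statistics) plus this jitter, so the panel SD is a
#'   representative, low-variance estimate of the gene's dispersion.
#' @param length_bp_range,depth_range transcript length (bp) and
#'   per-sample sequencing depth ranges; both are drawn uniformly so the
#'   FPKM conversion is non-trivially exercised.
#' @param hazard_gene index of the planted gene whose carriers have an
#'   elevated hazard; NULL for none.
#' @param hazard_ratio hazard ratio applied to hazard-gene carriers.
#' @param baseline_median_months median overall survival of
#'   non-carriers.
#' @param censoring_fraction expected fraction of censored cases.
#' @param subtype_link list of `list(gene = index, label = "Basal",
#'   prob = 0.6)` entries enriching a clinical label among carriers.
#' @param include_panel_genes add the Oncotype DX / PAM50 symbols (tagged
#'   by family) to the gene space.
#' @param no_survival emit NA survival columns (cell-line style bundle).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumors = 960, n_reference = 4,
                          n_family_genes = 408, n_background_genes = 2000,
                          planted_genes = NULL,
                          decoy_amplified_fraction = 0.02,
                          amplified_carrier_link = TRUE,
                          mutation_spec = NULL,
                          baseline_log2fpkm_mean_range = c(4, 9),
                          baseline_log2fpkm_sd_range = c(0.5, 1.5),
                          family_log2fpkm_mean_range = c(4, 6),
                          family_log2fpkm_sd_range = c(0.5, 1),
                          ref_jitter = 0.25,
                          length_bp_range = c(500, 4000),
                          depth_range = c(1e6, 3e7),
                          hazard_gene = NULL, hazard_ratio = 1,
                          baseline_median_months = 130,
                          censoring_fraction = 0.2,
                          subtype_link = NULL,
                          include_panel_genes = TRUE,
                          no_survival = FALSE) {
  planted <- if (is.null(planted_genes)) {
    data.frame(gene = integer(0), delta = numeric(0),
               carrier_fraction = numeric(0))
  } else if (is.data.frame(planted_genes)) {
    planted_genes
  } else {
    do.call(rbind, lapply(planted_genes, as.data.frame))
  }
  if (nrow(planted)) {
    if (any(planted$gene < 1 | planted$gene > n_family_genes))
      stop("planted gene index out of range 1..", n_family_genes,
           call. = FALSE)
    if (any(planted$delta < 0)) stop("planted delta must be >= 0",
                                     call. = FALSE)
    if (any(planted$carrier_fraction <= 0 | planted$carrier_fraction > 1))
      stop("carrier_fraction must be in (0, 1]", call. = FALSE)
    if (sum(planted$carrier_fraction) > 1)
      stop("carrier fractions sum above 1: carriers must be disjoint",
           call. = FALSE)
  }
  if (!is.null(hazard_gene) && !(hazard_gene %in% planted$gene))
    stop("hazard_gene must be a planted gene index", call. = FALSE)
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0, 1)", call. = FALSE)
  structure(list(
    n_tumors = n_tumors, n_reference = n_reference,
    n_family_genes = n_family_genes,
    n_background_genes = n_background_genes,
    planted_genes = planted,
    decoy_amplified_fraction = decoy_amplified_fraction,
    amplified_carrier_link = amplified_carrier_link,
    mutation_spec = mutation_spec,
    baseline_log2fpkm_mean_range = baseline_log2fpkm_mean_range,
    baseline_log2fpkm_sd_range = baseline_log2fpkm_sd_range,
    family_log2fpkm_mean_range = family_log2fpkm_mean_range,
    family_log2fpkm_sd_range = family_log2fpkm_sd_range,
    ref_jitter = ref_jitter,
    length_bp_range = length_bp_range, depth_range = depth_range,
    hazard_gene = hazard_gene, hazard_ratio = hazard_ratio,
    baseline_median_months = baseline_median_months,
    censoring_fraction = censoring_fraction,
    subtype_link = subtype_link,
    include_panel_genes = include_panel_genes,
    no_survival = no_survival), class = "cohort_config")
}

# Blom approximation to expected normal order statistics, rescaled to
# unit sample SD: the stratified reference pattern.
ref_pattern <- function(n) {
  p <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  p / stats::sd(p)
}

sample_enum <- function(n, levels, probs) {
  sample(levels, n, replace = TRUE, prob = probs)
}

#' Generate a synthetic cohort bundle
#'
#' Single pseudo-random stream, drawn in a fixed order (genes, reference,
#' tumors, sequencing, copy number, clinical, survival), so the full
#' bundle is reproducible byte-for-byte from `(config, seed)`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed fixing the full output.
#' @return A list of class `synthetic_cohort` with elements `counts`
#'   ([count_matrix()]), `cna` ([cna_matrix()]), `clinical`
#'   ([clinical_table()]), `mutations` ([mutation_table()]), `annotation`
#'   ([gene_annotation()]), `truth` (planted gene ids, carrier ids per
#'   gene, the true over-expressed set under the generator's own
#'   definitions, hazard carriers) and `config`.
#' @export
generate_cohort <- function(config, seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  nt <- config$n_tumors; nr <- config$n_reference
  nf <- config$n_family_genes

  # --- gene space ----------------------------------------------------
  family_ids <- sprintf("ORsim%04d", seq_len(nf))
  panel_ids <- character(0); panel_family <- character(0)
  if (config$include_panel_genes) {
    panel_ids <- union(oncotypedx_genes, pam50_genes)
    panel_family <- ifelse(panel_ids %in% oncotypedx_genes, "oncotypedx",
                           "pam50")
  }
  bg_ids <- sprintf("BG%05d", seq_len(config$n_background_genes))
  gene_ids <- c(family_ids, panel_ids, bg_ids)
  G <- length(gene_ids)
  annotation <- gene_annotation(data.frame(
    gene_id = gene_ids, symbol = gene_ids,
    length_bp = round(stats::runif(G, config$length_bp_range[1L],
                                   config$length_bp_range[2L])),
    family = c(rep("OR", nf), panel_family,
               rep("other", config$n_background_genes)),
    stringsAsFactors = FALSE))

  mu <- stats::runif(G, config$baseline_log2fpkm_mean_range[1L],
                     config$baseline_log2fpkm_mean_range[2L])
  sigma <- stats::runif(G, config$baseline_log2fpkm_sd_range[1L],
                        config$baseline_log2fpkm_sd_range[2L])
  fam <- seq_len(nf)
  mu[fam] <- stats::runif(nf, config$family_log2fpkm_mean_range[1L],
                          config$family_log2fpkm_mean_range[2L])
  sigma[fam] <- stats::runif(nf, config$family_log2fpkm_sd_range[1L],
                             config$family_log2fpkm_sd_range[2L])

  tumor_ids <- sprintf("TUMOR%04d", seq_len(nt))
  ref_ids <- sprintf("NORM%02d", seq_len(nr))

  # --- reference panel: stratified scores + jitter -------------------
  # the pattern is permuted independently per gene so no reference
  # column is systematically high or low across genes (a shared pattern
  # would cancel through library-size normalization and deflate the
  # estimated reference SDs)
  pat <- ref_pattern(nr)
  pat_mat <- t(vapply(seq_len(G), function(i) pat[sample.int(nr)],
                      numeric(nr)))
  y_ref <- mu + sigma * pat_mat +
    (sigma * config$ref_jitter) * matrix(stats::rnorm(G * nr), G, nr)

  # --- tumors and planted carriers -----------------------------------
  y_tum <- mu + sigma * matrix(stats::rnorm(G * nt), G, nt)
  planted <- config$planted_genes
  carriers <- list()
  if (nrow(planted)) {
    perm <- sample(nt)
    offset <- 0L
    for (i in seq_len(nrow(planted))) {
      nc <- max(1L, round(planted$carrier_fraction[i] * nt))
      idx <- perm[(offset + 1L):(offset + nc)]
      offset <- offset + nc
      g <- planted$gene[i]
      y_tum[g, idx] <- y_tum[g, idx] + planted$delta[i] * sigma[g]
      carriers[[family_ids[g]]] <- sort(tumor_ids[idx])
    }
  }

  # --- counts through the FPKM inverse -------------------------------
  y <- cbind(y_tum, y_ref)
  colnames(y) <- c(tumor_ids, ref_ids)
  rownames(y) <- gene_ids
  depth <- round(stats::runif(nt + nr, config$depth_range[1L],
                              config$depth_range[2L]))
  fpkm <- pmax(2^y - 1, 0)
  counts_mat <- round(sweep(fpkm * annotation$length_bp / 1e9, 2L, depth,
                            "*"))
  roles <- stats::setNames(rep(c("tumor", "reference"), c(nt, nr)),
                           c(tumor_ids, ref_ids))
  counts <- count_matrix(counts_mat, roles)

  # --- copy-number calls ---------------------------------------------
  cna_mat <- matrix(sample(c(-2L, -1L, 0L, 1L), G * nt, replace = TRUE,
                           prob = c(0.01, 0.09, 0.71, 0.19)),
                    G, nt, dimnames = list(gene_ids, tumor_ids))
  amplified_true <- character(0)
  if (nrow(planted) && config$amplified_carrier_link) {
    for (i in seq_len(nrow(planted))) {
      gid <- family_ids[planted$gene[i]]
      carr <- carriers[[gid]]
      pick <- sort(sample(carr, max(1L, round(0.3 * length(carr)))))
      cna_mat[gid, pick] <- 2L
      amplified_true <- c(amplified_true, gid)
    }
  }
  n_decoy <- round(config$decoy_amplified_fraction * nf)
  decoys <- character(0)
  if (n_decoy > 0L) {
    pool <- setdiff(family_ids, family_ids[planted$gene])
    decoys <- sort(sample(pool, n_decoy))
    for (gid in decoys)
      cna_mat[gid, sample(nt, sample(1:3, 1L))] <- 2L
  }
  cna <- cna_matrix(cna_mat)

  # --- mutation table -------------------------------------------------
  mut <- config$mutation_spec
  if (is.null(mut)) {
    pool <- setdiff(family_ids, family_ids[planted$gene])
    picks <- utils::tail(pool, 15L)
    mut <- data.frame(gene_id = picks,
                      n_mutations = c(8L, 8L, 7L, 7L, rep(6L, 11L)),
                      stringsAsFactors = FALSE)
  }
  mutations <- mutation_table(mut)

  # --- clinical labels ------------------------------------------------
  subtype <- sample_enum(nt, c("LumA", "LumB", "Her2", "Basal", "Normal",
                               NA),
                         c(0.44, 0.20, 0.10, 0.15, 0.05, 0.06))
  if (!is.null(config$subtype_link)) {
    for (lk in config$subtype_link) {
      gid <- family_ids[lk$gene]
      carr <- carriers[[gid]]
      if (is.null(carr)) next
      hit <- stats::runif(length(carr)) < lk$prob
      subtype[match(carr[hit], tumor_ids)] <- lk$label
    }
  }
  er_p <- ifelse(is.na(subtype), 0.70,
          ifelse(subtype %in% c("LumA", "LumB"), 0.95,
          ifelse(subtype == "Her2", 0.40,
          ifelse(subtype == "Basal", 0.10, 0.70))))
  her2_p <- ifelse(is.na(subtype), 0.15,
            ifelse(subtype == "Her2", 0.95,
            ifelse(subtype == "LumB", 0.25, 0.10)))
  draw_status <- function(p) {
    s <- ifelse(stats::runif(nt) < p, "pos", "neg")
    s[stats::runif(nt) < 0.02] <- NA
    s
  }
  er <- draw_status(er_p)
  her2 <- draw_status(her2_p)
  tnbc <- ifelse(is.na(er) | is.na(her2), NA, er == "neg" & her2 == "neg")
  stage <- sample_enum(nt, c("i", "ii", "iii", "iv", NA),
                       c(0.12, 0.55, 0.25, 0.04, 0.04))
  morph <- sample_enum(nt, c("IDC", "ILC", "mixed", "other", NA),
                       c(0.72, 0.15, 0.06, 0.04, 0.03))

  # --- survival --------------------------------------------------------
  if (config$no_survival) {
    months <- rep(NA_real_, nt)
    event <- rep(NA, nt)
    hz_carr <- character(0)
  } else {
    lambda <- rep(log(2) / config$baseline_median_months, nt)
    hz_carr <- character(0)
    if (!is.null(config$hazard_gene)) {
      hz_carr <- carriers[[family_ids[config$hazard_gene]]]
      lambda[match(hz_carr, tumor_ids)] <-
        lambda[match(hz_carr, tumor_ids)] * config$hazard_ratio
    }
    t_event <- stats::rexp(nt, lambda)
    f <- config$censoring_fraction
    t_cens <- if (f > 0) stats::rexp(nt, lambda * f / (1 - f))
              else rep(Inf, nt)
    months <- round(pmin(t_event, t_cens), 2)
    event <- t_event <= t_cens
  }
  clinical <- clinical_table(data.frame(
    sample_id = tumor_ids, stage = stage, er_status = er,
    her2_status = her2, tnbc = tnbc, morphology = morph,
    subtype_label = subtype, survival_months = months, event = event,
    stringsAsFactors = FALSE))

  truth <- list(
    planted = data.frame(gene_id = family_ids[planted$gene],
                         delta = planted$delta,
                         carrier_fraction = planted$carrier_fraction,
                         stringsAsFactors = FALSE),
    carriers = carriers,
    true_overexpressed = family_ids[planted$gene][planted$delta > 0 &
      family_ids[planted$gene] %in% amplified_true],
    decoy_amplified = decoys,
    hazard_gene = if (is.null(config$hazard_gene)) NA_character_
                  else family_ids[config$hazard_gene],
    hazard_carriers = hz_carr,
    seed = seed)

  structure(list(counts = counts, cna = cna, clinical = clinical,
                 mutations = mutations, annotation = annotation,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Write a cohort bundle as canonical TSV files
#'
#' @param bundle a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_count_matrix(bundle$counts, file.path(dir, "counts.tsv"))
  write_cna_matrix(bundle$cna, file.path(dir, "cna.tsv"))
  write_table_tsv(bundle$clinical, file.path(dir, "clinical.tsv"))
  write_table_tsv(bundle$mutations, file.path(dir, "mutations.tsv"))
  write_table_tsv(bundle$annotation, file.path(dir, "annotation.tsv"))
  write_table_tsv(data.frame(sample_id = names(bundle$counts$sample_role),
                             role = unname(bundle$counts$sample_role)),
                  file.path(dir, "roles.tsv"))
  invisible(dir)
}

#' Canonical named fixtures
#'
#' Four bundles exercising the main downstream behaviors:
#' \describe{
#'   \item{null}{no planted effects and no high-level amplification
#'     calls: the clean negative control, whose over-expressed set is
#'     empty by construction.}
#'   \item{three_subpop}{three planted genes (delta 6, disjoint 20%
#'     carrier groups) with carrier-linked amplification and amplified
#'     decoys; the third gene's carriers are enriched for the Basal
#'     label.}
#'   \item{hazard}{one planted gene whose carriers have hazard ratio 3
#'     with ~20% censoring.}
#'   \item{cellline}{a 54-sample bundle without survival data, with a
#'     TNBC-enriched planted gene.}
#' }
#'
#' @param out_dir optional directory; when given, each bundle is written
#'   as TSVs under `out_dir/<name>/`.
#' @param seed base seed; fixture k uses `seed + k`.
#' @return Named list of `synthetic_cohort` bundles.
#' @export
make_fixture_suite <- function(out_dir = NULL, seed = 1) {
  three <- data.frame(gene = c(10L, 150L, 300L), delta = 6,
                      carrier_fraction = 0.2)
  cfgs <- list(
    null = cohort_config(decoy_amplified_fraction = 0),
    three_subpop = cohort_config(
      planted_genes = three,
      subtype_link = list(list(gene = 300L, label = "Basal", prob = 0.6))),
    hazard = cohort_config(
      planted_genes = data.frame(gene = 10L, delta = 6,
                                 carrier_fraction = 0.3),
      hazard_gene = 10L, hazard_ratio = 3),
    cellline = cohort_config(
      n_tumors = 54, n_reference = 4,
      planted_genes = data.frame(gene = c(10L, 150L, 300L), delta = 6,
                                 carrier_fraction = 0.25),
      subtype_link = list(list(gene = 300L, label = "Basal", prob = 0.9)),
      no_survival = TRUE))
  bundles <- Map(function(cfg, k) generate_cohort(cfg, seed + k),
                 cfgs, seq_along(cfgs))
  if (!is.null(out_dir))
    for (nm in names(bundles))
      write_bundle(bundles[[nm]], file.path(out_dir, nm))
  bundles
}

#' Quantify and screen a cohort bundle end to end
#'
#' Convenience wrapper chaining [compute_fpkm()], [log2_transform()] and
#' [run_screen()] on a bundle (synthetic or ingested).
#'
#' @param bundle list with `counts`, `annotation` and optionally `cna`.
#' @param ... passed to [run_screen()].
#' @return A `screen_result`.
#' @export
screen_bundle <- function(bundle, ...) {
  expr <- log2_transform(compute_fpkm(bundle$counts, bundle$annotation))
  run_screen(expr, cna = bundle$cna, annotation = bundle$annotation, ...)
}
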