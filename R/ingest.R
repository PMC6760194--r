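#' @title Tabular ingest for the screening pipeline
#' @description Readers and writers for the five tab-separated inputs the
#'   pipeline consumes: a gene x sample count matrix, a GISTIC-style
#'   copy-number call matrix, a per-sample clinical table, a gene
#'   annotation table and a per-gene mutation-count table. The dialect is
#'   fixed: tab-separated, UTF-8, header row, `NA` for missing values,
#'   matching GDC/cBioPortal exports.
#' @name ingest
NULL

.enum_stage     <- c("i", "ii", "iii", "iv")
.enum_receptor  <- c("pos", "neg")
.enum_morph     <- c("IDC", "ILC", "mixed", "other")
.enum_subtype   <- c("LumA", "LumB", "Her2", "Basal", "Normal")
.enum_family    <- c("OR", "oncotypedx", "pam50", "other")
.enum_role      <- c("tumor", "reference")

# Reads a genes-x-samples TSV into a numeric matrix, failing loudly on
# ragged lines, duplicate ids or non-numeric cells.
read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fields <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(fields) < 2L)
    stop("malformed TSV '", path, "': need a header row and at least one data row",
         call. = FALSE)
  bad <- which(fields != fields[1L])
  if (length(bad))
    stop(sprintf("malformed TSV '%s': line %d has %d fields, header has %d",
                 path, bad[1L], fields[bad[1L]], fields[1L]), call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2L)
    stop("malformed TSV '", path, "': no sample columns", call. = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicated gene id(s) in '", path, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "), call. = FALSE)
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop("duplicated sample id(s) in '", path, "': ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  vals <- df[, -1L, drop = FALSE]
  non_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(non_num))
    stop("non-numeric entries in '", path, "', column(s): ",
         paste(samples[non_num], collapse = ", "), call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' Construct and validate a count matrix
#'
#' @param values numeric matrix of non-negative integer read counts with
#'   gene ids as rownames and sample ids as colnames.
#' @param sample_role named character vector mapping every sample id to
#'   `"tumor"` or `"reference"`.
#' @return An object of class `count_matrix`: a list with elements
#'   `values` (integer-valued matrix) and `sample_role`.
#' @export
count_matrix <- function(values, sample_role) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("count matrix needs gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values))) stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicated sample ids", call. = FALSE)
  if (anyNA(values)) stop("counts must not contain NA", call. = FALSE)
  if (any(values < 0))
    stop("negative counts are invalid (first offending gene: ",
         rownames(values)[which(values < 0, arr.ind = TRUE)[1L, 1L]], ")",
         call. = FALSE)
  if (max(abs(values - round(values))) > 1e-8)
    stop("counts must be integers", call. = FALSE)
  samples <- colnames(values)
  unknown <- setdiff(names(sample_role), samples)
  if (length(unknown))
    stop("role map names sample(s) absent from the matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing_role <- setdiff(samples, names(sample_role))
  if (length(missing_role))
    stop("sample(s) lack a role: ", paste(missing_role, collapse = ", "),
         call. = FALSE)
  sample_role <- sample_role[samples]
  if (!all(sample_role %in% .enum_role))
    stop("sample roles must be 'tumor' or 'reference'", call. = FALSE)
  structure(list(values = values, sample_role = sample_role),
            class = "count_matrix")
}

#' Read a raw read-count matrix
#'
#' @param path TSV file: first column gene ids, remaining columns one per
#'   sample, header row of sample ids.
#' @param role_map sample-to-role assignment: a named character vector, a
#'   data frame with columns `sample_id` and `role`, or the path of a
#'   two-column TSV with those headers. Roles are `"tumor"` or
#'   `"reference"`; every sample in the matrix must be covered.
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(path, role_map) {
  m <- read_tsv_matrix(path)
  count_matrix(m, as_role_map(role_map))
}

as_role_map <- function(role_map) {
  if (is.character(role_map) && is.null(names(role_map)) &&
      length(role_map) == 1L && file.exists(role_map)) {
    role_map <- utils::read.delim(role_map, stringsAsFactors = FALSE)
  }
  if (is.data.frame(role_map)) {
    need <- c("sample_id", "role")
    if (!all(need %in% colnames(role_map)))
      stop("role map table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    role_map <- stats::setNames(as.character(role_map$role),
                                as.character(role_map$sample_id))
  }
  if (is.null(names(role_map)))
    stop("role map must be named by sample id", call. = FALSE)
  role_map
}

#' Read a GISTIC-style copy-number call matrix
#'
#' Calls follow GISTIC semantics: 2 = high-level amplification, 1 =
#' low-level gain, 0 = diploid, -1 = shallow (heterozygous) loss, -2 =
#' deep (homozygous) deletion.
#'
#' @param path TSV file shaped like the count matrix.
#' @return A matrix of class `cna_matrix` with all entries in -2..2.
#' @export
read_cna_matrix <- function(path) {
  cna_matrix(read_tsv_matrix(path))
}

#' @rdname read_cna_matrix
#' @param values integer matrix of calls.
#' @export
cna_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (anyNA(values)) stop("copy-number calls must not contain NA", call. = FALSE)
  ok <- values %in% c(-2L, -1L, 0L, 1L, 2L)
  if (!all(ok)) {
    first <- which(!ok)[1L]
    stop("invalid copy-number call ", values[first],
         " (allowed: -2, -1, 0, 1, 2)", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicated gene or sample ids", call. = FALSE)
  storage.mode(values) <- "integer"
  structure(values, class = c("cna_matrix", class(matrix())))
}

map_enum <- function(x, allowed, col) {
  x <- as.character(x)
  bad <- !is.na(x) & x != "NA" & !(x %in% allowed)
  if (any(bad)) {
    warning("column '", col, "': unknown token(s) mapped to NA: ",
            paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    x[bad] <- NA_character_
  }
  x[x == "NA"] <- NA_character_
  x
}

#' Read the per-sample clinical table
#'
#' Required columns: `sample_id`, `stage` (i/ii/iii/iv), `er_status` and
#' `her2_status` (pos/neg), `tnbc` (logical), `morphology`
#' (IDC/ILC/mixed/other), `subtype_label` (LumA/LumB/Her2/Basal/Normal),
#' `survival_months` (non-negative), `event` (logical; death observed).
#' Unknown enum tokens become NA with a warning.
#'
#' @param path TSV file.
#' @return A validated data frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "stage", "er_status", "her2_status", "tnbc",
            "morphology", "subtype_label", "survival_months", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  clinical_table(data.frame(
    sample_id       = as.character(df$sample_id),
    stage           = map_enum(df$stage, .enum_stage, "stage"),
    er_status       = map_enum(df$er_status, .enum_receptor, "er_status"),
    her2_status     = map_enum(df$her2_status, .enum_receptor, "her2_status"),
    tnbc            = as.logical(df$tnbc),
    morphology      = map_enum(df$morphology, .enum_morph, "morphology"),
    subtype_label   = map_enum(df$subtype_label, .enum_subtype, "subtype_label"),
    survival_months = as.numeric(df$survival_months),
    event           = as.logical(df$event),
    stringsAsFactors = FALSE))
}

#' @rdname read_clinical
#' @param df data frame with the documented columns.
#' @export
clinical_table <- function(df) {
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample ids in clinical table", call. = FALSE)
  if (any(df$survival_months < 0, na.rm = TRUE))
    stop("survival_months must be >= 0", call. = FALSE)
  if (any(!is.na(df$survival_months) & is.na(df$event)))
    stop("event must be defined wherever survival_months is defined",
         call. = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read the gene annotation table
#'
#' Required columns: `gene_id`, `symbol`, `length_bp` (positive integer,
#' transcript length used for FPKM), `family` (OR/oncotypedx/pam50/other).
#'
#' @param path TSV file.
#' @return A validated data frame of class `gene_annotation`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "symbol", "length_bp", "family")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  gene_annotation(data.frame(
    gene_id   = as.character(df$gene_id),
    symbol    = as.character(df$symbol),
    length_bp = df$length_bp,
    family    = map_enum(df$family, .enum_family, "family"),
    stringsAsFactors = FALSE))
}

#' @rdname read_annotation
#' @param df data frame with the documented columns.
#' @export
gene_annotation <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene ids in annotation", call. = FALSE)
  if (anyNA(df$length_bp) || any(df$length_bp < 1) ||
      max(abs(df$length_bp - round(df$length_bp))) > 1e-8)
    stop("length_bp must be a positive integer for every gene", call. = FALSE)
  df$length_bp <- as.integer(round(df$length_bp))
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read the per-gene mutation-count table
#'
#' Required columns: `gene_id`, `n_mutations` (non-negative integer count
#' of cases carrying a mutation in that gene).
#'
#' @param path TSV file.
#' @return A validated data frame of class `mutation_table`.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "n_mutations")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mutation_table(data.frame(gene_id = as.character(df$gene_id),
                            n_mutations = df$n_mutations,
                            stringsAsFactors = FALSE))
}

#' @rdname read_mutations
#' @param df data frame with the documented columns.
#' @export
mutation_table <- function(df) {
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene ids in mutation table", call. = FALSE)
  if (anyNA(df$n_mutations) || any(df$n_mutations < 0))
    stop("mutation counts must be non-negative", call. = FALSE)
  df$n_mutations <- as.integer(round(df$n_mutations))
  class(df) <- c("mutation_table", "data.frame")
  df
}

write_tsv_matrix <- function(values, path, id_col = "gene_id") {
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write pipeline tables in the canonical TSV dialect
#'
#' Writers are exact inverses of the corresponding readers: for a file
#' produced by a writer, `write(read(f))` is byte-identical to `f`.
#'
#' @param x the object to write.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path) {
  write_tsv_matrix(x$values, path)
}

#' @rdname write_count_matrix
#' @export
write_cna_matrix <- function(x, path) {
  write_tsv_matrix(unclass(x), path)
}

#' @rdname write_count_matrix
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Restrict a count matrix to genes present in the annotation
#'
#' Screening only sees genes present in both the annotation and the count
#' matrix; the dropped genes are recorded on the result.
#'
#' @param counts a [count_matrix()].
#' @param annotation a [gene_annotation()].
#' @return The restricted `count_matrix`, with attribute `dropped_genes`
#'   listing the gene ids that had no annotation.
#' @export
align_gene_space <- function(counts, annotation) {
  keep <- intersect(rownames(counts$values), annotation$gene_id)
  dropped <- setdiff(rownames(counts$values), keep)
  if (length(dropped))
    warning(length(dropped), " gene(s) in counts lack annotation and are ",
            "excluded from quantification", call. = FALSE)
  out <- count_matrix(counts$values[keep, , drop = FALSE], counts$sample_role)
  attr(out, "dropped_genes") <- dropped
  out
}
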