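roles3 <- c(s01 = "tumor", s02 = "reference")

write_counts_file <- function(txt) {
  f <- tempfile(fileext = ".tsv")
  writeLines(txt, f)
  f
}

test_that("a well-formed count TSV parses with the expected shape", {
  f <- write_counts_file(c("gene_id\ts01\ts02",
                           "gA\t10\t0", "gB\t5\t7", "gC\t0\t2"))
  cm <- read_count_matrix(f, roles3)
  expect_s3_class(cm, "count_matrix")
  expect_equal(dim(cm$values), c(3L, 2L))
  expect_equal(unname(cm$sample_role), c("tumor", "reference"))
})

test_that("malformed or invalid count input is rejected with a clear error", {
  dup <- write_counts_file(c("gene_id\ts01\ts02",
                             "gA\t1\t2", "gA\t3\t4"))
  expect_error(read_count_matrix(dup, roles3), "duplicated gene")
  neg <- write_counts_file(c("gene_id\ts01\ts02", "gA\t-5\t2"))
  expect_error(read_count_matrix(neg, roles3), "egative")
  txtv <- write_counts_file(c("gene_id\ts01\ts02", "gA\tfoo\t2"))
  expect_error(read_count_matrix(txtv, roles3), "non-numeric")
  ragged <- write_counts_file(c("gene_id\ts01\ts02", "gA\t1"))
  expect_error(read_count_matrix(ragged, roles3), "line 2")
  f <- write_counts_file(c("gene_id\ts01\ts02", "gA\t1\t2"))
  expect_error(read_count_matrix(f, c(roles3, ghost = "tumor")),
               "absent from the matrix")
  expect_error(read_count_matrix(f, roles3["s01"]), "lack a role")
})

test_that("copy-number calls are validated against the five-value set", {
  f <- write_counts_file(c("gene_id\ts01\ts02",
                           "gA\t0\t0", "gB\t0\t0"))
  cn <- read_cna_matrix(f)
  expect_true(all(cn == 0L)) # diploid everywhere is valid
  f2 <- write_counts_file(c("gene_id\ts01\ts02", "gA\t2\t-2"))
  expect_equal(unname(read_cna_matrix(f2)[1L, ]), c(2L, -2L))
  expect_error(read_cna_matrix(
    write_counts_file(c("gene_id\ts01", "gA\t-3"))), "invalid")
  expect_error(read_cna_matrix(
    write_counts_file(c("gene_id\ts01", "gA\t1.5"))), "invalid")
  expect_error(read_cna_matrix(
    write_counts_file(c("gene_id\ts01", "gA\t3"))), "invalid")
})

test_that("clinical rows parse, unknown tokens map to NA with a warning", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste("sample_id", "stage", "er_status", "her2_status",
                     "tnbc", "morphology", "subtype_label",
                     "survival_months", "event", sep = "\t"),
               "s01\tiv\tpos\tneg\tFALSE\tIDC\tLumA\t150\tTRUE",
               "s02\tbogus\tpos\tneg\tFALSE\tIDC\tLumA\t20\tFALSE"), f)
  expect_warning(cl <- read_clinical(f), "unknown token")
  expect_equal(cl$stage, c("iv", NA))
  expect_equal(cl$survival_months, c(150, 20))
  expect_true(cl$event[1L])
  # missing required column
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tstage", "s01\tii"), f2)
  expect_error(read_clinical(f2), "missing column")
  # event must accompany survival
  bad <- data.frame(sample_id = "s01", stage = "ii", er_status = "pos",
                    her2_status = "neg", tnbc = FALSE, morphology = "IDC",
                    subtype_label = "LumA", survival_months = 10, event = NA)
  expect_error(clinical_table(bad), "event must be defined")
})

test_that("annotation and mutation tables enforce their invariants", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tlength_bp\tfamily",
               "gA\tGENEA\t0\tOR"), f)
  expect_error(read_annotation(f), "length_bp")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tsymbol\tlength_bp\tfamily",
               "gA\tGENEA\t1000\tOR",
               "gB\tGENEB\t2000\toncotypedx"), f2)
  ann <- read_annotation(f2)
  expect_equal(ann$family, c("OR", "oncotypedx"))
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tn_mutations", "OR5I1\t8", "OR11H1\t8"), f3)
  mut <- read_mutations(f3)
  expect_equal(mut$n_mutations[mut$gene_id == "OR5I1"], 8L)
  expect_error(mutation_table(data.frame(gene_id = "g", n_mutations = -1)),
               "non-negative")
})

test_that("write(read(f)) is byte-identical for the canonical dialect", {
  cm <- count_matrix(mat(c(10, 5, 0, 0, 7, 2), 3), roles3)
  f1 <- tempfile(); f2 <- tempfile()
  write_count_matrix(cm, f1)
  write_count_matrix(read_count_matrix(f1, roles3), f2)
  expect_identical(readLines(f1), readLines(f2))

  cn <- cna_matrix(mat(c(0L, 2L, -1L, 1L, -2L, 0L), 3))
  write_cna_matrix(cn, f1)
  write_cna_matrix(read_cna_matrix(f1), f2)
  expect_identical(readLines(f1), readLines(f2))

  cl <- clinical_table(data.frame(
    sample_id = c("s01", "s02"), stage = c("ii", NA),
    er_status = c("pos", "neg"), her2_status = c("neg", NA),
    tnbc = c(FALSE, NA), morphology = c("IDC", "ILC"),
    subtype_label = c("LumA", "Basal"),
    survival_months = c(12.5, 80), event = c(TRUE, FALSE)))
  write_table_tsv(cl, f1)
  write_table_tsv(read_clinical(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene-space join drops unannotated genes and records them", {
  cm <- count_matrix(mat(c(1, 2, 3, 4), 2, genes = c("gA", "gZ")), roles3)
  ann <- gene_annotation(data.frame(gene_id = "gA", symbol = "A",
                                    length_bp = 1000, family = "OR"))
  expect_warning(al <- align_gene_space(cm, ann), "lack annotation")
  expect_equal(rownames(al$values), "gA")
  expect_equal(attr(al, "dropped_genes"), "gZ")
})
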