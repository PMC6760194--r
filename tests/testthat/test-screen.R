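ref4 <- c(r1 = "reference", r2 = "reference", r3 = "reference",
          r4 = "reference")

test_that("reference statistics use the sample SD and flag flat genes", {
  v <- mat(c(3, 1, 3, 2, 3, 3, 3, 4), 2, genes = c("flat", "spread"),
           samples = names(ref4))
  e <- make_expr(v, roles = ref4)
  rs <- reference_stats(e, names(ref4))
  expect_equal(rs$mean_ref, c(3, 2.5))
  expect_equal(rs$sd_ref[2L], sd(1:4), tolerance = 1e-12) # 1.2910
  expect_equal(rs$sd_ref[1L], 0)
  expect_equal(rs$screenable, c(FALSE, TRUE))
  expect_error(reference_stats(e, "r1"), "at least 2")
})

test_that("z-scores measure deviation in reference-SD units", {
  roles <- c(ref4, t1 = "tumor")
  v <- mat(c(2.5, 2.5, 1, 2, 2.5, 3, 2.5, 4, 3, 2), 2,
           genes = c("gA", "gB"), samples = names(roles))
  # gA: refs (2.5, 1, 2.5, 2.5) -> handled generically; use clean genes:
  v["gA", ] <- c(2, 4, 2, 4, 3)   # mean 3, sd ~1.1547
  v["gB", ] <- c(2.5, 3.5, 2.5, 3.5, 2)
  e <- make_expr(v, roles = roles)
  rs <- reference_stats(e, names(ref4))
  z <- zscores(e, rs)
  expect_equal(z["gA", "t1"], (3 - 3) / sd(c(2, 4, 2, 4)))
  expect_equal(z["gB", "t1"], (2 - 3) / sd(c(2.5, 3.5, 2.5, 3.5)))
  # hand cases via a manufactured reference table
  rs2 <- data.frame(gene_id = c("gA", "gB"), mean_ref = 3,
                    sd_ref = c(1, 0.5), n_ref = 4, screenable = TRUE)
  e2 <- make_expr(mat(c(5, 2), 2, genes = c("gA", "gB"), samples = "t1"))
  z2 <- zscores(e2, rs2)
  expect_equal(unname(z2[, "t1"]), c(2, -2))
  rs2$screenable[2L] <- FALSE
  expect_error(zscores(e2, rs2, genes = c("gA", "gB")), "unscreenable")
})

test_that("burden statistics follow the cohort definitions exactly", {
  z <- mat(c(2.5, 1.0, 3.0, -1.0), 1, genes = "gA")
  st <- burden_stats(z, z_cut = 2, sum_mode = "all")
  # cohort m: samples with any gene at Z >= 2 -> columns 1 and 3
  expect_equal(attr(st, "m"), 2L)
  expect_equal(st$n_upreg, 2L)
  expect_equal(st$sum_upreg, 5.5)
  expect_identical(st$weighted_upreg, st$n_upreg * st$sum_upreg) # 11
  expect_equal(st$prevalence, 2 / 4)

  # boundary: Z = 2.0 exactly counts as upregulated
  zb <- mat(c(2.0, 1.999999), 1, genes = "gA")
  expect_equal(burden_stats(zb)$n_upreg, 1L)

  # all below cut: n = 0, weighted = 0
  z0 <- mat(c(1, 0.5, -3), 1, genes = "gA")
  st0 <- burden_stats(z0)
  expect_equal(st0$n_upreg, 0L)
  expect_equal(st0$weighted_upreg, 0)

  expect_error(burden_stats(z[, 0, drop = FALSE]), "empty cohort")
})

test_that("weighted upregulation is machine-exactly n * sum, any mode", {
  set.seed(11)
  for (mode in c("all", "positive", "above_cut")) {
    z <- mat(rnorm(300, sd = 2), 15)
    st <- burden_stats(z, sum_mode = mode)
    expect_identical(st$weighted_upreg, st$n_upreg * st$sum_upreg)
    expect_true(all(st$n_upreg >= 0 & st$n_upreg <= ncol(z)))
    expect_true(all(st$prevalence >= 0 & st$prevalence <= 1))
  }
})

test_that("thresholds sit at the one-sided normal upper-alpha point", {
  st <- data.frame(gene_id = c("a", "b", "c"), sum_upreg = c(8, 10, 12),
                   n_upreg = c(8, 10, 12), weighted_upreg = c(8, 10, 12))
  thr <- significance_thresholds(st, alpha = 0.05)
  expect_equal(thr$sum_threshold, 10 + qnorm(0.95) * 2)
  expect_equal(thr$sum_threshold, 13.2897, tolerance = 1e-4)
  # alpha = 0.5 degenerates to the mean
  expect_equal(significance_thresholds(st, alpha = 0.5)$sum_threshold, 10)
  # constant statistic: threshold equals the constant, with a warning
  stc <- data.frame(gene_id = c("a", "b", "c"), sum_upreg = 7,
                    n_upreg = 7, weighted_upreg = 7)
  w <- testthat::capture_warnings(thc <- significance_thresholds(stc))
  expect_match(w, "degenerate", all = TRUE)
  expect_length(w, 3L) # one per statistic
  expect_equal(thc$sum_threshold, 7)
  expect_error(significance_thresholds(st[1:2, ]), "at least 3")
  expect_error(significance_thresholds(st, alpha = 1), "alpha")
})

test_that("two-part selection demands both statistics jointly", {
  st <- data.frame(gene_id = c("onlysum", "both", "neither"),
                   sum_upreg = c(100, 100, 0),
                   n_upreg = c(0, 50, 0),
                   weighted_upreg = c(0, 5000, 0))
  thr <- list(sum_threshold = 50, count_threshold = 10,
              weighted_threshold = 1000)
  sel <- select_two_part(st, thr)
  expect_equal(sel$part1, "both") # "onlysum" fails the weighted leg
  expect_equal(sel$part2, "both")
  expect_equal(sel$shared, "both")
  thr_hi <- list(sum_threshold = 1e6, count_threshold = 1e6,
                 weighted_threshold = 1e6)
  sel2 <- select_two_part(st, thr_hi)
  expect_length(sel2$part1, 0)
  expect_length(sel2$shared, 0)
})

test_that("high-level amplification means a call of 2, low gain does not", {
  cn <- cna_matrix(mat(c(0L, 0L, 1L, 0L, 2L, 1L), 3,
                       genes = c("none", "with2", "gain1")))
  expect_equal(high_amplification_genes(cn), "with2")
  cn0 <- cna_matrix(mat(rep(0L, 6), 3))
  expect_length(high_amplification_genes(cn0), 0)
})

test_that("the over-expressed set is the shared/amplified intersection", {
  sel <- list(part1 = c("A", "B", "C"), part2 = c("A", "B", "C"),
              shared = c("A", "B", "C"))
  res <- overexpressed_set(sel, c("B", "C", "D"))
  expect_equal(res$overexpressed, c("B", "C"))
  expect_length(overexpressed_set(sel, character(0))$overexpressed, 0)
  # per-case flags
  z <- mat(c(3, 0, 0, 0, 1, 2.5), 3, genes = c("A", "B", "C"))
  res2 <- overexpressed_set(sel, c("B", "C"), z = z, z_cut = 2)
  expect_equal(unname(res2$case_flags), c(FALSE, TRUE)) # s02 has C at 2.5
})

test_that("nesting invariants of the funnel hold on generated screens", {
  set.seed(3)
  b <- generate_cohort(small_cohort_config(
    planted_genes = data.frame(gene = 1L, delta = 6,
                               carrier_fraction = 0.3)), seed = 5)
  res <- screen_bundle(b)
  expect_true(all(res$overexpressed %in% res$shared))
  expect_true(all(res$shared %in% res$part1))
  expect_true(all(res$shared %in% res$part2))
  expect_true(all(res$overexpressed %in% res$amplified))
})

test_that("raising z_cut never increases the upregulated-case count", {
  set.seed(9)
  z <- mat(rnorm(400, sd = 2), 20)
  cuts <- c(1, 1.5, 2, 2.5, 3)
  n_by_cut <- sapply(cuts, function(ct) burden_stats(z, z_cut = ct)$n_upreg)
  expect_true(all(apply(n_by_cut, 1L, function(v) all(diff(v) <= 0))))
  # enlarging the amplified set never shrinks the over-expressed set
  sel <- list(shared = rownames(z), part1 = rownames(z), part2 = rownames(z))
  small <- overexpressed_set(sel, rownames(z)[1:3])$overexpressed
  large <- overexpressed_set(sel, rownames(z)[1:10])$overexpressed
  expect_true(all(small %in% large))
})

test_that("the downregulation mirror counts Z <= -cut and can come up empty", {
  z <- mat(c(-3, -2.5, 1, 0.4), 1, genes = "gA")
  std <- burden_stats(-z, z_cut = 2)
  expect_equal(std$n_upreg, 2L)
  # all-positive z-scores: empty mirror result
  roles <- c(ref4, t1 = "tumor", t2 = "tumor")
  set.seed(21)
  v <- mat(rnorm(60, mean = 5), 10, samples = names(roles))
  v[, c("t1", "t2")] <- v[, c("t1", "t2")] + 6 # tumors far above refs
  e <- make_expr(v, roles = roles)
  res <- suppressWarnings(downregulation_screen(e)) # degenerate thresholds
  expect_equal(res$direction, "down")
  expect_length(res$overexpressed, 0)
})

test_that("mutation overlap intersects over-expressed and mutated genes", {
  res <- structure(list(overexpressed = c("A", "B")),
                   class = "screen_result")
  mut <- mutation_table(data.frame(gene_id = c("A", "C"),
                                   n_mutations = c(3L, 1L)))
  expect_equal(mutation_overlap(res, mut), "A")
  disjoint <- mutation_table(data.frame(gene_id = c("X", "Y"),
                                        n_mutations = c(8L, 6L)))
  expect_length(mutation_overlap(res, disjoint), 0)
  none <- mutation_table(data.frame(gene_id = character(0),
                                    n_mutations = integer(0)))
  expect_length(mutation_overlap(res, none), 0)
})

test_that("prevalence bins are right-open with a closed last bin", {
  st <- data.frame(prevalence = c(0.01, 0.02, 0.11))
  expect_equal(unname(prevalence_summary(st, edges = c(0.05, 0.10))),
               c(2L, 0L, 1L))
  st0 <- data.frame(prevalence = numeric(0))
  expect_equal(unname(prevalence_summary(st0, edges = c(0.05, 0.10))),
               c(0L, 0L, 0L))
  # boundary prevalence exactly at an edge falls in the upper bin
  st1 <- data.frame(prevalence = c(0.05, 1))
  expect_equal(unname(prevalence_summary(st1, edges = c(0.05, 0.10))),
               c(0L, 1L, 1L))
})

test_that("screen diagnostics report every funnel size per sum mode", {
  b <- generate_cohort(small_cohort_config(), seed = 2)
  expr <- log2_transform(compute_fpkm(b$counts, b$annotation))
  d <- screen_diagnostics(expr, cna = b$cna, annotation = b$annotation)
  expect_equal(d$sum_mode, c("all", "positive", "above_cut"))
  expect_true(all(c("n_part1", "n_part2", "n_shared", "n_overexpressed",
                    "sum_threshold", "weighted_threshold") %in% colnames(d)))
  expect_true(all(d$n_shared <= pmin(d$n_part1, d$n_part2)))
})
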