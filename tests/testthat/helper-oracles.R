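# Independent oracles: deliberately naive re-implementations (explicit
# loops, from-scratch formulas) used only to check the package's output.

# Brute-force funnel enumeration over a z-score matrix and CNA calls.
oracle_funnel <- function(z, cna, z_cut = 2, alpha = 0.05,
                          sum_mode = "all") {
  genes <- rownames(z)
  cohort <- c()
  for (j in seq_len(ncol(z))) {
    any_up <- FALSE
    for (i in seq_len(nrow(z))) if (z[i, j] >= z_cut) any_up <- TRUE
    if (any_up) cohort <- c(cohort, j)
  }
  n_i <- s_i <- numeric(length(genes))
  for (i in seq_along(genes)) {
    for (j in cohort) {
      if (z[i, j] >= z_cut) n_i[i] <- n_i[i] + 1
      s_i[i] <- s_i[i] + switch(sum_mode,
        all = z[i, j],
        positive = if (z[i, j] > 0) z[i, j] else 0,
        above_cut = if (z[i, j] >= z_cut) z[i, j] else 0)
    }
  }
  w_i <- n_i * s_i
  thr <- function(v) if (sd(v) == 0) v[1] else mean(v) + qnorm(1 - alpha) * sd(v)
  ts <- thr(s_i); tn <- thr(n_i); tw <- thr(w_i)
  part1 <- genes[s_i > ts & w_i > tw]
  part2 <- genes[n_i > tn & w_i > tw]
  shared <- intersect(part1, part2)
  amplified <- c()
  for (g in rownames(cna)) {
    has2 <- FALSE
    for (j in seq_len(ncol(cna))) if (cna[g, j] == 2) has2 <- TRUE
    if (has2) amplified <- c(amplified, g)
  }
  list(part1 = part1, part2 = part2, shared = shared,
       amplified = intersect(amplified, genes),
       overexpressed = intersect(shared, intersect(amplified, genes)),
       n_i = n_i, s_i = s_i, w_i = w_i)
}

# One-way ANOVA from first principles (sums of squares).
oracle_anova_f <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    v <- values[groups == lev]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# Product-limit estimator by hand (events before censorings at ties).
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]; events <- as.logical(events[ord])
  ts <- sort(unique(times[events]))
  surv <- numeric(length(ts)); s <- 1
  for (k in seq_along(ts)) {
    n_risk <- sum(times >= ts[k])
    d <- sum(times == ts[k] & events)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Two-group log-rank by observed-minus-expected tabulation.
oracle_logrank <- function(t1, e1, t2, e2) {
  times <- c(t1, t2); events <- as.logical(c(e1, e2))
  grp <- rep(1:2, c(length(t1), length(t2)))
  ts <- sort(unique(times[events]))
  o_minus_e <- 0; v <- 0
  for (tk in ts) {
    n <- sum(times >= tk)
    n1 <- sum(times >= tk & grp == 1)
    d <- sum(times == tk & events)
    d1 <- sum(times == tk & events & grp == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Quick builders -------------------------------------------------------

make_expr <- function(values, roles = NULL, stage = "log2fpkm") {
  if (is.null(roles))
    roles <- setNames(rep("tumor", ncol(values)), colnames(values))
  expression_matrix(values, stage, sample_role = roles,
                    pseudocount = if (stage == "log2fpkm") 1 else NULL)
}

mat <- function(v, nr, genes = NULL, samples = NULL) {
  m <- matrix(v, nrow = nr)
  rownames(m) <- if (is.null(genes)) sprintf("g%02d", seq_len(nrow(m)))
                 else genes
  colnames(m) <- if (is.null(samples)) sprintf("s%02d", seq_len(ncol(m)))
                 else samples
  m
}

small_cohort_config <- function(...) {
  cohort_config(n_tumors = 60, n_reference = 4, n_family_genes = 40,
                n_background_genes = 120, include_panel_genes = FALSE, ...)
}
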