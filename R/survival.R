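#' @title Kaplan-Meier estimation and log-rank stratification
#' @name survival-module
NULL

#' Kaplan-Meier product-limit estimate
#'
#' Standard convention at tied times: events before censorings, so a
#' censored observation at t still counts in the risk set of the event at
#' t. With no censoring the estimate equals the empirical survival
#' function.
#'
#' @param times non-negative follow-up times (months).
#' @param events logical (or 0/1): TRUE when death was observed.
#' @return Data frame of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (step function value just after
#'   `time`; S(0) = 1).
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("empty survival input", call. = FALSE)
  if (any(times < 0, na.rm = TRUE)) stop("times must be >= 0", call. = FALSE)
  events <- as.logical(events)
  keep <- !is.na(times) & !is.na(events)
  if (!any(keep)) stop("no usable (time, event) pairs", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times[keep], events[keep]) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, row.names = NULL)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank statistic with the hypergeometric variance and
#' no continuity correction.
#'
#' @param times_a,events_a follow-up and event indicators, group A.
#' @param times_b,events_b follow-up and event indicators, group B.
#' @return List with `chisq`, `df`, `p`.
#' @export
logrank <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("both groups must be non-empty", call. = FALSE)
  times <- c(times_a, times_b)
  events <- as.logical(c(events_a, events_b))
  grp <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ grp, rho = 0)
  chisq <- unname(sd_$chisq)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

#' Survival stratified by gene upregulation
#'
#' Splits cases into "upregulated" (Z >= z_cut in the gene, or in any
#' member of a gene group) versus the rest, estimates both Kaplan-Meier
#' curves and compares them by the log-rank test.
#'
#' @param z z-score matrix (genes x tumor samples).
#' @param gene a gene id, or a character vector for a gene group.
#' @param clinical a [clinical_table()] supplying `survival_months` and
#'   `event` for the z-score columns.
#' @param z_cut upregulation cut-off (default 2, the screen's cut).
#' @return List of class `stratified_survival`: `groups` (named character
#'   vector "upregulated"/"not_upregulated"), `curves` (list of two
#'   `km_curve`s), `chisq`, `p`, `n`.
#' @export
stratify_by_gene <- function(z, gene, clinical, z_cut = 2) {
  miss <- setdiff(gene, rownames(z))
  if (length(miss)) stop("gene(s) not in z-score matrix: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  idx <- match(colnames(z), clinical$sample_id)
  usable <- !is.na(idx) & !is.na(clinical$survival_months[idx])
  if (!any(usable)) stop("no cases with survival data", call. = FALSE)
  ids <- colnames(z)[usable]
  months <- clinical$survival_months[idx[usable]]
  events <- clinical$event[idx[usable]]
  up <- apply(z[gene, ids, drop = FALSE] >= z_cut, 2L, any)
  lab <- paste(gene, collapse = "+")
  if (!any(up)) stop("no upregulated cases for ", lab, call. = FALSE)
  if (all(up)) stop("no non-upregulated cases for ", lab, call. = FALSE)
  lr <- logrank(months[up], events[up], months[!up], events[!up])
  structure(list(
    groups = stats::setNames(ifelse(up, "upregulated", "not_upregulated"),
                             ids),
    curves = list(upregulated = km_estimate(months[up], events[up]),
                  not_upregulated = km_estimate(months[!up], events[!up])),
    chisq = lr$chisq, p = lr$p, n = length(ids), gene = lab),
    class = "stratified_survival")
}

#' @export
print.stratified_survival <- function(x, ...) {
  cat("Survival stratified by", x$gene, "upregulation\n")
  cat("  n =", x$n, "(", sum(x$groups == "upregulated"), "upregulated )\n")
  cat(sprintf("  log-rank chi-square = %.3f, p = %.4g\n", x$chisq, x$p))
  invisible(x)
}
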