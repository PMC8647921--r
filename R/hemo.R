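#' Acute hemodynamic response (AHR)
#'
#' Percentage change in LV dP/dt_max from baseline to biventricular
#' pacing: `100 * (biv - baseline) / baseline`.
#'
#' @param baseline,biv dP/dt_max in mmHg/s (vectorized; baseline must be
#'   positive).
#' @return AHR in percent.
#' @export
ahr <- function(baseline, biv) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline dP/dt_max must be positive")
  100 * (biv - baseline) / baseline
}

#' Classify a pacing site as an acute responder
#'
#' The mean AHR over repeat measurements at the site is compared with the
#' threshold (default 10%). The comparison is strict `>` by default, with
#' `strict = FALSE` switching to `>=` (both conventions appear in the
#' source literature for this cutoff).
#'
#' @param ahr_values AHR values (%) at one site; at least one required.
#' @param threshold percent (default 10).
#' @param strict use strict `>` (default) instead of `>=`.
#' @return Logical.
#' @export
classify_responder <- function(ahr_values, threshold = 10, strict = TRUE) {
  if (!length(ahr_values)) stop("no AHR values supplied")
  m <- mean(ahr_values)
  if (strict) m > threshold else m >= threshold
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: with all
#' margins fixed, p is the sum of hypergeometric point probabilities of
#' every admissible table whose probability does not exceed that of the
#' observed table (within a relative slack of 1e-7 to absorb floating
#' point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List: `p` (two-sided p-value), `estimate` (sample odds ratio).
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("all-zero table")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0) stop("all margins must be positive")
  n <- r1 + r2
  x <- tab[1, 1]
  support <- max(0L, c1 - r2):min(r1, c1)
  dens <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(x, r1, r2, c1)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(p = min(p, 1), estimate = or)
}

#' Volumetric reverse-remodeling response
#'
#' Responder iff the relative LVESV reduction
#' `100 * (esv0 - esv6) / esv0` exceeds the threshold (default 15%;
#' strict `>` by default, `strict = FALSE` for `>=`).
#'
#' @param esv0,esv6 baseline and 6-month LV end-systolic volumes (ml,
#'   positive; vectorized).
#' @param threshold percent improvement (default 15).
#' @param strict strict `>` (default) or `>=`.
#' @return Logical vector.
#' @export
remodeling_response <- function(esv0, esv6, threshold = 15, strict = TRUE) {
  if (any(esv0 <= 0) || any(esv6 <= 0)) stop("volumes must be positive")
  impr <- 100 * (esv0 - esv6) / esv0
  if (strict) impr > threshold else impr >= threshold
}

#' Paired comparison of two measurement series
#'
#' Paired t test for normally distributed data or Wilcoxon signed-rank
#' test otherwise, as a thin wrapper over the standard tests. Degenerate
#' inputs for the t test (zero variance of the paired differences,
#' including identical vectors) are flagged: identical vectors report
#' p = 1, a constant non-zero difference reports `NA` (the t statistic is
#' undefined).
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 2).
#' @param method `"paired_t"` or `"wilcoxon"`.
#' @return List: `statistic`, `p`, `method`, `degenerate` flag.
#' @export
paired_comparison <- function(values_a, values_b,
                              method = c("paired_t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(values_a) != length(values_b)) stop("length mismatch")
  if (length(values_a) < 2L) stop("need at least 2 pairs")
  d <- values_a - values_b
  if (method == "paired_t") {
    if (stats::sd(d) == 0) {
      return(list(statistic = NA_real_,
                  p = if (all(d == 0)) 1 else NA_real_,
                  method = method, degenerate = TRUE))
    }
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value,
         method = method, degenerate = FALSE)
  } else {
    if (all(d == 0))
      return(list(statistic = NA_real_, p = 1, method = method,
                  degenerate = TRUE))
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              paired = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value,
         method = method, degenerate = FALSE)
  }
}

#' Cohort-level hemodynamic summary
#'
#' Summarizes a paired target/nontarget cohort (one AHR per site per
#' patient, as produced by [generate_hemo_cohort()]): group means and SDs,
#' per-site responder classification at the AHR threshold, the responder
#' 2x2 table with its exact p-value, and the paired target-vs-nontarget
#' test.
#'
#' @param cohort data.frame with `patient`, `is_target`, `ahr`.
#' @param threshold responder AHR threshold, percent (default 10).
#' @param strict strict `>` responder rule (default).
#' @param method paired test, `"paired_t"` (default) or `"wilcoxon"`.
#' @return List with `groups` (summary data.frame), `responders` (2x2
#'   matrix), `fisher` (exact test), `paired` (test result).
#' @export
hemo_summary <- function(cohort, threshold = 10, strict = TRUE,
                         method = "paired_t") {
  t_ahr <- cohort$ahr[cohort$is_target]
  n_ahr <- cohort$ahr[!cohort$is_target]
  resp_t <- vapply(t_ahr, classify_responder, logical(1),
                   threshold = threshold, strict = strict)
  resp_n <- vapply(n_ahr, classify_responder, logical(1),
                   threshold = threshold, strict = strict)
  tab <- matrix(c(sum(resp_t), sum(!resp_t), sum(resp_n), sum(!resp_n)),
                2, byrow = TRUE,
                dimnames = list(c("target", "nontarget"),
                                c("responder", "nonresponder")))
  paired <- if (length(t_ahr) == length(n_ahr) && length(t_ahr) >= 2)
    paired_comparison(t_ahr, n_ahr, method) else NULL
  fisher <- if (min(rowSums(tab)) > 0 && min(colSums(tab)) > 0)
    fisher_exact_2x2(tab) else NULL
  groups <- data.frame(
    site = c("target", "nontarget"),
    n = c(length(t_ahr), length(n_ahr)),
    mean_ahr = c(mean(t_ahr), mean(n_ahr)),
    sd_ahr = c(stats::sd(t_ahr), stats::sd(n_ahr)),
    responders = c(sum(resp_t), sum(resp_n)),
    responder_pct = 100 * c(mean(resp_t), mean(resp_n)))
  list(groups = groups, responders = tab, fisher = fisher, paired = paired)
}
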