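#!/usr/bin/env Rscript
# Hemodynamic validation and outcome statistics: the exact tests on the
# study's printed contingency tables, and a synthetic paired cohort at the
# published group parameters (AHR 14.4 +/- 7.4 % target vs 6.9 +/- 5.9 %
# nontarget, 12 pairs).

suppressMessages(library(crtarget))
dir.create("results", showWarnings = FALSE)

# printed counts: acute responders 10/12 target vs 3/12 nontarget sites
resp <- matrix(c(10, 2, 3, 9), 2, byrow = TRUE,
               dimnames = list(c("target", "nontarget"),
                               c("responder", "nonresponder")))
f1 <- fisher_exact_2x2(resp)
message(sprintf("acute responders %.1f%% vs %.1f%%, two-sided exact p = %.3f",
                100 * 10 / 12, 100 * 3 / 12, f1$p))

# printed counts: 6-month volumetric response 4/8 ICM vs 5/7 NICM
remod <- matrix(c(4, 4, 5, 2), 2, byrow = TRUE)
f2 <- fisher_exact_2x2(remod)
message(sprintf("remodeling by etiology 50.0%% vs 71.4%%, p = %.3f", f2$p))

# synthetic paired cohort at the published group parameters
cohort <- generate_hemo_cohort(12, seed = 77L)
utils::write.csv(cohort, "results/cohort.csv", row.names = FALSE)
s <- hemo_summary(cohort)
message(sprintf(
  "synthetic cohort: target AHR %.1f +/- %.1f%%, nontarget %.1f +/- %.1f%%; paired t p = %.4f",
  s$groups$mean_ahr[1], s$groups$sd_ahr[1],
  s$groups$mean_ahr[2], s$groups$sd_ahr[2], s$paired$p))

jsonlite::write_json(
  list(printed_responders = list(table = as.data.frame(resp), p = f1$p),
       printed_remodeling = list(p = f2$p),
       synthetic_cohort = list(groups = s$groups,
                               responders = as.data.frame(s$responders),
                               fisher_p = if (!is.null(s$fisher)) s$fisher$p,
                               paired_t_p = s$paired$p)),
  "results/hemo_stats.json", auto_unbox = TRUE, digits = NA, null = "null")
message("wrote results/hemo_stats.json")
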