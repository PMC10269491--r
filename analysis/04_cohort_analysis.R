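#!/usr/bin/env Rscript
# Step 4: cohort-level statistics on the synthetic cohort.
#
# Normality-gated two-group comparisons of RTL and the iron panel,
# second-order polynomial ferritin-vs-age fits, linear fits of
# biological vs chronological age by HIV status and by regimen, and the
# pairwise relation scan (viral load floored at the detection limit).

suppressPackageStartupMessages(library(ironclock))
dir.create("results", showWarnings = FALSE)

cohort <- read_subjects("results/cohort.csv", quiet = TRUE)
bt <- utils::read.csv("results/bioage.csv")

pos <- cohort[cohort$hiv_status == "positive", ]
neg <- cohort[cohort$hiv_status == "negative", ]

vars <- c("rtl", "serum_iron", "tibc", "ferritin", "transferrin",
          "transferrin_saturation")
rows <- list()
for (v in vars) {
  cmp <- compare_groups(neg[[v]], pos[[v]], labels = c("HIV-", "HIV+"),
                        variable = v)
  print(cmp)
  rows[[v]] <- data.frame(variable = v, test = cmp$test,
                          statistic = cmp$statistic, df = cmp$df,
                          p = cmp$p.value,
                          loc_neg = cmp$location[1], loc_pos = cmp$location[2],
                          scale_neg = cmp$scale[1], scale_pos = cmp$scale[2],
                          summary_type = cmp$summary_type)
}
# within-status age-band RTL comparisons (younger vs older)
for (st in c("negative", "positive")) {
  g <- cohort[cohort$hiv_status == st, ]
  cmp <- compare_groups(g$rtl[g$age <= 35], g$rtl[g$age >= 50],
                        labels = c("younger", "older"),
                        variable = paste0("rtl_", st))
  print(cmp)
  rows[[paste0("rtl_", st)]] <-
    data.frame(variable = paste0("rtl_", st), test = cmp$test,
               statistic = cmp$statistic, df = cmp$df, p = cmp$p.value,
               loc_neg = cmp$location[1], loc_pos = cmp$location[2],
               scale_neg = cmp$scale[1], scale_pos = cmp$scale[2],
               summary_type = cmp$summary_type)
}
utils::write.csv(do.call(rbind, rows), "results/comparisons.csv",
                 row.names = FALSE)

# ferritin-age curvature by HIV status
for (st in c("negative", "positive")) {
  g <- cohort[cohort$hiv_status == st, ]
  pf <- polyfit2(g$age, g$ferritin)
  cat(sprintf("ferritin ~ age, HIV %s: c0 %.3f, c1 %.4f, c2 %.6f (n = %d)\n",
              st, pf$coefficients["c0"], pf$coefficients["c1"],
              pf$coefficients["c2"], pf$n))
}

fits_status <- bioage_fits(bt, cohort, group_by = "hiv_status")
fits_regimen <- bioage_fits(bt, cohort, group_by = "regimen")
fits <- rbind(cbind(grouping = "hiv_status", fits_status),
              cbind(grouping = "regimen", fits_regimen))
utils::write.csv(fits, "results/bioage_fits.csv", row.names = FALSE)
cat("\nbiological-vs-chronological age fits:\n")
print(within(fits, {slope <- round(slope, 3); intercept <- round(intercept, 2)
                    r_squared <- round(r_squared, 3)}))

scan <- relation_scan(cohort)
utils::write.csv(scan, "results/relation_scan.csv", row.names = FALSE)
cat("\nrelation scan (no significance claims):\n")
print(within(scan, {slope <- signif(slope, 3); intercept <- signif(intercept, 4)
                    r_squared <- round(r_squared, 4)}))
cat("wrote results/comparisons.csv, results/bioage_fits.csv, results/relation_scan.csv\n")
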