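#!/usr/bin/env Rscript
# Step 1: simulate the study's data world.
#
# Generates (a) a synthetic referent population per age band, with the
# published normalization moments and normalized age-slopes, and (b) a
# synthetic HIV+/HIV- study cohort with the published group structure
# (105 HIV-infected, 100 uninfected blood donors).  Writes both under
# results/.

suppressPackageStartupMessages(library(ironclock))
dir.create("results", showWarnings = FALSE)
seed <- 1

for (band in c("younger", "older")) {
  pop <- generate_referent(referent_spec(band, n = 10000, seed = seed))
  ntr <- attr(pop, "n_truncated")
  utils::write.csv(pop, file.path("results", paste0("referent_", band, ".csv")),
                   row.names = FALSE)
  cat(sprintf("referent %-7s n = %d, mean age %.2f, truncated at zero: %s\n",
              band, nrow(pop), mean(pop$age),
              paste(names(ntr), ntr, collapse = ", ")))
}

cohort <- generate_cohort(cohort_spec(seed = seed))
write_subjects(cohort, "results/cohort.csv")
cat(sprintf("cohort: %d HIV+ (%d naive), %d HIV-; undetectable pVL: %d/%d\n",
            sum(cohort$hiv_status == "positive"),
            sum(cohort$regimen == "naive"),
            sum(cohort$hiv_status == "negative"),
            sum(cohort$pvl < 20, na.rm = TRUE),
            sum(!is.na(cohort$pvl))))
cat("wrote results/referent_{younger,older}.csv and results/cohort.csv\n")
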