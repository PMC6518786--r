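#!/usr/bin/env Rscript
# Stage 4 — prevalence ratios of cause-specific death by hour, age, sex.
#
# Modified-Poisson (log-link, robust-variance) regression of the
# cause indicator on 23 hour dummies (reference 0:00-0:59), sex, and age,
# over all deaths; the three causes are merged side by side in the
# familiar hour/sex/age table layout.
#
# Reads:  scratch/cohort.csv
# Writes: results/prevalence_ratios.csv, results/prevalence_ratios.json

library(circamort)

cohort <- read_records("scratch/cohort.csv")
causes <- c("cancer", "ischemic_heart_disease", "pneumonia")

tabs <- lapply(causes, function(cz) fit_pr(cohort, cz))
report <- pr_report(tabs,
                    csv = "results/prevalence_ratios.csv",
                    json = "results/prevalence_ratios.json")

print(as.data.frame(report), row.names = FALSE)
cat("\nThe injected 1.2x heaping at hours 6 and 20 is cause-neutral (every",
    "cause shares one time distribution), so it cancels out of the",
    "cause-specific prevalence ratios: hour rows stay near 1 even at the",
    "heaped hours. An elevation like a 1.24 PR at 6 am requires",
    "cause-specific registration behaviour. 23 hour contrasts are shown",
    "per cause with no multiplicity adjustment.\n")
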