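#!/usr/bin/env Rscript
# Stage 2 — parametric sinusoidal circadian test per cause.
#
# Encodes each cause's times of death on the circle and tests uniformity
# with the resultant-length statistic z = n Rbar^2, p = exp(-z); the
# cosinor model on hourly counts is run alongside as a sensitivity check.
#
# Reads:  scratch/cohort.csv
# Writes: results/circadian_tests.csv

library(circamort)

cohort <- read_records("scratch/cohort.csv")
causes <- c("cancer", "ischemic_heart_disease", "pneumonia")

rows <- lapply(causes, function(cz) {
  sel <- cohort[cohort$cause == cz, ]
  ct <- circadian_test(sel)
  cs <- cosinor_test(aggregate_counts(sel, "hour"))
  tibble::tibble(cause = cz, n = ct$n,
                 z = round(ct$z, 3), p = round(ct$p, 4),
                 Rbar = signif(ct$Rbar, 3),
                 cosinor_lr = round(cs$statistic, 2),
                 cosinor_p = signif(cs$p, 3))
})
tab <- dplyr::bind_rows(rows)
readr::write_csv(tab, "results/circadian_tests.csv")

print(as.data.frame(tab), row.names = FALSE)
cat("\nThe cohort has no true rhythm (rho = 0), but the 1.2x heaping at",
    "hours 6 and 20 is not antipodal, so it leaves a tiny first-harmonic",
    "resultant (population Rbar ~ 0.004). At registry scale (n ~ 58k-92k)",
    "z = n Rbar^2 can therefore cross the 5% threshold for some causes:",
    "the sinusoidal test picks up any first-harmonic departure, including",
    "pure registration artifacts.\n")
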