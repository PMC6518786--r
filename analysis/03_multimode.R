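#!/usr/bin/env Rscript
# Stage 3 — nonparametric multimode (excess-mass) test per cause.
#
# H0: the time-of-death density has one unique mode. The statistic is the
# excess-mass difference (2 x dip), calibrated by a smoothed bootstrap from
# the KDE at the critical bandwidth. Run on the line (clock values) as the
# primary analysis, with the circular variant as sensitivity.
#
# Reads:  scratch/cohort.csv
# Writes: results/multimode_tests.csv

library(circamort)

cohort <- read_records("scratch/cohort.csv")
causes <- c("cancer", "ischemic_heart_disease", "pneumonia")

rows <- lapply(causes, function(cz) {
  t <- cohort$time_of_day[cohort$cause == cz]
  em <- excess_mass_test(t, n_boot = 500, seed = 42)
  delta_circ <- excess_mass_stat((t + runif(length(t), -0.5, 0.5)) %% 1440,
                                 circular = TRUE)
  tibble::tibble(cause = cz, n = length(t),
                 excess_mass = signif(em$delta, 3),
                 p = signif(em$p, 3), n_boot = em$n_boot,
                 excess_mass_circular = signif(delta_circ, 3))
})
tab <- dplyr::bind_rows(rows)
readr::write_csv(tab, "results/multimode_tests.csv")

print(as.data.frame(tab), row.names = FALSE)
cat("\nExcess-mass values are small (order 0.01) yet the bootstrap can",
    "reject H0: near-flat densities sit at the boundary of unimodality,",
    "where the critical-bandwidth calibration is anti-conservative.\n")
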