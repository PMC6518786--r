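test_that("config invariants are enforced", {
  expect_error(sim_config(10, rho = 0.6), "0.5")
  expect_error(sim_config(10, cause_probs = c(cancer = 0.5, ischemic_heart_disease = 0.5,
                                              pneumonia = 0.1, other = -0.1)), "sum to 1")
  expect_error(sim_config(10, mu = 1500), "1440")
  expect_error(sim_config(10, heap_hours = list(c(6, -1))), "multiplier")
  expect_silent(sim_config(0))
})

test_that("identical seed and config give a bit-identical record stream", {
  cfg <- sim_config(n = 2000, pi_uniform = 0.5, rho = 0.3, seed = 99,
                    heap_hours = list(c(6, 1.5)))
  expect_identical(sample_records(cfg), sample_records(cfg))
  expect_identical(sample_times(cfg), sample_times(cfg))
  cfg2 <- sim_config(n = 2000, pi_uniform = 0.5, rho = 0.3, seed = 100,
                     heap_hours = list(c(6, 1.5)))
  expect_false(identical(sample_times(cfg), sample_times(cfg2)))
})

test_that("n = 0 yields an empty stream", {
  expect_length(sample_times(sim_config(0)), 0)
  expect_equal(nrow(sample_records(sim_config(0))), 0L)
})

test_that("rho = 0 times are marginally uniform (chi-square GOF over 24 bins)", {
  pvals <- vapply(1:40, function(s) {
    t <- sample_times(sim_config(n = 2000, rho = 0, pi_uniform = 0, seed = s))
    counts <- tabulate(t %/% 60L + 1L, nbins = 24L)
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }, 0)
  # rejections at 5% should occur at roughly the nominal rate
  expect_lte(mean(pvals < 0.05), 0.2)
  expect_gt(min(pvals), 0)
})

test_that("cardioid samples have E[cos(theta - mu)] = rho (numeric-integration oracle)", {
  rho <- 0.3
  expect_equal(cardioid_mean_cos(rho), rho, tolerance = 1e-8)
  n <- 20000
  t <- sample_times(sim_config(n = n, rho = rho, pi_uniform = 0, mu = 600, seed = 21))
  th <- 2 * pi * t / 1440
  m <- mean(cos(th - 2 * pi * 600 / 1440))
  se <- sd(cos(th - 2 * pi * 600 / 1440)) / sqrt(n)
  expect_lt(abs(m - rho), 3 * se)
})

test_that("von Mises family concentrates at the acrophase", {
  t <- sample_times(sim_config(n = 10000, rho = 0.6, pi_uniform = 0,
                               family = "von_mises", mu = 360, seed = 8))
  s <- to_angles(t)
  expect_equal(s$Rbar, 0.6, tolerance = 0.03)
  mu_est <- s$mean_direction * 1440 / (2 * pi)
  expect_lt(abs(mu_est - 360), 15)
})

test_that("acrophase is recovered within 15 minutes at rho = 0.4, n = 10000", {
  t <- sample_times(sim_config(n = 10000, rho = 0.4, pi_uniform = 0, mu = 360, seed = 4))
  mu_est <- to_angles(t)$mean_direction * 1440 / (2 * pi)
  expect_lt(abs(mu_est - 360), 15)
})

test_that("demographics follow the per-cause calibration", {
  rec <- sample_records(sim_config(n = 100000, seed = 31))
  shares <- prop.table(table(rec$cause))
  expect_equal(unname(shares["cancer"]), 0.165, tolerance = 0.02)
  expect_equal(unname(shares["pneumonia"]), 0.260, tolerance = 0.02)
  ca <- rec[rec$cause == "cancer", ]
  p_male <- mean(ca$sex == "male")
  se <- sqrt(0.567 * 0.433 / nrow(ca))
  expect_lt(abs(p_male - 0.567), 3 * se)
  expect_true(all(ca$age >= 18 & ca$age <= 108))
  expect_equal(stats::median(ca$age), 70, tolerance = 2)
})

test_that("cause_probs = (1,0,0,0) makes every record cancer", {
  rec <- sample_records(sim_config(n = 200, seed = 3,
                                   cause_probs = c(cancer = 1, ischemic_heart_disease = 0,
                                                   pneumonia = 0, other = 0)))
  expect_true(all(rec$cause == "cancer"))
})

test_that("heaping multiplies hour density by the stated factor (reweighting oracle)", {
  n <- 60000
  t <- sample_times(sim_config(n = n, rho = 0, heap_hours = list(c(6, 1.24)), seed = 13))
  counts <- tabulate(t %/% 60L + 1L, nbins = 24L)
  # reweighted 24-bin multinomial: p6 = 1.24 / (23 + 1.24)
  p6 <- 1.24 / (23 + 1.24)
  se <- sqrt(p6 * (1 - p6) * n)
  expect_lt(abs(counts[7] - n * p6), 4 * se)
  expect_equal(counts[7] / mean(counts[-7]), 1.24, tolerance = 0.08)
})

test_that("pr-structured records carry the designed hour and sex effects", {
  rec <- sample_pr_records(50000, pr_hour = 2, pr_sex = 1, base_prev = 0.1, seed = 5)
  y <- rec$cause == "cancer"
  hr <- rec$time_of_day %/% 60L
  crude <- mean(y[hr == 6]) / mean(y[hr != 6])
  expect_equal(crude, 2, tolerance = 0.2)
})
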