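test_that("with balanced covariates the hour PR is the crude two-sample ratio", {
  rec <- balanced_two_hour_records(p0 = 0.10, p1 = 0.15, m = 200)
  tab <- fit_pr(rec, "cancer")
  i <- match("hour_6", tab$term)
  expect_equal(tab$pr[i], 0.15 / 0.10, tolerance = 1e-8)
  expect_true(all(tab$conf_low <= tab$pr & tab$pr <= tab$conf_high))
  expect_equal(attr(tab, "reference"), "hour_0")
})

test_that("PR = exp(coefficient) and intervals use the robust SE", {
  rec <- sample_pr_records(20000, seed = 3)
  tab <- fit_pr(rec, "cancer")
  expect_equal(tab$pr, exp(tab$coefficient), tolerance = 1e-12)
  expect_equal(tab$conf_high,
               exp(tab$coefficient + qnorm(0.975) * tab$robust_se),
               tolerance = 1e-12)
})

test_that("robust variance matches an independent sandwich computation", {
  rec <- sample_pr_records(5000, seed = 8)
  tab <- fit_pr(rec, "cancer")
  # hand-rolled HC0 sandwich for the Poisson working model
  d <- data.frame(y = as.integer(rec$cause == "cancer"),
                  hour = factor(rec$time_of_day %/% 60L, levels = 0:23),
                  sex = factor(rec$sex, levels = c("female", "male")),
                  age = as.numeric(rec$age))
  fit <- glm(y ~ hour + sex + age, data = d, family = poisson())
  X <- model.matrix(fit)
  mu <- fitted(fit)
  A <- crossprod(X * mu, X)
  B <- crossprod(X * (d$y - mu))
  V <- solve(A) %*% B %*% solve(A)
  se_hand <- sqrt(diag(V))[c("hour6", "sexmale", "age")]
  i <- match(c("hour_6", "sex_male", "age"), tab$term)
  expect_equal(tab$robust_se[i], unname(se_hand), tolerance = 1e-6)
})

test_that("hours without outcome events are merged into the reference with a warning", {
  rec <- sample_pr_records(3000, base_prev = 0.05, seed = 2)
  # remove every cancer death from hour 3 but keep the hour populated
  drop <- rec$cause == "cancer" & rec$time_of_day %/% 60L == 3L
  rec$cause[drop] <- "other"
  expect_warning(tab <- fit_pr(rec, "cancer"), "hour")
  expect_false("hour_3" %in% tab$term)
  expect_true("hour_3" %in% sub("^", "", attr(tab, "dropped")) ||
                "hour_3" %in% attr(tab, "dropped"))
})

test_that("preconditions are enforced", {
  rec <- sample_pr_records(1000, seed = 1)
  expect_error(fit_pr(rec, "typo"), "cause")
  one_hour <- rec[rec$time_of_day %/% 60L == 6L, ]
  expect_error(fit_pr(one_hour, "cancer"), "2 hours")
})

test_that("the aggregate count form recovers the same crude hour effects", {
  rec <- sample_pr_records(40000, pr_hour = 1.5, pr_sex = 1, seed = 12)
  tab <- fit_pr(rec, "cancer", form = "aggregate")
  i <- match("hour_6", tab$term)
  expect_equal(tab$pr[i], 1.5, tolerance = 0.15)
  expect_false("sex_male" %in% tab$term)
})

test_that("pr_report lays out the merged table and plot data", {
  rec <- sample_records(sim_config(30000, seed = 14))
  tabs <- lapply(c("cancer", "ischemic_heart_disease", "pneumonia"),
                 function(cz) fit_pr(rec, cz))
  csv <- withr::local_tempfile(fileext = ".csv")
  json <- withr::local_tempfile(fileext = ".json")
  rep <- pr_report(tabs, csv = csv, json = json)
  expect_equal(nrow(rep), 26L)  # 24 hour rows + sex + age
  expect_equal(rep$cancer[1], "Reference")
  expect_match(rep$cancer[2], "^\\d+\\.\\d+ \\(\\d+\\.\\d+-\\d+\\.\\d+\\)$")
  expect_equal(rep$term[25], "Sex (male versus female)")
  pd <- attr(rep, "plot_data")
  expect_equal(nrow(pd), 72L)
  expect_true(all(pd$pr[pd$hour == 0] == 1))
  expect_true(file.exists(csv) && file.exists(json))
  parsed <- jsonlite::read_json(json)
  expect_equal(names(parsed), c("cancer", "ischemic_heart_disease", "pneumonia"))

  expect_error(pr_report(list()), "no prevalence")
  single <- pr_report(tabs[[1]])
  expect_equal(ncol(single), 2L)
})

test_that("mismatched term sets across causes are an error", {
  rec <- sample_pr_records(4000, base_prev = 0.05, seed = 2)
  drop <- rec$cause == "cancer" & rec$time_of_day %/% 60L == 3L
  rec$cause[drop] <- "other"
  t1 <- suppressWarnings(fit_pr(rec, "cancer"))
  rec$cause[seq_len(300)] <- "pneumonia"
  t2 <- fit_pr(rec, "pneumonia")
  expect_error(pr_report(list(t1, t2)), "mismatched")
})
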