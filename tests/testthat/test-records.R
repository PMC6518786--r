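test_that("rows parse to typed records and bad rows are rejected with reasons", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,cause,age,sex",
               "06:30,cancer,70,male",
               "23:59:59,pneumonia,85,F",
               "2010-03-01 00:00,ischemic_heart_disease,82,female",
               "24:00,cancer,70,male",
               "06:15,cancer,not_an_age,male",
               "nonsense,other,50,female"), f)
  recs <- suppressMessages(read_records(f))
  expect_equal(nrow(recs), 3L)
  expect_equal(recs$time_of_day, c(390L, 1439L, 0L))
  expect_equal(as.character(recs$cause[1]), "cancer")
  expect_equal(recs$age[1], 70L)
  expect_equal(as.character(recs$sex), c("male", "female", "female"))
  expect_equal(attr(recs, "n_rejected"), 3L)
  expect_setequal(attr(recs, "rejections")$reason,
                  c("unparseable or out-of-range time", "unparseable or negative age"))
})

test_that("a missing mandatory column is a hard error naming the column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,cause,age", "06:30,cancer,70"), f)
  expect_error(suppressMessages(read_records(f)), "sex")
})

test_that("schema config remaps columns and category labels", {
  cfg <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# registry extract layout",
               "time: tod", "cause: icd_group", "age: age_y", "sex: gender",
               "cause_map.CA: cancer", "cause_map.IHD: ischemic_heart_disease",
               "sex_map.1: male", "sex_map.2: female"), cfg)
  schema <- read_schema(cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("tod,icd_group,age_y,gender",
               "06:30,CA,70,1", "20:05,IHD,82,2", "10:00,ZZZ,90,1"), f)
  recs <- suppressMessages(read_records(f, schema))
  expect_equal(as.character(recs$cause), c("cancer", "ischemic_heart_disease", "other"))
  expect_equal(as.character(recs$sex), c("male", "female", "male"))
})

test_that("the bundled example extract loads through its schema config", {
  schema <- read_schema(system.file("extdata", "example_schema.cfg",
                                    package = "circamort"))
  recs <- suppressMessages(
    read_records(system.file("extdata", "example_deaths.csv",
                             package = "circamort"), schema))
  expect_equal(nrow(recs), 14L)
  expect_equal(attr(recs, "n_rejected"), 0L)
  expect_equal(sum(recs$cause == "cancer"), 4L)
  expect_equal(recs$time_of_day[1], 12L)
})

test_that("write then read round-trips all typed fields", {
  rec <- sample_records(sim_config(n = 500, seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  write_records(rec, f)
  r2 <- suppressMessages(read_records(f, record_schema(race = "race")))
  expect_identical(rec$time_of_day, r2$time_of_day)
  expect_identical(rec$cause, r2$cause)
  expect_identical(rec$age, r2$age)
  expect_identical(rec$sex, r2$sex)
  expect_identical(rec$race, r2$race)
})

test_that("implausible ages warn but records are kept", {
  expect_warning(r <- death_records(10L, "cancer", 130L, "male"), "plausible")
  expect_equal(nrow(r), 1L)
})

test_that("hour bins are half-open and totals conserved", {
  rec <- death_records(c(0L, 59L, 60L), rep("cancer", 3), c(70L, 71L, 72L),
                       rep("male", 3))
  hc <- aggregate_counts(rec, "hour")
  expect_equal(hc$deaths[1:2], c(2L, 1L))
  expect_equal(sum(hc$deaths), 3L)

  rec2 <- sample_records(sim_config(n = 777, seed = 2))
  expect_equal(sum(aggregate_counts(rec2, "hour")$deaths), 777L)
  expect_equal(sum(aggregate_counts(rec2, "minute")$deaths), 777L)
})

test_that("one record per minute fills every hourly bin with 60", {
  rec <- death_records(0:1439, rep("other", 1440), rep(70L, 1440),
                       rep("female", 1440))
  hc <- aggregate_counts(rec, "hour")
  expect_equal(hc$deaths, rep(60L, 24))
})

test_that("minute aggregation re-binned by 60 equals the hourly aggregate", {
  rec <- sample_records(sim_config(n = 3000, pi_uniform = 0, rho = 0.4, seed = 5))
  mc <- aggregate_counts(rec, "minute")
  hc <- aggregate_counts(rec, "hour")
  rebin <- tapply(mc$deaths, mc$minute %/% 60L, sum)
  expect_equal(as.vector(rebin), hc$deaths)
})

test_that("empty selections give zero counts, not errors", {
  rec <- death_records(10L, "cancer", 70L, "male")
  hc <- aggregate_counts(rec, "hour", cause = "pneumonia")
  expect_equal(sum(hc$deaths), 0L)
  expect_equal(attr(hc, "n"), 0L)
})
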