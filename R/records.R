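#' Column schema for death-record tables
#'
#' The reader is schema-configurable because registry extracts differ in
#' column naming and category labels. A schema maps the input columns onto
#' the canonical record fields (`time_of_day`, `cause`, `age`, `sex`,
#' optionally `race`) and recodes cause/sex labels onto the canonical
#' categories.
#'
#' @param time,cause,age,sex,race Input column names. `race = NULL` (the
#'   default) means no race column is read.
#' @param cause_map Named character vector mapping raw cause labels to the
#'   canonical categories `r paste(CAUSE_LEVELS, collapse = ", ")`. Raw
#'   labels absent from the map fall through to `unmapped_cause`.
#' @param unmapped_cause Category assigned to cause labels not covered by
#'   `cause_map` (default `"other"`); set to `NA` to reject such rows.
#' @param sex_map Named character vector mapping raw sex labels (matched in
#'   lower case) to `"male"`/`"female"`.
#' @param age_range Plausible age range in years; ages outside it raise a
#'   warning but the rows are kept (registry maxima reach 117).
#' @return A list of class `record_schema`.
#' @export
record_schema <- function(time = "time", cause = "cause", age = "age",
                          sex = "sex", race = NULL,
                          cause_map = NULL, unmapped_cause = "other",
                          sex_map = c(male = "male", m = "male", female = "female", f = "female"),
                          age_range = c(0, 120)) {
  if (!is.na(unmapped_cause) && !unmapped_cause %in% CAUSE_LEVELS)
    abort("`unmapped_cause` must be one of the canonical categories or NA")
  structure(list(time = time, cause = cause, age = age, sex = sex,
                 race = race, cause_map = cause_map,
                 unmapped_cause = unmapped_cause, sex_map = sex_map,
                 age_range = age_range),
            class = "record_schema")
}

#' Read a schema from a plain-text key-value config file
#'
#' Lines have the form `key: value` (or `key = value`). Recognised keys are
#' the column names (`time`, `cause`, `age`, `sex`, `race`), `unmapped_cause`,
#' `age_range` (two comma-separated numbers), and dotted map entries
#' `cause_map.<raw> : <canonical>` and `sex_map.<raw> : <male|female>`.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the config file.
#' @return A `record_schema`.
#' @export
read_schema <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^([^:=]+)[:=](.*)$", lines))
  bad <- lengths(m) != 3L
  if (any(bad)) abort(paste0("unparseable config line: ", lines[bad][1]))
  keys <- trimws(vapply(m, `[`, "", 2))
  vals <- trimws(vapply(m, `[`, "", 3))
  args <- list()
  cause_map <- character()
  sex_map <- c(male = "male", m = "male", female = "female", f = "female")
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "cause_map.")) {
      cause_map[sub("^cause_map\\.", "", k)] <- v
    } else if (startsWith(k, "sex_map.")) {
      sex_map[tolower(sub("^sex_map\\.", "", k))] <- v
    } else if (k == "age_range") {
      args$age_range <- as.numeric(strsplit(v, ",")[[1]])
    } else if (k %in% c("time", "cause", "age", "sex", "race", "unmapped_cause")) {
      args[[k]] <- v
    } else {
      abort(paste0("unknown schema key: ", k))
    }
  }
  if (length(cause_map)) args$cause_map <- cause_map
  args$sex_map <- sex_map
  do.call(record_schema, args)
}

# Parse clock times given as HH:MM, HH:MM:SS or full ISO date-times (the
# date part is discarded). Returns integer minutes since midnight, NA where
# unparseable or out of [0, 1440).
parse_time_of_day <- function(x) {
  x <- trimws(as.character(x))
  pat <- "^(?:\\d{4}-\\d{2}-\\d{2}[ T])?(\\d{1,2}):(\\d{2})(?::(\\d{2}(?:\\.\\d+)?))?$"
  m <- regmatches(x, regexec(pat, x))
  hh <- vapply(m, function(g) if (length(g) == 4L) as.numeric(g[2]) else NA_real_, 0)
  mm <- vapply(m, function(g) if (length(g) == 4L) as.numeric(g[3]) else NA_real_, 0)
  out <- ifelse(!is.na(hh) & !is.na(mm) & hh < 24 & mm < 60,
                hh * 60 + mm, NA_real_)
  as.integer(out)
}

#' Construct a validated death-record table
#'
#' @param time_of_day Integer minutes since midnight in `[0, 1440)`.
#' @param cause Cause category (one of `r paste(CAUSE_LEVELS, collapse = ", ")`).
#' @param age Age in whole years, non-negative.
#' @param sex `"male"` or `"female"`.
#' @param race Optional character vector.
#' @param age_range Plausible age range; values outside warn.
#' @return A tibble with one row per death, columns `time_of_day` (integer
#'   minutes), `cause` and `sex` (factors), `age` (integer), and `race` if
#'   supplied.
#' @export
death_records <- function(time_of_day, cause, age, sex, race = NULL,
                          age_range = c(0, 120)) {
  time_of_day <- as.integer(time_of_day)
  if (anyNA(time_of_day) || any(time_of_day < 0L | time_of_day >= MINUTES_PER_DAY))
    abort("`time_of_day` must be integer minutes in [0, 1440)")
  if (!all(cause %in% CAUSE_LEVELS)) abort("unknown cause category")
  if (!all(sex %in% SEX_LEVELS)) abort("`sex` must be 'male' or 'female'")
  age <- as.integer(age)
  if (anyNA(age) || any(age < 0L)) abort("`age` must be non-negative years")
  n_out <- sum(age < age_range[1] | age > age_range[2])
  if (n_out > 0)
    warn(paste0(n_out, " record(s) with age outside the plausible range [",
                age_range[1], ", ", age_range[2], "]"))
  out <- tibble::tibble(
    time_of_day = time_of_day,
    cause = factor(cause, levels = CAUSE_LEVELS),
    age = age,
    sex = factor(sex, levels = SEX_LEVELS))
  if (!is.null(race)) out$race <- as.character(race)
  out
}

#' Read death records from a delimited text file
#'
#' Each input row becomes one validated record or is rejected with a logged
#' reason; rejected rows are counted and reported, never imputed. Per-stage
#' record counts are logged to stderr.
#'
#' @param path Path to a CSV file with a header.
#' @param schema A [record_schema()] mapping columns and category labels.
#' @return A record tibble (see [death_records()]) with attributes
#'   `n_rejected` (count) and `rejections` (a tibble of reasons).
#' @export
read_records <- function(path, schema = record_schema()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c(schema$time, schema$cause, schema$age, schema$sex)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    abort(paste0("mandatory column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")))

  tod <- parse_time_of_day(raw[[schema$time]])
  age <- suppressWarnings(as.integer(raw[[schema$age]]))
  sex_raw <- tolower(trimws(raw[[schema$sex]]))
  sex <- unname(schema$sex_map[sex_raw])
  cause_raw <- trimws(raw[[schema$cause]])
  if (is.null(schema$cause_map)) {
    cause <- ifelse(cause_raw %in% CAUSE_LEVELS, cause_raw, NA_character_)
    if (!is.na(schema$unmapped_cause)) cause[is.na(cause)] <- schema$unmapped_cause
  } else {
    cause <- unname(schema$cause_map[cause_raw])
    cause[cause_raw %in% CAUSE_LEVELS & is.na(cause)] <-
      cause_raw[cause_raw %in% CAUSE_LEVELS & is.na(cause)]
    if (!is.na(schema$unmapped_cause)) cause[is.na(cause)] <- schema$unmapped_cause
  }

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(cause)] <- "unmapped cause"
  reason[is.na(sex)] <- "unparseable sex"
  reason[is.na(age) | (!is.na(age) & age < 0)] <- "unparseable or negative age"
  reason[is.na(tod)] <- "unparseable or out-of-range time"
  ok <- is.na(reason)

  rejections <- tibble::tibble(reason = reason[!ok])
  rejections <- dplyr::count(rejections, .data$reason, name = "n")
  if (nrow(rejections))
    inform(paste0("read_records: rejected ", sum(!ok), " of ", nrow(raw),
                  " row(s): ",
                  paste0(rejections$reason, " (", rejections$n, ")", collapse = "; ")))
  inform(paste0("read_records: ", sum(ok), " record(s) accepted from ", path))

  recs <- death_records(tod[ok], cause[ok], age[ok], sex[ok],
                        race = if (!is.null(schema$race) && schema$race %in% names(raw))
                          raw[[schema$race]][ok],
                        age_range = schema$age_range)
  attr(recs, "n_rejected") <- sum(!ok)
  attr(recs, "rejections") <- rejections
  recs
}

#' Write death records to CSV
#'
#' Times are written as `HH:MM`; a subsequent [read_records()] with the
#' default schema round-trips all typed fields.
#'
#' @param records A record tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- tibble::tibble(
    time = sprintf("%02d:%02d", records$time_of_day %/% 60L,
                   records$time_of_day %% 60L),
    cause = as.character(records$cause),
    age = records$age,
    sex = as.character(records$sex))
  if ("race" %in% names(records)) out$race <- records$race
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Aggregate death records to hourly or minute counts
#'
#' Hour bins are half-open clock intervals `[h:00, h+1:00)`: a death at
#' exactly `h:00` belongs to bin `h`. Totals are conserved; an empty
#' selection yields all-zero counts with `n = 0`.
#'
#' @param records A record tibble.
#' @param resolution `"hour"` (24 bins) or `"minute"` (1440 bins).
#' @param cause Optional cause filter (one canonical category).
#' @return A tibble with columns `hour` (0-23) or `minute` (0-1439) and
#'   `deaths`, with attributes `n` (total) and `cause`.
#' @export
aggregate_counts <- function(records, resolution = c("hour", "minute"),
                             cause = NULL) {
  resolution <- match.arg(resolution)
  if (!is.null(cause)) {
    if (!cause %in% CAUSE_LEVELS) abort("unknown cause category")
    records <- records[records$cause == cause, , drop = FALSE]
  }
  if (resolution == "hour") {
    bins <- 0:23
    idx <- records$time_of_day %/% 60L
    out <- tibble::tibble(hour = bins,
                          deaths = tabulate(idx + 1L, nbins = 24L))
  } else {
    bins <- 0:(MINUTES_PER_DAY - 1L)
    out <- tibble::tibble(minute = bins,
                          deaths = tabulate(records$time_of_day + 1L,
                                            nbins = MINUTES_PER_DAY))
  }
  attr(out, "n") <- nrow(records)
  attr(out, "cause") <- cause %||% "all"
  out
}
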