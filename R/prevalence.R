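# Table-2-style row label for an hour bin, 12-hour clock.
hour_label <- function(h) {
  h12 <- ifelse(h %% 12 == 0, ifelse(h %% 24 < 12, 0, 12), h %% 12)
  ampm <- ifelse(h < 12, "am", "pm")
  sprintf("During %d:00-%d:59 %s", h12, h12, ampm)
}

#' Prevalence ratios of cause-specific death by hour, age, and sex
#'
#' Estimates adjusted prevalence ratios (PRs) of dying of a given cause —
#' rather than any other cause — by hour of day, sex, and age, across all
#' death records. The default is the modified-Poisson prevalence-ratio
#' estimator: a log-link Poisson working model for the binary outcome
#' `Y = 1{cause}` with 23 hour dummies (reference 0:00-0:59), a male
#' indicator, and linear age, paired with a heteroskedasticity-robust (HC0
#' sandwich) covariance. `PR = exp(beta)` with 95% Wald intervals
#' `exp(beta +/- 1.96 SE)`.
#'
#' Hours in which no outcome events occur cannot identify their dummy
#' (the log-PR diverges); such terms are dropped — the hour is merged into
#' the reference — with a logged warning.
#'
#' An alternative reading of the same estimand is available with
#' `form = "aggregate"`: a Poisson log-linear model of per-hour
#' cause-specific counts with the per-hour all-cause total as offset
#' (no age/sex adjustment, since individual covariates are aggregated
#' away). That model is saturated — one count per hour cell — so its
#' intervals use the classical Poisson covariance; the `robust_se` column
#' then holds the model-based SE.
#'
#' @param records A record tibble covering all causes of death.
#' @param cause Index cause (one canonical category).
#' @param form `"individual"` (default, modified Poisson on records) or
#'   `"aggregate"` (count model on hourly totals).
#' @param conf_level Confidence level for the Wald intervals.
#' @return A tibble of class `pr_table`, one row per model term (`hour_1` ..
#'   `hour_23`, `sex_male`, `age`), with columns `term`, `coefficient`,
#'   `robust_se`, `pr`, `conf_low`, `conf_high`, and attributes `cause`,
#'   `n`, `form`, `reference` (`"hour_0"`), and `dropped` (merged hour
#'   terms, if any). No multiplicity adjustment is applied across the 23
#'   simultaneous hour contrasts.
#' @export
fit_pr <- function(records, cause, form = c("individual", "aggregate"),
                   conf_level = 0.95) {
  form <- match.arg(form)
  if (!cause %in% CAUSE_LEVELS) abort("unknown cause category")
  if (!any(records$cause == cause)) abort(paste0("no records with cause ", cause))
  zcrit <- qnorm(1 - (1 - conf_level) / 2)

  if (form == "aggregate") {
    tot <- aggregate_counts(records, "hour")
    cz <- aggregate_counts(records, "hour", cause = cause)
    d <- tibble::tibble(y = cz$deaths, hour = factor(tot$hour, levels = 0:23),
                        tot = tot$deaths)
    d <- d[d$tot > 0, ]
    d$hour <- droplevels(d$hour)
    if (!"0" %in% levels(d$hour)) abort("reference hour 0 has no records")
    fit <- glm(y ~ hour, data = d, family = poisson(), offset = log(d$tot))
    if (!fit$converged) abort("aggregate count model did not converge")
    # with one count per hour cell the model is saturated, so a sandwich
    # estimator degenerates; use the classical Poisson covariance
    V <- vcov(fit)
    hrs <- setdiff(levels(d$hour), "0")
    terms <- paste0("hour", hrs)
    out_terms <- paste0("hour_", hrs)
  } else {
    if (length(unique(records$time_of_day %/% 60L)) < 2)
      abort("records must span at least 2 hours")
    if (length(unique(records$sex)) < 2)
      abort("records must include both sexes")
    d <- tibble::tibble(
      y = as.integer(records$cause == cause),
      hour = factor(records$time_of_day %/% 60L, levels = 0:23),
      sex = factor(records$sex, levels = c("female", "male")),
      age = as.numeric(records$age))
    d$hour <- droplevels(d$hour)  # hours with no records carry no term
    # hours with records but no outcome events cannot identify a log-PR:
    # merge into the reference and log it
    ev <- tapply(d$y, d$hour, sum, default = 0)
    dead_hours <- as.integer(names(ev)[ev == 0 & as.integer(names(ev)) != 0])
    if (length(dead_hours)) {
      warn(paste0("no ", cause, " deaths in hour(s) ",
                  paste(dead_hours, collapse = ", "),
                  "; term(s) dropped (merged into the reference hour)"))
      levs <- levels(d$hour)
      levs[levs %in% as.character(dead_hours)] <- "0"
      levels(d$hour) <- levs
    }
    d$hour <- droplevels(d$hour)
    fit <- glm(y ~ hour + sex + age, data = d, family = poisson())
    if (!fit$converged) abort("prevalence-ratio model did not converge")
    V <- sandwich::vcovHC(fit, type = "HC0")
    hrs <- setdiff(levels(d$hour), "0")
    terms <- c(paste0("hour", hrs), "sexmale", "age")
    out_terms <- c(paste0("hour_", hrs), "sex_male", "age")
  }

  b <- coef(fit)[terms]
  se <- sqrt(diag(V)[terms])
  out <- tibble::tibble(
    term = out_terms,
    coefficient = unname(b),
    robust_se = unname(se),
    pr = exp(unname(b)),
    conf_low = exp(unname(b) - zcrit * unname(se)),
    conf_high = exp(unname(b) + zcrit * unname(se)))
  class(out) <- c("pr_table", class(out))
  attr(out, "cause") <- cause
  attr(out, "n") <- nrow(records)
  attr(out, "form") <- form
  attr(out, "reference") <- "hour_0"
  attr(out, "dropped") <- if (form == "individual" && length(dead_hours))
    paste0("hour_", dead_hours) else character(0)
  out
}

#' Merge per-cause prevalence-ratio tables into a report
#'
#' Lays out one column per cause in the familiar hour/sex/age table shape:
#' a 24-row hour block (the reference hour rendered "Reference"), then the
#' sex and age rows, each cell formatted `PR (low-high)`. Optionally writes
#' CSV and JSON copies.
#'
#' @param tables A named list of `pr_table` objects (names are causes), or a
#'   single `pr_table`.
#' @param csv,json Optional output paths.
#' @return A tibble in report layout with attribute `plot_data`: a long
#'   tibble (`cause`, `hour`, `pr`, `conf_low`, `conf_high`) of the per-hour
#'   PRs, reference hour included at PR 1.
#' @export
pr_report <- function(tables, csv = NULL, json = NULL) {
  if (inherits(tables, "pr_table")) tables <- list(tables)
  if (length(tables) == 0L) abort("no prevalence-ratio tables supplied")
  causes <- vapply(tables, function(t) attr(t, "cause"), "")
  names(tables) <- causes
  term_sets <- lapply(tables, function(t) t$term)
  if (length(unique(lapply(term_sets, sort))) != 1L)
    abort("prevalence-ratio tables have mismatched term sets")

  fmt <- function(t, term) {
    i <- match(term, t$term)
    if (is.na(i)) return("Reference")
    sprintf("%.2f (%.2f-%.2f)", t$pr[i], t$conf_low[i], t$conf_high[i])
  }
  has_sex <- "sex_male" %in% term_sets[[1]]
  rows <- c(paste0("hour_", 0:23), if (has_sex) c("sex_male", "age"))
  labels <- c(hour_label(0:23),
              if (has_sex) c("Sex (male versus female)", "Age (per 1 year increment)"))
  out <- tibble::tibble(term = labels)
  for (cz in causes) {
    vals <- vapply(rows, function(tm)
      if (tm == "hour_0") "Reference" else fmt(tables[[cz]], tm), "")
    out[[cz]] <- unname(vals)
  }

  plot_data <- dplyr::bind_rows(lapply(causes, function(cz) {
    t <- tables[[cz]]
    hr <- t[grepl("^hour_", t$term), ]
    tibble::tibble(cause = cz,
                   hour = c(0L, as.integer(sub("hour_", "", hr$term))),
                   pr = c(1, hr$pr),
                   conf_low = c(1, hr$conf_low),
                   conf_high = c(1, hr$conf_high))
  }))
  attr(out, "plot_data") <- plot_data

  if (!is.null(csv)) readr::write_csv(out, csv, progress = FALSE)
  if (!is.null(json)) {
    payload <- lapply(tables, function(t)
      list(cause = attr(t, "cause"), n = attr(t, "n"), form = attr(t, "form"),
           reference = attr(t, "reference"),
           terms = as.list(tibble::as_tibble(t))))
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
  }
  out
}
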