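#' Configuration for the synthetic death-record generator
#'
#' The generator draws minute-resolution times of day from a two-component
#' mixture: with probability `pi_uniform` a time is uniform on the day, and
#' otherwise it comes from a unimodal circular density centred at the
#' acrophase `mu`. The default rhythmic family is the cardioid
#' `f(theta) = (1/2pi) (1 + 2 rho cos(theta - mu))`, whose density is
#' exactly a sinusoid — the shape a sinusoidal circadian test targets; the
#' von Mises family is available for sharper peaks. Cause, age and sex are
#' then assigned per record from registry-calibrated defaults, and optional
#' count heaping at specified clock hours mimics registration artifacts
#' such as nursing shift changes.
#'
#' @param n Number of records to generate.
#' @param rho Concentration of the rhythmic component, expressed as its mean
#'   resultant length. Must lie in `[0, 0.5]` for the cardioid family
#'   (density non-negativity); for the von Mises family any value in
#'   `[0, 1)` is accepted and converted internally to the concentration
#'   parameter kappa.
#' @param mu Acrophase, minutes since midnight in `[0, 1440)`. Default 360
#'   (06:00), the morning peak classically reported for cardiac events.
#' @param pi_uniform Mixing weight of the uniform component in `[0, 1]`.
#'   Default 1: pure uniform times, the arrhythmic regime.
#' @param family `"cardioid"` or `"von_mises"`.
#' @param cause_probs Probabilities over the four cause categories, summing
#'   to 1. Defaults are the registry shares 16.5% cancer, 6.1% ischemic
#'   heart disease, 26.0% pneumonia, remainder other.
#' @param age_params Per-cause age model: a list with entries
#'   `c(mean, sd, lo, hi)` of a truncated normal in years.
#' @param sex_probs Per-cause probability that a record is male.
#' @param race_probs Per-cause probability that a record is Chinese (the
#'   registry's dominant category); records otherwise get `"other"`.
#' @param heap_hours Optional registration-artifact spec: a two-column
#'   matrix-like of `(hour, multiplier)` pairs, `multiplier > 0`. The time
#'   density within each listed hour is multiplied by its factor (relative
#'   to unlisted hours) via rejection reweighting.
#' @param seed Integer seed; one global seed drives the whole record stream
#'   through deterministically derived per-stage sub-seeds.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n,
                       rho = 0.3, mu = 360, pi_uniform = 1,
                       family = c("cardioid", "von_mises"),
                       cause_probs = c(cancer = 0.165,
                                       ischemic_heart_disease = 0.061,
                                       pneumonia = 0.260,
                                       other = 0.514),
                       age_params = list(
                         cancer = c(mean = 70, sd = 15, lo = 18, hi = 108),
                         ischemic_heart_disease = c(mean = 82, sd = 13, lo = 19, hi = 113),
                         pneumonia = c(mean = 85, sd = 12, lo = 18, hi = 117),
                         other = c(mean = 75, sd = 18, lo = 0, hi = 120)),
                       sex_probs = c(cancer = 0.567,
                                     ischemic_heart_disease = 0.520,
                                     pneumonia = 0.560,
                                     other = 0.550),
                       race_probs = c(cancer = 0.978,
                                      ischemic_heart_disease = 0.962,
                                      pneumonia = 0.977,
                                      other = 0.970),
                       heap_hours = NULL,
                       seed = 1L) {
  family <- match.arg(family)
  if (n < 0) abort("`n` must be non-negative")
  if (family == "cardioid" && (rho < 0 || rho > 0.5))
    abort("cardioid concentration `rho` must lie in [0, 0.5]")
  if (family == "von_mises" && (rho < 0 || rho >= 1))
    abort("von Mises mean resultant length `rho` must lie in [0, 1)")
  if (mu < 0 || mu >= MINUTES_PER_DAY) abort("`mu` must be in [0, 1440)")
  if (pi_uniform < 0 || pi_uniform > 1) abort("`pi_uniform` must be in [0, 1]")
  if (any(cause_probs < 0) || abs(sum(cause_probs) - 1) > 1e-12)
    abort("`cause_probs` must be non-negative and sum to 1")
  if (!identical(names(cause_probs), CAUSE_LEVELS))
    abort("`cause_probs` must be named by the four canonical causes, in order")
  if (!is.null(heap_hours)) {
    heap_hours <- matrix(as.numeric(unlist(heap_hours)), ncol = 2,
                         byrow = is.list(heap_hours))
    if (any(heap_hours[, 1] < 0 | heap_hours[, 1] > 23) ||
        any(heap_hours[, 2] <= 0))
      abort("`heap_hours` needs hours in 0..23 and multipliers > 0")
  }
  structure(list(n = as.integer(n), rho = rho, mu = mu,
                 pi_uniform = pi_uniform, family = family,
                 cause_probs = cause_probs, age_params = age_params,
                 sex_probs = sex_probs, race_probs = race_probs,
                 heap_hours = heap_hours, seed = as.integer(seed)),
            class = "sim_config")
}

# von Mises kappa with mean resultant length rho: solves A1(kappa) = rho,
# A1 = I1/I0 (Bessel ratio).
vm_kappa <- function(rho) {
  if (rho == 0) return(0)
  A1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  stats::uniroot(function(k) A1(k) - rho, c(1e-8, 1e4), tol = 1e-10)$root
}

# Cardioid draws by rejection from a uniform proposal; acceptance
# probability (1 + 2 rho cos(theta - mu)) / (1 + 2 rho).
rcardioid <- function(n, rho, mu_rad) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.2 * (n - length(out)) * (1 + 2 * rho)))
    th <- runif(m, 0, 2 * pi)
    acc <- runif(m) < (1 + 2 * rho * cos(th - mu_rad)) / (1 + 2 * rho)
    out <- c(out, th[acc])
  }
  out[seq_len(n)]
}

# von Mises draws via the Best-Fisher (1979) wrapped-Cauchy rejection
# envelope.
rvonmises <- function(n, kappa, mu_rad) {
  if (kappa < 1e-9) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      i <- i + 1L
      out[i] <- (mu_rad + sign(u3 - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

# Raw mixture draws in minutes (continuous scale floored to integer minutes).
draw_minutes <- function(n, config) {
  if (n == 0L) return(integer(0))
  from_unif <- runif(n) < config$pi_uniform
  mins <- numeric(n)
  mins[from_unif] <- runif(sum(from_unif), 0, MINUTES_PER_DAY)
  n_rhythm <- sum(!from_unif)
  if (n_rhythm > 0) {
    mu_rad <- 2 * pi * config$mu / MINUTES_PER_DAY
    th <- if (config$family == "cardioid")
      rcardioid(n_rhythm, config$rho, mu_rad)
    else
      rvonmises(n_rhythm, vm_kappa(config$rho), mu_rad)
    mins[!from_unif] <- th * MINUTES_PER_DAY / (2 * pi)
  }
  as.integer(floor(mins)) %% MINUTES_PER_DAY
}

# Rejection reweighting of times into heaped hours: the marginal density is
# multiplied, hour-wise, by the listed factors (1 elsewhere).
apply_heaping <- function(draw, n, config) {
  mult <- rep(1, 24)
  mult[config$heap_hours[, 1] + 1] <- config$heap_hours[, 2]
  mmax <- max(mult)
  out <- integer(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.2 * (n - length(out)) * mmax))
    t <- draw(m)
    keep <- runif(m) < mult[t %/% 60L + 1L] / mmax
    out <- c(out, t[keep])
  }
  out[seq_len(n)]
}

#' Draw synthetic times of death
#'
#' Returns `n` integer minutes since midnight from the configured
#' uniform/rhythmic mixture, with heaping applied when `heap_hours` is set.
#' Identical seed and config give an identical stream.
#'
#' @param config A [sim_config()].
#' @return Integer vector of minutes in `[0, 1440)`.
#' @export
sample_times <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "times"))
  if (is.null(config$heap_hours)) {
    draw_minutes(config$n, config)
  } else {
    apply_heaping(function(m) draw_minutes(m, config), config$n, config)
  }
}

# Truncated-normal ages in whole years.
rage <- function(n, par) {
  if (n == 0L) return(integer(0))
  plo <- pnorm(par[["lo"]], par[["mean"]], par[["sd"]])
  phi <- pnorm(par[["hi"]], par[["mean"]], par[["sd"]])
  a <- qnorm(runif(n, plo, phi), par[["mean"]], par[["sd"]])
  as.integer(pmin(pmax(round(a), par[["lo"]]), par[["hi"]]))
}

#' Generate a synthetic death-record table
#'
#' Times come from [sample_times()]; each record is then assigned a cause by
#' `cause_probs`, an age from the per-cause truncated normal, a sex from the
#' per-cause male share, and a race category. Defaults are calibrated to the
#' Hong Kong hospital registry demographics the pipeline was built around.
#'
#' @param config A [sim_config()].
#' @return A record tibble (see [death_records()]).
#' @export
sample_records <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tod <- sample_times(config)
  n <- config$n
  set.seed(stage_seed(config$seed, "demographics"))
  cause <- sample(CAUSE_LEVELS, n, replace = TRUE, prob = config$cause_probs)
  age <- integer(n)
  sex <- character(n)
  race <- character(n)
  for (cz in CAUSE_LEVELS) {
    idx <- which(cause == cz)
    age[idx] <- rage(length(idx), config$age_params[[cz]])
    sex[idx] <- ifelse(rbinom(length(idx), 1, config$sex_probs[[cz]]) == 1,
                       "male", "female")
    race[idx] <- ifelse(rbinom(length(idx), 1, config$race_probs[[cz]]) == 1,
                        "chinese", "other")
  }
  if (n == 0L)
    return(death_records(integer(0), character(0), integer(0), character(0),
                         race = character(0)))
  death_records(tod, cause, age, sex, race = race)
}

#' Synthetic records with a known prevalence-ratio structure
#'
#' A testbed for the prevalence-ratio regression: the probability that a
#' death is of the index cause follows the log-linear model
#' `log P(Y=1) = log(base_prev) + log(pr_hour) 1\{hour = peak_hour\} +
#' log(pr_sex) 1\{male\}`, with uniform times, balanced sex, and an age
#' column drawn independently of the outcome (true age PR 1 per year).
#'
#' @param n Number of records.
#' @param pr_hour True prevalence ratio at `peak_hour` versus other hours.
#' @param peak_hour Hour (0-23) carrying the elevated prevalence.
#' @param pr_sex True male-versus-female prevalence ratio.
#' @param base_prev Baseline prevalence (female, off-peak hour).
#' @param cause Index cause label assigned when the outcome fires.
#' @param seed Integer seed.
#' @return A record tibble; records not of the index cause get cause
#'   `"other"`.
#' @export
sample_pr_records <- function(n, pr_hour = 1.25, peak_hour = 6, pr_sex = 1.3,
                              base_prev = 0.1, cause = "cancer", seed = 1L) {
  pmax_ <- base_prev * pr_hour * pr_sex
  if (pmax_ > 1) abort("base_prev * pr_hour * pr_sex must not exceed 1")
  set.seed(stage_seed(seed, "pr_records"))
  tod <- as.integer(floor(runif(n, 0, MINUTES_PER_DAY)))
  male <- rbinom(n, 1, 0.5)
  p <- base_prev * pr_hour^((tod %/% 60L) == peak_hour) * pr_sex^male
  y <- rbinom(n, 1, p)
  age <- as.integer(pmin(pmax(round(rnorm(n, 75, 12)), 18), 110))
  death_records(tod, ifelse(y == 1, cause, "other"), age,
                ifelse(male == 1, "male", "female"))
}
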