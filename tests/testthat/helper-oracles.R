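# Independent oracles used across the suite.

# Upper envelope of lines value(l) = intercept + slope * l; returns the
# breakpoints of the envelope (convex-hull-trick construction).
envelope_breaks <- function(slope, intercept) {
  o <- order(slope, -intercept)
  slope <- slope[o]; intercept <- intercept[o]
  keep <- !duplicated(slope)
  slope <- slope[keep]; intercept <- intercept[keep]
  hs <- hi <- hx <- numeric(0)
  for (i in seq_along(slope)) {
    repeat {
      m <- length(hs)
      if (m == 0L) { x <- -Inf; break }
      x <- (hi[m] - intercept[i]) / (slope[i] - hs[m])
      if (x <= hx[m]) { hs <- hs[-m]; hi <- hi[-m]; hx <- hx[-m] } else break
    }
    hs <- c(hs, slope[i]); hi <- c(hi, intercept[i]); hx <- c(hx, x)
  }
  hx[is.finite(hx)]
}

# Brute-force excess mass: max over lambda > 0 of E2(lambda) - E1(lambda),
# by direct optimization over all intervals with endpoints at data points
# and lambda on the breakpoints of the two upper envelopes. Exact for small
# n; completely independent of the dip algorithm.
excess_mass_brute <- function(x) {
  v <- sort(unique(x))
  m <- length(v)
  p <- len <- numeric(0); lo <- hi <- integer(0)
  for (i in seq_len(m)) for (j in i:m) {
    p <- c(p, mean(x >= v[i] & x <= v[j]))
    len <- c(len, v[j] - v[i])
    lo <- c(lo, i); hi <- c(hi, j)
  }
  b1 <- envelope_breaks(-len, p)
  p2 <- len2 <- numeric(0)
  for (a in seq_along(p)) for (b in seq_along(p)) {
    if (hi[a] < lo[b]) { p2 <- c(p2, p[a] + p[b]); len2 <- c(len2, len[a] + len[b]) }
  }
  if (length(p2) == 0L) return(0)
  b2 <- envelope_breaks(-len2, p2)
  lam <- sort(unique(c(b1, b2)))
  lam <- lam[lam > 0]
  lam <- c(1e-9, lam, if (length(lam)) max(lam) + 1 else 1)
  E1 <- vapply(lam, function(l) max(p - l * len), 0)
  E2 <- vapply(lam, function(l) max(p2 - l * len2), 0)
  max(E2 - E1)
}

# Mean of cos(theta - mu) under the cardioid by numeric integration.
cardioid_mean_cos <- function(rho) {
  stats::integrate(function(t) cos(t) * (1 + 2 * rho * cos(t)) / (2 * pi),
                   0, 2 * pi, rel.tol = 1e-10)$value
}

# Small balanced record table with outcome prevalence depending on hour
# only; every (hour, sex, age) cell gets the same size and the same exact
# event fraction, so the crude two-sample prevalence ratio is the truth.
balanced_two_hour_records <- function(p0, p1, m = 200) {
  stopifnot((p0 * m) %% 1 == 0, (p1 * m) %% 1 == 0)
  cells <- expand.grid(hour = c(0L, 6L), sex = c("male", "female"),
                       age = c(60L, 80L), stringsAsFactors = FALSE)
  recs <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    h <- cells$hour[i]
    k <- round(ifelse(h == 0L, p0, p1) * m)
    data.frame(time_of_day = h * 60L + seq_len(m) %% 60L,
               cause = c(rep("cancer", k), rep("other", m - k)),
               age = cells$age[i], sex = cells$sex[i])
  }))
  death_records(recs$time_of_day, recs$cause, recs$age, recs$sex)
}
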