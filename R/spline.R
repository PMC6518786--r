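#' Restricted cubic spline basis with three knots
#'
#' Builds the design columns `[1, x, s(x)]` of a restricted (natural) cubic
#' spline: piecewise cubic between the knots, constrained to be linear
#' beyond the boundary knots. With three knots `t1 < t2 < t3` there is a
#' single restricted term,
#' `s(x) = [(x-t1)^3_+ - (x-t2)^3_+ (t3-t1)/(t3-t2) +
#'          (x-t3)^3_+ (t2-t1)/(t3-t2)] / (t3-t1)^2`,
#' so the basis has exactly three free parameters.
#'
#' @param x Numeric predictor values (hours, for the mortality use).
#' @param knots Three strictly increasing knot locations.
#' @return A numeric matrix with columns `(Intercept)`, `x`, `rcs1`.
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 3L) abort("exactly 3 knots are required")
  if (any(diff(knots) <= 0)) abort("knots must be strictly increasing")
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  cube <- function(u) pmax(u, 0)^3
  s <- (cube(x - t1) - cube(x - t2) * (t3 - t1) / (t3 - t2) +
          cube(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  cbind(`(Intercept)` = 1, x = x, rcs1 = s)
}

# Weighted quantiles of the hour variable (record-level hour distribution
# represented by its 24 bin counts).
hour_quantiles <- function(counts, probs) {
  quantile(rep(counts$hour + 0.5, counts$deaths), probs, names = FALSE)
}

#' Fit a restricted cubic spline to hourly death counts
#'
#' Least-squares fit of the 24 hourly counts on the three-knot restricted
#' cubic spline basis evaluated at the hour-bin midpoints. The default knot
#' rule places knots at the 10th/50th/90th percentiles of the record-level
#' hour variable — the most widely used default for three-knot restricted
#' splines. The fit is descriptive (the figure-overlay smooth);
#' `link = "log"` swaps in a Poisson log-link fit when non-negativity
#' matters.
#'
#' @param counts An hourly count tibble from [aggregate_counts()].
#' @param knots Three knot locations on the hour axis, or `NULL` for the
#'   percentile rule.
#' @param link `"identity"` (least squares, default) or `"log"` (Poisson).
#' @return An object of class `spline_fit`: a list with `knots`,
#'   `coefficients` (intercept, linear, restricted term), `fitted` (24
#'   values), `rss`, `link`, and the model frame needed by
#'   [predict.spline_fit()].
#' @export
fit_spline <- function(counts, knots = NULL, link = c("identity", "log")) {
  link <- match.arg(link)
  if (!all(c("hour", "deaths") %in% names(counts)) || nrow(counts) != 24L)
    abort("`counts` must be a 24-row hourly count table")
  x <- counts$hour + 0.5
  if (is.null(knots)) knots <- hour_quantiles(counts, c(0.1, 0.5, 0.9))
  if (any(diff(knots) <= 0))
    abort("degenerate knot placement (knots not strictly increasing); supply `knots`")
  B <- rcs_basis(x, knots)
  if (qr(B)$rank < ncol(B)) abort("degenerate design")
  fit <- if (link == "identity")
    lm(counts$deaths ~ B - 1)
  else
    glm(counts$deaths ~ B - 1, family = poisson())
  fv <- unname(fitted(fit))
  structure(list(knots = knots,
                 coefficients = setNames(unname(coef(fit)), colnames(B)),
                 fitted = fv,
                 rss = sum((counts$deaths - fv)^2),
                 link = link),
            class = "spline_fit")
}

#' Evaluate a fitted restricted cubic spline
#'
#' @param object A `spline_fit`.
#' @param newdata Hour values at which to evaluate (defaults to a fine grid
#'   over the day).
#' @param ... Unused.
#' @return Numeric predictions on the response scale.
#' @export
predict.spline_fit <- function(object, newdata = seq(0, 24, by = 0.1), ...) {
  eta <- drop(rcs_basis(newdata, object$knots) %*% object$coefficients)
  if (object$link == "log") exp(eta) else eta
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf("Restricted cubic spline fit (3 knots at %.2f, %.2f, %.2f; %s link)\n",
              x$knots[1], x$knots[2], x$knots[3], x$link))
  cat(sprintf("  RSS = %.4g; fitted range %.1f - %.1f\n",
              x$rss, min(x$fitted), max(x$fitted)))
  invisible(x)
}
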