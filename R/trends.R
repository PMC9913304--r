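#' True survival trend curves
#'
#' A `true_trend` is the ground-truth net-survival curve used by the
#' synthetic-registry generator: a function of calendar year returning the
#' net-survival fraction in (0, 1] at a fixed horizon (1 or 5 years since
#' diagnosis). Four families are available: constant, linear, logistic and
#' piecewise-linear (the latter records its changepoint year exactly, so
#' breakpoint-recovery simulations have an unambiguous target).
#'
#' @param group group label (e.g. "DK_male"); free-form.
#' @param horizon `"1y"` or `"5y"`.
#' @param family one of `"constant"`, `"linear"`, `"logistic"`,
#'   `"piecewise_linear"`.
#' @param parameters named list of family parameters, all on the fraction
#'   scale (survival in (0, 1]) with slopes per calendar year:
#'   \describe{
#'     \item{constant}{`level`}
#'     \item{linear}{`ref_year`, `level` (at `ref_year`), `slope`}
#'     \item{logistic}{`lower`, `upper`, `midpoint` (year), `rate` (/yr)}
#'     \item{piecewise_linear}{`ref_year`, `level` (at `ref_year`),
#'       `slope_before`, `slope_after`, `changepoint` (year)}
#'   }
#' @return an object of class `true_trend`; call it like a function of
#'   calendar year, or use [trend_value()].
#' @examples
#' tr <- true_trend("DK_male", "5y", "linear",
#'                  list(ref_year = 1973, level = 0.4, slope = 0.005))
#' trend_value(tr, c(1973, 2018))
#' @export
true_trend <- function(group, horizon = c("5y", "1y"), family, parameters) {
  horizon <- match.arg(horizon)
  family <- match.arg(family,
                      c("constant", "linear", "logistic", "piecewise_linear"))
  req <- switch(family,
    constant = "level",
    linear = c("ref_year", "level", "slope"),
    logistic = c("lower", "upper", "midpoint", "rate"),
    piecewise_linear = c("ref_year", "level", "slope_before", "slope_after",
                         "changepoint"))
  missing <- setdiff(req, names(parameters))
  if (length(missing))
    stop("true_trend(): missing parameters for family '", family, "': ",
         paste(missing, collapse = ", "))
  p <- lapply(parameters[req], as.numeric)
  if (!all(vapply(p, is.finite, logical(1))))
    stop("true_trend(): non-finite parameter value")
  structure(list(group = group, horizon = horizon, family = family,
                 parameters = p),
            class = "true_trend")
}

#' Evaluate a true trend at calendar years
#'
#' @param trend a [true_trend()] object.
#' @param year numeric vector of (decimal) calendar years.
#' @return net-survival fractions; an error is raised if the family's
#'   parameters put any value outside (0, 1].
#' @export
trend_value <- function(trend, year) {
  stopifnot(inherits(trend, "true_trend"))
  p <- trend$parameters
  v <- switch(trend$family,
    constant = rep(p$level, length(year)),
    linear = p$level + p$slope * (year - p$ref_year),
    logistic = p$lower + (p$upper - p$lower) /
      (1 + exp(-p$rate * (year - p$midpoint))),
    piecewise_linear = {
      base <- p$level +
        p$slope_before * (pmin(year, p$changepoint) - p$ref_year)
      base + p$slope_after * pmax(year - p$changepoint, 0)
    })
  if (any(!is.finite(v)) || any(v <= 0) || any(v > 1))
    stop("true_trend '", trend$group, "': curve value outside (0, 1] at ",
         "year(s) ", paste(utils::head(year[v <= 0 | v > 1], 3), collapse = ", "))
  v
}

#' @export
print.true_trend <- function(x, ...) {
  cat("<true_trend> group=", x$group, " horizon=", x$horizon,
      " family=", x$family, "\n  parameters: ",
      paste(names(x$parameters), signif(unlist(x$parameters), 5),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Changepoint year of a piecewise-linear trend (NA for other families);
# the ground truth for breakpoint-recovery tests.
#' @rdname trend_value
#' @export
trend_changepoint <- function(trend) {
  stopifnot(inherits(trend, "true_trend"))
  if (trend$family == "piecewise_linear") trend$parameters$changepoint else NA_real_
}
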