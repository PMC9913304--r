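#' Annual change in survival
#'
#' Summaries of the first derivative of a survival measure with respect to
#' calendar year: per posterior draw the derivative is analytic (carried by
#' the curve set), and the posterior median and 95% equal-tailed interval
#' are reported per grid point, in percent units per year.
#'
#' @param curves a [posterior_curveset()] with grid spacing <= 1 year.
#' @return data frame `group`, `year`, `median`, `lo`, `hi`.
#' @export
annual_change <- function(curves) {
  if (max(diff(curves$grid)) > 1)
    stop("annual_change(): grid spacing exceeds 1 year")
  curve_summary(curves, "d1")
}

#' Plausible-trend intervals
#'
#' Maximal contiguous runs of grid points where the 95% credible interval
#' of the first derivative excludes zero, with constant sign within a run
#' (a sign change splits the run); runs spanning at least `min_years`
#' calendar years (last minus first grid point, boundaries counting) are
#' reported.
#'
#' @param curves a [posterior_curveset()].
#' @param min_years minimum run span (default 5).
#' @return data frame `group`, `start_year`, `end_year`, `direction`
#'   (`"upward"`/`"downward"`); zero rows when nothing qualifies.
#' @export
plausible_intervals <- function(curves, min_years = 5) {
  s <- curve_summary(curves, "d1")
  out <- lapply(split(s, s$group), function(d) {
    d <- d[order(d$year), ]
    sign_run <- ifelse(d$lo > 0, 1L, ifelse(d$hi < 0, -1L, 0L))
    runs <- qualifying_runs(d$year, sign_run, min_years)
    if (nrow(runs) == 0) return(NULL)
    data.frame(group = d$group[1], start_year = runs$start,
               end_year = runs$end,
               direction = ifelse(runs$sign > 0, "upward", "downward"))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(group = character(), start_year = numeric(),
                      end_year = numeric(), direction = character())
  rownames(out) <- NULL
  out[order(out$group, out$start_year), , drop = FALSE]
}

#' Breakpoint detection
#'
#' Finds times at which the annual change itself credibly shifts: maximal
#' contiguous runs where the 95% credible interval of the second
#' derivative excludes zero, kept when spanning at least `min_years`
#' (default 3) calendar years. Within each run the breakpoint is the grid
#' point maximizing the absolute posterior median second derivative;
#' direction is the sign of the median second derivative (upward =
#' positive, accelerating improvement).
#'
#' @param curves a [posterior_curveset()].
#' @param min_years minimum qualifying-run span (default 3).
#' @return data frame `group`, `year`, `direction`, `interval_start`,
#'   `interval_end`; zero rows when nothing qualifies.
#' @export
detect_breakpoints <- function(curves, min_years = 3) {
  s <- curve_summary(curves, "d2")
  out <- lapply(split(s, s$group), function(d) {
    d <- d[order(d$year), ]
    sign_run <- ifelse(d$lo > 0, 1L, ifelse(d$hi < 0, -1L, 0L))
    runs <- qualifying_runs(d$year, sign_run, min_years)
    if (nrow(runs) == 0) return(NULL)
    peaks <- vapply(seq_len(nrow(runs)), function(i) {
      seg <- d[d$year >= runs$start[i] & d$year <= runs$end[i], ]
      seg$year[which.max(abs(seg$median))]
    }, numeric(1))
    data.frame(group = d$group[1], year = peaks,
               direction = ifelse(runs$sign > 0, "upward", "downward"),
               interval_start = runs$start, interval_end = runs$end)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(group = character(), year = numeric(),
                      direction = character(), interval_start = numeric(),
                      interval_end = numeric())
  rownames(out) <- NULL
  out[order(out$group, out$year), , drop = FALSE]
}

# maximal sign-constant runs of nonzero `sign_run`, kept when the spanned
# calendar range (boundary points counting) is >= min_years
qualifying_runs <- function(year, sign_run, min_years) {
  r <- rle(sign_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != 0 & (year[ends] - year[starts]) >= min_years
  data.frame(start = year[starts[keep]], end = year[ends[keep]],
             sign = r$values[keep])
}

#' Extract all trend features for a curve set
#'
#' Bundles [annual_change()], [plausible_intervals()] and
#' [detect_breakpoints()] with provenance; serializable with
#' [write_trend_features()].
#'
#' @param curves a [posterior_curveset()].
#' @return list of class `trend_features`.
#' @export
trend_features <- function(curves) {
  structure(list(metric = curves$metric,
                 plausible_intervals = plausible_intervals(curves),
                 breakpoints = detect_breakpoints(curves),
                 annual_change = annual_change(curves),
                 provenance = curves$provenance),
            class = "trend_features")
}

#' @export
print.trend_features <- function(x, ...) {
  cat("<trend_features> metric=", x$metric, ": ",
      nrow(x$plausible_intervals), " plausible interval(s), ",
      nrow(x$breakpoints), " breakpoint(s)\n", sep = "")
  invisible(x)
}

#' Serialize trend features
#'
#' Writes the intervals/breakpoints to JSON (with provenance) and the
#' grid-wise derivative summaries to a tidy CSV.
#'
#' @param features a [trend_features()] object.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @export
write_trend_features <- function(features, json_path = NULL,
                                 csv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(metric = features$metric,
           plausible_intervals = features$plausible_intervals,
           breakpoints = features$breakpoints,
           provenance = features$provenance[
             setdiff(names(features$provenance), "diagnostics")]),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv_path))
    utils::write.csv(features$annual_change, csv_path, row.names = FALSE)
  invisible(features)
}

#' Per-draw integral of the first derivative (consistency check)
#'
#' Integrates each posterior draw's analytic first derivative over the
#' grid span by knot-aware composite Simpson quadrature (exact for the
#' piecewise-quadratic spline derivative) -- an independent numerical path
#' that must agree with the endpoint difference `f(b) - f(a)` of the draw.
#' Requires a spline-backed curve set (coefficient draws present).
#'
#' @param curves a fitted [posterior_curveset()] (not a ratio set).
#' @return named list per group: vector of per-draw integrals.
#' @export
integral_first_derivative <- function(curves) {
  if (is.null(curves$basis))
    stop("integral_first_derivative(): needs a spline-backed curve set")
  a <- min(curves$grid); b <- max(curves$grid)
  ks <- curves$basis$knots
  pts <- sort(unique(c(a, b, ks[ks > a & ks < b])))
  lapply(stats::setNames(curves$groups, curves$groups), function(g) {
    co <- curves$draws[[g]]$coef
    dmat <- function(x) {   # draws x length(x) analytic first derivative
      B1 <- basis_matrix(curves$basis, x, deriv = 1)
      outer(co$sl, B1[, 2]) + co$gamma %*% t(B1[, -(1:2), drop = FALSE])
    }
    tot <- 0
    for (i in seq_len(length(pts) - 1)) {
      lo <- pts[i]; hi <- pts[i + 1]
      tot <- tot + (hi - lo) / 6 *
        (dmat(lo) + 4 * dmat((lo + hi) / 2) + dmat(hi))
    }
    as.numeric(tot)
  })
}
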