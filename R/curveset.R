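#' Posterior curve sets
#'
#' Container for posterior draws of a survival measure on a fine calendar
#' grid: per group, matrices `f` (curve), `d1`, `d2` (analytic first and
#' second derivatives), all `draws x grid`, on the percent scale. Draws
#' are never clipped to [0, 100]: the Gaussian identity-link model may
#' exceed the bounds and downstream ratios must see unclipped draws.
#'
#' @param metric `"1y"`, `"5y"` or `"5/1y"`.
#' @param grid strictly increasing calendar years.
#' @param draws named list (one entry per group) of lists with matrices
#'   `f`, `d1`, `d2` and optionally `coef` (slope / penalized-coefficient
#'   draws enabling exact off-grid evaluation).
#' @param provenance list (seed, spec hash, method, diagnostics, ...).
#' @param basis the shared [build_basis()] object, when available.
#' @param theta full coefficient draw matrix, when available.
#' @return object of class `posterior_curveset`.
#' @export
posterior_curveset <- function(metric, grid, draws, provenance = list(),
                               basis = NULL, theta = NULL) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("posterior_curveset(): grid must be strictly increasing")
  for (g in names(draws)) {
    f <- draws[[g]]$f
    if (!all(is.finite(f)))
      stop("posterior_curveset(): non-finite draws for group ", g)
    if (ncol(f) != length(grid))
      stop("posterior_curveset(): draw matrix does not match grid")
  }
  structure(list(metric = metric, grid = grid, groups = names(draws),
                 draws = draws, provenance = provenance, basis = basis,
                 theta = theta),
            class = "posterior_curveset")
}

#' @export
print.posterior_curveset <- function(x, ...) {
  nd <- nrow(x$draws[[1]]$f)
  cat("<posterior_curveset> metric=", x$metric, ", ", length(x$groups),
      " group(s), ", nd, " draws on ", length(x$grid), " grid points (",
      min(x$grid), "-", max(x$grid), ")\n", sep = "")
  invisible(x)
}

#' Summarize posterior curves
#'
#' @param curves a `posterior_curveset`.
#' @param what `"f"`, `"d1"` or `"d2"`.
#' @param probs interval probabilities (default 95% equal-tailed).
#' @return data frame `group`, `year`, `median`, `lo`, `hi`.
#' @export
curve_summary <- function(curves, what = c("f", "d1", "d2"),
                          probs = c(0.025, 0.975)) {
  what <- match.arg(what)
  do.call(rbind, lapply(curves$groups, function(g) {
    m <- curves$draws[[g]][[what]]
    qs <- apply(m, 2, stats::quantile, probs = c(0.5, probs))
    data.frame(group = g, year = curves$grid, median = qs[1, ],
               lo = qs[2, ], hi = qs[3, ], row.names = NULL)
  }))
}

#' Conditional (5/1-year) survival from paired posterior draws
#'
#' Divides posterior draws of the 5-year survival model by draws of the
#' 1-year model, paired by draw index, giving the posterior of the
#' conditional survival `100 * S5 / S1` (percent). Derivative draws are
#' propagated analytically by the quotient rule, so the downstream
#' derivative rules apply unchanged. Draws with a non-positive 1-year
#' value anywhere on the grid are excluded (count logged in
#' `provenance$excluded_draws`).
#'
#' @param five_year,one_year `posterior_curveset`s on identical grids with
#'   identical groups and draw counts.
#' @return a `posterior_curveset` with metric `"5/1y"`.
#' @export
conditional_ratio <- function(five_year, one_year) {
  if (!isTRUE(all.equal(five_year$grid, one_year$grid)))
    stop("conditional_ratio(): grids differ")
  if (!identical(five_year$groups, one_year$groups))
    stop("conditional_ratio(): groups differ")
  excluded <- integer(0)
  draws <- stats::setNames(vector("list", length(five_year$groups)),
                           five_year$groups)
  for (g in five_year$groups) {
    a <- five_year$draws[[g]]; b <- one_year$draws[[g]]
    if (nrow(a$f) != nrow(b$f))
      stop("conditional_ratio(): draw counts differ for group ", g)
    bad <- apply(b$f <= 0, 1, any)
    excluded[g] <- sum(bad)
    f5 <- a$f[!bad, , drop = FALSE]; f1 <- b$f[!bad, , drop = FALSE]
    d15 <- a$d1[!bad, , drop = FALSE]; d11 <- b$d1[!bad, , drop = FALSE]
    d25 <- a$d2[!bad, , drop = FALSE]; d21 <- b$d2[!bad, , drop = FALSE]
    r <- 100 * f5 / f1
    r1 <- 100 * (d15 * f1 - f5 * d11) / f1^2
    r2 <- 100 * (d25 / f1 - 2 * d15 * d11 / f1^2 - f5 * d21 / f1^2 +
                   2 * f5 * d11^2 / f1^3)
    draws[[g]] <- list(f = r, d1 = r1, d2 = r2)
  }
  if (sum(excluded) > 0)
    message("conditional_ratio(): excluded ", sum(excluded),
            " draw(s) with non-positive 1-year values")
  posterior_curveset(
    metric = "5/1y", grid = five_year$grid, draws = draws,
    provenance = list(
      pairing = "paired by draw index (induces independence between models)",
      excluded_draws = excluded,
      five_year = five_year$provenance, one_year = one_year$provenance))
}
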