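#' Low-rank penalized spline basis with analytic derivatives
#'
#' One-dimensional thin-plate spline basis for smooth calendar-time
#' effects: radial basis functions `|x - k|^3` at `n_knots` knots placed
#' at quantiles of the observed midyears, restricted to the null space of
#' the thin-plate constraints, and orthogonalized against `{1, x}` over
#' the observed midyears (the sum-to-zero identifiability constraint for
#' group-specific smooths). The penalty is the integrated squared second
#' derivative over the knot hull, computed exactly (the integrand is
#' piecewise quadratic), and the nonlinear columns are rescaled so the
#' penalty is the identity -- a `N(0, tau^2 I)` prior on their
#' coefficients is then the standard random-effect form of the smooth.
#'
#' The basis spans constants and linear functions exactly (intercept and
#' slope columns) and every column carries analytic first and second
#' derivatives and an antiderivative (`deriv = -1`).
#'
#' @param midyears observed calendar midyears (>= `n_knots` distinct).
#' @param n_knots number of knots (default 5).
#' @return object of class `spline_basis` with `knots`, `center`, `q`
#'   (number of nonlinear columns) and the transform matrix; use
#'   [basis_matrix()] to evaluate.
#' @export
build_basis <- function(midyears, n_knots = 5) {
  xs <- sort(unique(midyears))
  if (length(xs) < n_knots)
    stop("build_basis(): need at least ", n_knots, " distinct midyears, got ",
         length(xs))
  knots <- unname(stats::quantile(xs, probs = seq(0, 1, length.out = n_knots),
                                  type = 7))
  m <- length(knots)
  ctr <- mean(midyears)
  # null space of the thin-plate constraints sum(d) = 0, sum(d * k) = 0
  C <- rbind(rep(1, m), knots)
  Z <- qr.Q(qr(t(C)), complete = TRUE)[, -(1:2), drop = FALSE]  # m x (m-2)
  # orthogonalize RZ against {1, x} at the observed midyears
  R_obs <- abs(outer(midyears, knots, "-"))^3
  B0 <- R_obs %*% Z
  L <- cbind(1, midyears)
  A <- solve(crossprod(L), crossprod(L, B0))                    # 2 x q
  # exact integrated squared second derivative over the knot hull:
  # columns of d2 are piecewise linear => products piecewise quadratic,
  # composite Simpson on inter-knot panels is exact
  d2fun <- function(x) (6 * abs(outer(x, knots, "-"))) %*% Z
  q <- ncol(Z)
  P <- matrix(0, q, q)
  for (i in seq_len(m - 1)) {
    a <- knots[i]; b <- knots[i + 1]
    fa <- d2fun(a); fm <- d2fun((a + b) / 2); fb <- d2fun(b)
    P <- P + (b - a) / 6 *
      (crossprod(fa) + 4 * crossprod(fm) + crossprod(fb))
  }
  U <- chol((P + t(P)) / 2)
  CN <- rbind(Z, -A) %*% backsolve(U, diag(q))   # (m+2) x q feature map
  structure(list(knots = knots, center = ctr, q = q, CN = CN,
                 midyears = sort(midyears)),
            class = "spline_basis")
}

#' Evaluate a spline basis (or a derivative / antiderivative)
#'
#' @param basis a [build_basis()] object.
#' @param x evaluation points (calendar years).
#' @param deriv 0 (function values), 1, 2 (analytic derivatives) or -1
#'   (antiderivative, fixed so that columns are primitives of the
#'   `deriv = 0` columns).
#' @return matrix with `2 + basis$q` columns: intercept, centered linear
#'   term, then the penalized nonlinear columns.
#' @export
basis_matrix <- function(basis, x, deriv = 0) {
  stopifnot(inherits(basis, "spline_basis"), deriv %in% c(-1, 0, 1, 2))
  u <- outer(x, basis$knots, "-")
  feats <- switch(as.character(deriv),
    "0"  = cbind(abs(u)^3, 1, x),
    "1"  = cbind(3 * u * abs(u), 0, 1),
    "2"  = cbind(6 * abs(u), 0, 0),
    "-1" = cbind(u^3 * abs(u) / 4, x, x^2 / 2))
  N <- feats %*% basis$CN
  const <- switch(as.character(deriv),
    "0" = 1, "1" = 0, "2" = 0, "-1" = x)
  lin <- switch(as.character(deriv),
    "0" = x - basis$center, "1" = 1, "2" = 0,
    "-1" = (x - basis$center)^2 / 2)
  cbind(const = rep_len(const, length(x)), lin = rep_len(lin, length(x)), N)
}

#' @export
print.spline_basis <- function(x, ...) {
  cat("<spline_basis> ", length(x$knots), " knots at ",
      paste(signif(x$knots, 6), collapse = ", "),
      "; ", x$q, " penalized columns\n", sep = "")
  invisible(x)
}
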