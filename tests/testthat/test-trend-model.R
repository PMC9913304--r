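mids <- seq(1973, 2018, by = 5)

test_that("build_basis spans linear functions and differentiates analytically", {
  b <- build_basis(mids, 5)
  # unpenalized least squares on the basis reproduces linear data exactly
  X <- basis_matrix(b, mids, 0)
  y <- 40 + 0.5 * (mids - 1973)
  fit <- stats::lm.fit(X, y)
  expect_lt(max(abs(fit$residuals)), 1e-8)
  # derivative of a constant fit is zero everywhere
  xs <- seq(1971, 2020, by = 0.37)
  co_const <- c(7, rep(0, ncol(X) - 1))
  expect_equal(drop(basis_matrix(b, xs, 1) %*% co_const),
               rep(0, length(xs)), tolerance = 1e-12)
  # analytic derivatives vs central finite differences (h = 0.01, 4th-order
  # stencil: exact for piecewise cubics) on 100 random coefficient vectors;
  # evaluation points within 2h of a knot are skipped -- the spline's third
  # derivative jumps there and no finite difference is valid across it
  set.seed(5)
  h <- 0.01
  xs <- xs[vapply(xs, function(x) min(abs(x - b$knots)), 1) > 2 * h]
  cd4 <- function(d) {
    (basis_matrix(b, xs - 2 * h, d) - 8 * basis_matrix(b, xs - h, d) +
       8 * basis_matrix(b, xs + h, d) - basis_matrix(b, xs + 2 * h, d)) /
      (12 * h)
  }
  B1 <- basis_matrix(b, xs, 1)
  B2 <- basis_matrix(b, xs, 2)
  FD1 <- cd4(0); FD2 <- cd4(1)
  worst1 <- 0; worst2 <- 0
  for (i in 1:100) {
    co <- stats::rnorm(ncol(X))
    worst1 <- max(worst1, max(abs((B1 - FD1) %*% co)))
    worst2 <- max(worst2, max(abs((B2 - FD2) %*% co)))
  }
  expect_lt(worst1, 1e-6)
  expect_lt(worst2, 1e-6)
  # antiderivative columns are primitives of the deriv-0 columns
  A <- basis_matrix(b, c(1975, 2010), -1)
  for (j in seq_len(ncol(A))) {
    iq <- stats::integrate(function(x) basis_matrix(b, x, 0)[, j],
                           1975, 2010, rel.tol = 1e-10,
                           subdivisions = 1000)$value
    expect_equal(as.numeric(A[2, j] - A[1, j]), iq, tolerance = 1e-6)
  }
  expect_error(build_basis(c(1, 2, 3), 5), "at least 5")
})

test_that("fit_trend flags the no-signal case as flat", {
  pts <- data.frame(group = "G", midyear = mids, estimate = 70, se = 0.5,
                    horizon = "5y")
  fit <- fit_trend(pts, trend_model_spec(draws = 2000), seed = 1)
  s <- curve_summary(fit, "f")
  expect_true(all(s$median >= 69 & s$median <= 71))
  d <- curve_summary(fit, "d1")
  expect_true(all(d$lo <= 0 & d$hi >= 0))
  expect_true(fit$provenance$converged)
  expect_gte(nrow(fit$draws[["G"]]$f), 1000)
})

test_that("fit_trend recovers a linear trend at near-noiseless SE", {
  tr <- true_trend("G", "5y", "linear",
                   list(ref_year = 1973, level = 0.50, slope = 0.0048))
  pts <- simulate_survival_points(tr, se_level = 0.2, seed = 11)
  fit <- fit_trend(pts, trend_model_spec(draws = 2000), seed = 5)
  s <- curve_summary(fit, "f")
  at_mid <- s$year %in% mids
  truth <- 100 * trend_value(tr, s$year[at_mid])
  expect_lt(max(abs(s$median[at_mid] - truth)), 1.0)
})

test_that("doubling all SEs inflates the posterior pointwise SD", {
  tr <- true_trend("G", "5y", "logistic",
                   list(lower = 0.5, upper = 0.72, midpoint = 1995.5,
                        rate = 0.12))
  pts <- simulate_survival_points(tr, se_level = 1, seed = 13)
  f1 <- fit_trend(pts, trend_model_spec(draws = 4000), seed = 7)
  pts2 <- pts; pts2$se <- 2 * pts2$se
  f2 <- fit_trend(pts2, trend_model_spec(draws = 4000), seed = 7)
  sd1 <- apply(f1$draws[["G"]]$f, 2, stats::sd)
  sd2 <- apply(f2$draws[["G"]]$f, 2, stats::sd)
  expect_gte(mean(sd2 > sd1), 0.95)
})

test_that("posterior contracts to the data as SE -> 0", {
  # data lying in the basis span (representable), SE = 0.01
  b <- build_basis(mids, 5)
  set.seed(21)
  co <- c(70, 0.3, stats::rnorm(3, 0, 2))
  y <- drop(basis_matrix(b, mids, 0) %*% co)
  pts <- data.frame(group = "G", midyear = mids, estimate = y, se = 0.01,
                    horizon = "5y")
  fit <- fit_trend(pts, trend_model_spec(draws = 2000), seed = 3)
  s <- curve_summary(fit, "f")
  at_mid <- match(mids, s$year)
  expect_lt(max(abs(s$median[at_mid] - y)), 0.1)
})

test_that("group labels are exchangeable and seeds deterministic", {
  trA <- true_trend("A", "5y", "linear",
                    list(ref_year = 1973, level = 0.45, slope = 0.005))
  trB <- true_trend("B", "5y", "logistic",
                    list(lower = 0.5, upper = 0.7, midpoint = 1995,
                         rate = 0.15))
  pts <- simulate_survival_points(list(trA, trB), se_level = 0.5, seed = 31)
  fit1 <- fit_trend(pts, trend_model_spec(draws = 4000), seed = 9)
  # permuted labels: swap A <-> B
  pts2 <- pts
  pts2$group <- ifelse(pts$group == "A", "B", "A")
  fit2 <- fit_trend(pts2, trend_model_spec(draws = 4000), seed = 9)
  for (g in c("A", "B")) {
    other <- setdiff(c("A", "B"), g)
    m1 <- colMeans(fit1$draws[[g]]$f)
    m2 <- colMeans(fit2$draws[[other]]$f)
    expect_lt(max(abs(m1 - m2)), 0.15)   # identical up to Monte Carlo error
  }
  # seed determinism: identical draw matrices
  fit3 <- fit_trend(pts, trend_model_spec(draws = 4000), seed = 9)
  expect_identical(fit1$draws[["A"]]$f, fit3$draws[["A"]]$f)
  expect_identical(fit1$draws[["B"]]$d2, fit3$draws[["B"]]$d2)
  # errors: too few points per group, non-positive SE
  expect_error(fit_trend(pts[pts$midyear < 1990, ], seed = 1), "< 5 points")
  bad <- pts; bad$se[3] <- 0
  expect_error(fit_trend(bad, seed = 1), "positive")
})

test_that("MCMC parity mode agrees with the exact posterior", {
  tr <- true_trend("G", "5y", "logistic",
                   list(lower = 0.5, upper = 0.72, midpoint = 1995.5,
                        rate = 0.12))
  pts <- simulate_survival_points(tr, se_level = 1, seed = 21)
  fe <- fit_trend(pts, trend_model_spec(draws = 4000), seed = 2)
  fm <- fit_trend(pts, trend_model_spec(method = "mcmc", iter = 2000,
                                        warmup = 500), seed = 3)
  se_ <- curve_summary(fe, "f")
  sm_ <- curve_summary(fm, "f")
  expect_lt(mean(abs(se_$median - sm_$median)), 0.2)
  expect_true(all(fm$provenance$diagnostics$rhat < 1.05))
})
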