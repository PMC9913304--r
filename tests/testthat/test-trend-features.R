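fit_pair <- function(seed = 1, draws = 2000) {
  tr5 <- true_trend("G", "5y", "logistic",
                    list(lower = 0.50, upper = 0.72, midpoint = 1995.5,
                         rate = 0.12))
  tr1 <- true_trend("G", "1y", "logistic",
                    list(lower = 0.70, upper = 0.88, midpoint = 1993,
                         rate = 0.12))
  p5 <- simulate_survival_points(tr5, 1, seed = seed)
  p1 <- simulate_survival_points(tr1, 1, seed = seed + 5000)
  list(f5 = fit_trend(p5, trend_model_spec(draws = draws), seed = seed + 1),
       f1 = fit_trend(p1, trend_model_spec(draws = draws), seed = seed + 2))
}

test_that("conditional_ratio is the per-draw quotient with exact round-trip", {
  fits <- fit_pair(3)
  r <- conditional_ratio(fits$f5, fits$f1)
  expect_equal(r$metric, "5/1y")
  # x/x: a set divided by itself is 100 everywhere
  rii <- conditional_ratio(fits$f1, fits$f1)
  expect_equal(max(abs(rii$draws[["G"]]$f - 100)), 0, tolerance = 1e-10)
  expect_equal(max(abs(rii$draws[["G"]]$d1)), 0, tolerance = 1e-10)
  # arithmetic: S5 = 40, S1 = 80 -> 50
  g <- seq(2000, 2010, 0.5)
  c5 <- linear_curveset(g, a = 40, b = 0)
  c1 <- linear_curveset(g, a = 80, b = 0)
  expect_equal(conditional_ratio(c5, c1)$draws[["G"]]$f[1, 1], 50)
  # algebraic round-trip to 1e-10 elementwise
  back <- r$draws[["G"]]$f * fits$f1$draws[["G"]]$f / 100
  expect_lt(max(abs(back - fits$f5$draws[["G"]]$f)), 1e-10)
  # ratio derivatives match finite differences of the ratio draws
  h <- g[2] - g[1]
  c5b <- linear_curveset(g, a = c(40, 42), b = c(0.5, 0.4))
  c1b <- linear_curveset(g, a = c(80, 81), b = c(0.2, 0.1))
  rb <- conditional_ratio(c5b, c1b)
  fd <- (rb$draws[["G"]]$f[, -(1:2)] -
           rb$draws[["G"]]$f[, 1:(length(g) - 2)]) / (2 * h)
  expect_lt(max(abs(rb$draws[["G"]]$d1[, 2:(length(g) - 1)] - fd)), 1e-3)
  # draws with non-positive one-year values are excluded and logged
  c1bad <- linear_curveset(g, a = c(80, -1), b = c(0.2, 0))
  expect_message(rx <- conditional_ratio(c5b, c1bad), "excluded 1")
  expect_equal(nrow(rx$draws[["G"]]$f), 1)
  expect_equal(rx$provenance$excluded_draws[["G"]], 1L)
  # mismatched grids are an error
  c1g <- linear_curveset(seq(2000, 2010, 0.25), a = 80, b = 0)
  expect_error(conditional_ratio(c5, c1g), "grids differ")
})

test_that("annual_change summarizes first-derivative draws", {
  g <- seq(1990, 2010, 0.25)
  # flat draws -> derivative 0; linear slope 0.8 -> derivative 0.8
  flat <- linear_curveset(g, a = c(70, 70, 70), b = c(0, 0, 0))
  ac <- annual_change(flat)
  expect_true(all(ac$median == 0 & ac$lo == 0 & ac$hi == 0))
  lin <- linear_curveset(g, a = c(50, 51), b = c(0.8, 0.8))
  expect_true(all(annual_change(lin)$median == 0.8))
  # grid spacing above 1 year is rejected
  coarse <- linear_curveset(seq(1990, 2010, 2), a = 50, b = 0.8)
  expect_error(annual_change(coarse), "grid spacing")
  # integral of posterior-median derivative ~ endpoint difference of the
  # posterior-median curve (exact per draw; approximate for medians)
  fits <- fit_pair(7)
  s <- curve_summary(fits$f5, "f")
  d <- curve_summary(fits$f5, "d1")
  gr <- fits$f5$grid
  step <- gr[2] - gr[1]
  trap <- sum((d$median[-1] + d$median[-length(gr)]) / 2) * step
  expect_lt(abs(trap - (s$median[length(gr)] - s$median[1])), 0.1)
})

test_that("plausible_intervals applies the 5-year derivative rule", {
  g <- seq(2000, 2020, 0.25)
  # degenerate posteriors give point-mass CIs: a run of exactly 4.75
  # years is excluded, 5.0 years included
  mk <- function(span) {
    d1 <- matrix(0, 2, length(g))
    d1[, g >= 2005 & g <= 2005 + span] <- 1
    f <- matrix(70, 2, length(g))
    posterior_curveset("5y", g, list(G = list(f = f, d1 = d1,
                                              d2 = d1 * 0)))
  }
  expect_equal(nrow(plausible_intervals(mk(4.75))), 0)
  pi5 <- plausible_intervals(mk(5.0))
  expect_equal(nrow(pi5), 1)
  expect_equal(pi5$direction, "upward")
  expect_equal(pi5$end_year - pi5$start_year, 5.0)
  # sign change splits a run
  d1 <- matrix(0, 2, length(g))
  d1[, g <= 2007] <- -1
  d1[, g >= 2012] <- 1
  cs <- posterior_curveset("5y", g,
                           list(G = list(f = d1 * 0 + 70, d1 = d1,
                                         d2 = d1 * 0)))
  pis <- plausible_intervals(cs)
  expect_equal(pis$direction, c("downward", "upward"))
  # strong linear trend: single interval covering >= 80% of the span
  tr <- true_trend("G", "5y", "linear",
                   list(ref_year = 1973, level = 0.45, slope = 0.01))
  pts <- simulate_survival_points(tr, se_level = 0.3, seed = 41)
  fit <- fit_trend(pts, trend_model_spec(draws = 2000), seed = 42)
  pi_lin <- plausible_intervals(fit)
  expect_equal(nrow(pi_lin), 1)
  expect_gte(pi_lin$end_year - pi_lin$start_year,
             0.8 * (max(fit$grid) - min(fit$grid)))
})

test_that("detect_breakpoints applies the 3-year second-derivative rule", {
  g <- seq(2000, 2020, 0.25)
  base <- matrix(0, 2, length(g))
  mkd2 <- function(lo, hi, peak_at, sign = 1) {
    d2 <- base
    sel <- g >= lo & g <= hi
    d2[, sel] <- rep(sign * (1 + exp(-(g[sel] - peak_at)^2)), each = 2)
    posterior_curveset("5y", g, list(G = list(f = base + 70, d1 = base,
                                              d2 = d2)))
  }
  # run of 2.75 years: rejected; 3 years: kept, peak inside the run
  expect_equal(nrow(detect_breakpoints(mkd2(2005, 2007.75, 2006))), 0)
  bk <- detect_breakpoints(mkd2(2005, 2008, 2006))
  expect_equal(nrow(bk), 1)
  expect_equal(bk$year, 2006)
  expect_equal(bk$direction, "upward")
  expect_gte(bk$year, bk$interval_start)
  expect_lte(bk$year, bk$interval_end)
  expect_equal(detect_breakpoints(mkd2(2005, 2008, 2006, sign = -1))$direction,
               "downward")
  # time reversal maps breakpoints to mirrored years; the second
  # derivative's sign (direction) is invariant under reversal
  tr <- true_trend("G", "5y", "piecewise_linear",
                   list(ref_year = 1973, level = 0.50, slope_before = 0.003,
                        slope_after = 0.011, changepoint = 1998))
  pts <- simulate_survival_points(tr, se_level = 0.3, seed = 51)
  ctr <- mean(range(pts$midyear))
  rev_pts <- pts
  rev_pts$midyear <- 2 * ctr - pts$midyear
  fit <- fit_trend(pts, trend_model_spec(draws = 3000), seed = 52)
  fit_rev <- fit_trend(rev_pts, trend_model_spec(draws = 3000), seed = 52)
  bk_f <- detect_breakpoints(fit)
  bk_r <- detect_breakpoints(fit_rev)
  up_f <- bk_f[bk_f$direction == "upward", ]
  up_r <- bk_r[bk_r$direction == "upward", ]
  expect_equal(nrow(up_f), 1)
  expect_equal(nrow(up_r), 1)
  expect_lt(abs(up_r$year - (2 * ctr - up_f$year)), 1.0)
})

test_that("trend_features bundles and serializes", {
  fits <- fit_pair(61)
  feat <- trend_features(fits$f5)
  expect_s3_class(feat, "trend_features")
  # breakpoint containment invariant
  bk <- feat$breakpoints
  if (nrow(bk) > 0) {
    expect_true(all(bk$year >= bk$interval_start &
                      bk$year <= bk$interval_end))
  }
  jp <- tempfile(fileext = ".json"); cp <- tempfile(fileext = ".csv")
  write_trend_features(feat, jp, cp)
  j <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(j$metric, "5y")
  got <- utils::read.csv(cp)
  expect_equal(nrow(got), nrow(feat$annual_change))
})
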