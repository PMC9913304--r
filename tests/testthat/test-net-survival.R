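test_that("expected_survival integrates piecewise annual hazards", {
  rec <- data.frame(id = 1, country = "X", sex = "all", age_dx = 50,
                    dx_year = 2000, futime = 10, status = "censored")
  # zero table
  expect_equal(expected_survival(rec, zero_life_table(), c(0, 1, 5)),
               c(1, 1, 1))
  # constant hazard 0.01/yr
  ltc <- make_life_table("X", "all", 1990:2020, c(0.01, 0, 1))
  expect_equal(expected_survival(rec, ltc, 5), exp(-0.05), tolerance = 1e-12)
  # piecewise: 0.01 in the first follow-up year, 0.02 after (via a table
  # whose hazard doubles from calendar year 2001 on)
  lt2 <- make_life_table("X", "all", 1990:2000, c(0.01, 0, 1))
  lt2b <- make_life_table("X", "all", 2001:2020, c(0.02, 0, 1))
  ltp <- structure(list(country = "X", sex = "all",
                        years = c(lt2$years, lt2b$years),
                        ages = lt2$ages,
                        hazard = rbind(lt2$hazard, lt2b$hazard)),
                   class = "life_table")
  expect_equal(expected_survival(rec, ltp, 3), exp(-(0.01 + 0.02 * 2)),
               tolerance = 1e-12)
  # out-of-span lookup names the missing cell
  expect_error(expected_survival(rec, lt2, 3), "year=2001")
})

test_that("pohar_perme reduces to exp(-Nelson-Aalen) under a zero table", {
  grid <- seq(0, 5, by = 0.25)
  for (seed in 1:5) {
    rec <- random_cohort(100, seed)
    est <- pohar_perme(rec, zero_life_table(), grid)
    # independent Nelson-Aalen from the survival package
    f <- survival::survfit(survival::Surv(futime, status == "died") ~ 1,
                           data = rec, ctype = 1)
    na <- stats::stepfun(f$time, c(0, cumsum(f$n.event / f$n.risk)))
    expect_equal(est$estimate, exp(-na(grid)), tolerance = 1e-12)
  }
})

test_that("pohar_perme matches single-subject closed forms", {
  # censored alive at 5 years under constant population hazard 0.02:
  # net survival rises above 1, S_E(5) = exp(+0.1)
  lt <- make_life_table("X", "all", 1990:2010, c(0.02, 0, 1))
  rec <- as_records(data.frame(id = 1, country = "X", sex = "all",
                               age_dx = 50, dx_year = 2000, futime = 5,
                               status = "censored"))
  est <- pohar_perme(rec, lt, c(0, 5))
  expect_equal(est$estimate, c(1, exp(0.1)), tolerance = 1e-12)
})

test_that("pohar_perme agrees with the brute-force oracle", {
  # three hand-built records: deaths at 1 and 3 years, censoring at 5,
  # constant population hazard 0.01
  lt <- make_life_table("X", "all", 1995:2010, c(0.01, 0, 1))
  rec <- as_records(data.frame(
    id = 1:3, country = "X", sex = "all", age_dx = c(55, 60, 65),
    dx_year = 2000, futime = c(1, 3, 5),
    status = c("died", "died", "censored")))
  grid <- 0:5
  est <- pohar_perme(rec, lt, grid)
  orc <- pp_oracle(rec, lt, grid)
  expect_equal(est$estimate, orc$estimate, tolerance = 1e-10)
  expect_equal(est$var_cum_excess_hazard, orc$var_cum_excess_hazard,
               tolerance = 1e-10)
  # random small cohorts (deeper sweep lives in the acceptance suite)
  lt2 <- test_life_table()
  for (seed in 1:10) {
    rec <- random_cohort(sample(3:30, 1), seed)
    est <- pohar_perme(rec, lt2, seq(0, 5, 0.5))
    orc <- pp_oracle(rec, lt2, seq(0, 5, 0.5))
    expect_equal(est$estimate, orc$estimate, tolerance = 1e-10)
  }
  # ties: events precede censorings at the same time
  rec_t <- as_records(data.frame(
    id = 1:4, country = "X", sex = "all", age_dx = 60, dx_year = 2000,
    futime = c(2, 2, 2, 5), status = c("died", "died", "censored", "censored")))
  est_t <- pohar_perme(rec_t, zero_life_table(), 0:5)
  # both deaths see all 4 subjects at risk: jump = 2/4
  expect_equal(est_t$estimate[est_t$time == 2], exp(-0.5), tolerance = 1e-12)
  # errors
  expect_error(pohar_perme(rec[0, ], lt, 0:5), "no records")
})

test_that("age standardization is a convex combination with w^2 variance", {
  lt <- zero_life_table()
  rec <- random_cohort(60, 42)
  grid <- seq(0, 5, 0.5)
  cu <- pohar_perme(rec, lt, grid)
  w <- standard_weights(c(0, 45, 65), c(45, 65, 90), c(0.2, 0.3, 0.5))
  # identical curves in all bands: output equals the common curve
  std <- age_standardize(list("0-45" = cu, "45-65" = cu, "65-90" = cu), w)
  expect_equal(std$estimate, cu$estimate, tolerance = 1e-12)
  expect_equal(std$variance, sum(w$weight^2) * cu$variance, tolerance = 1e-12)
  # two bands, arithmetic
  cuA <- cu; cuA$estimate <- rep(0.6, length(grid))
  cuB <- cu; cuB$estimate <- rep(0.8, length(grid))
  w2 <- standard_weights(c(0, 45), c(45, 90), c(0.5, 0.5))
  std2 <- age_standardize(list("0-45" = cuA, "45-90" = cuB), w2)
  expect_equal(std2$estimate, rep(0.7, length(grid)), tolerance = 1e-12)
  # three distinct curves: spreadsheet-style recomputation at 10 points
  set.seed(1)
  cus <- lapply(1:3, function(i) {
    x <- cu; x$estimate <- sort(runif(length(grid), 0.3, 1), decreasing = TRUE)
    x$variance <- runif(length(grid), 0, 0.01); x
  })
  std3 <- age_standardize(stats::setNames(cus, c("0-45", "45-65", "65-90")), w)
  manual <- 0.2 * cus[[1]]$estimate + 0.3 * cus[[2]]$estimate +
    0.5 * cus[[3]]$estimate
  expect_equal(std3$estimate, manual, tolerance = 1e-12)
  expect_equal(std3$variance,
               0.04 * cus[[1]]$variance + 0.09 * cus[[2]]$variance +
                 0.25 * cus[[3]]$variance, tolerance = 1e-12)
  # empty band: dropped with warning, weights renormalized
  expect_warning(
    std4 <- age_standardize(list("0-45" = cuA, "45-65" = cuB), w),
    "renormalized")
  expect_equal(std4$estimate, rep((0.2 * 0.6 + 0.3 * 0.8) / 0.5, length(grid)),
               tolerance = 1e-12)
})

test_that("period designs coincide when follow-up is complete", {
  lt <- test_life_table()
  tr <- true_trend("NO/male", "5y", "logistic",
                   list(lower = 0.4, upper = 0.72, midpoint = 1995,
                        rate = 0.1))
  # window-only diagnoses, everyone with complete 5-year potential
  # follow-up: hybrid degenerates to cohort exactly
  rec <- simulate_cohort(tr, lt, 2000, periods = 2000, seed = 5,
                         study_end = 2010)
  eH <- period_window_estimate(rec, lt, c(2000, 2004), design = "hybrid",
                               study_end = 2010)
  eC <- period_window_estimate(rec, lt, c(2000, 2004), design = "cohort")
  expect_equal(eH$estimate, eC$estimate, tolerance = 1e-12)
  expect_equal(eH$se, eC$se, tolerance = 1e-12)
  # cohort design equals pohar_perme on the window's diagnosis cohort
  pp <- pohar_perme(rec[rec$dx_year >= 2000 & rec$dx_year < 2005, ],
                    lt, c(0, 1, 5))
  expect_equal(eC$estimate, 100 * pp$estimate[2:3], tolerance = 1e-12)
  expect_error(period_window_estimate(rec, lt, c(1971, 1975)),
               "no eligible records")
})

test_that("hybrid design recovers truth under truncated follow-up", {
  # constant truth so that borrowing earlier diagnoses is unbiased; the
  # last 5 diagnosis years have truncated follow-up
  lt <- test_life_table()
  tr <- true_trend("NO/male", "5y", "constant", list(level = 0.55))
  rec <- simulate_cohort(tr, lt, 20000, periods = seq(2001, 2016, 5),
                         seed = 77, study_end = 2021)
  est <- period_window_estimate(rec, lt, c(2016, 2020), design = "hybrid",
                                study_end = 2021)
  expect_equal(est$design, c("hybrid", "hybrid"))
  expect_lt(abs(est$estimate[2] - 55), 2 * est$se[2])
  expect_lt(abs(est$estimate[1] - 100 * 0.55^(1 / 5)), 2 * est$se[1])
})

test_that("se_from_ci converts symmetric percent-scale intervals", {
  expect_equal(se_from_ci(c(70, 70)), 0)
  expect_equal(se_from_ci(c(68.04, 71.96)), 1.0, tolerance = 1e-4)
  expect_equal(se_from_ci(c(60.5, 66.3)), 1.4796, tolerance = 1e-4)
  expect_error(se_from_ci(c(70, 69)), "reversed")
})
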