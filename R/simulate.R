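#' Simulate an individual-level registry cohort
#'
#' Generates diagnosis and follow-up records whose excess (cancer) hazard
#' follows a configurable calendar-time trend, on top of background
#' mortality from a life table. The excess hazard is constant over
#' follow-up within a diagnosis year and calibrated so that
#' `exp(-h * lambda_E(d))` equals the trend's `h`-year net survival at
#' diagnosis year `d` (`h` from the trend's horizon, usually 5). Subjects
#' are administratively censored at `study_end`; optional
#' loss-to-follow-up censoring is exponential with rate `ltf_rate`
#' (default off: registries report minimal loss to follow-up).
#'
#' @param truth a [true_trend()] (one group per call).
#' @param life_table a `life_table` supplying background mortality.
#' @param n_per_period subjects per period (>= 1).
#' @param periods integer vector of 5-year period start years
#'   (default `seq(1971, 2016, by = 5)`, ten periods 1971-2020).
#' @param seed integer seed; identical seed + config gives identical output.
#' @param country,sex labels for the records; default parsed from the
#'   trend's group label when it is `"country/sex"`.
#' @param age_range ages at diagnosis drawn uniformly over
#'   `[age_range[1], age_range[2])`; default 15-89.
#' @param ltf_rate loss-to-follow-up censoring rate per year (default 0).
#' @param study_end administrative censoring calendar time (decimal year;
#'   default end of the last period).
#' @return records data frame (see [as_records()]), with attribute
#'   `"truth"` carrying the generating trend.
#' @export
simulate_cohort <- function(truth, life_table, n_per_period,
                            periods = seq(1971, 2016, by = 5), seed,
                            country = NULL, sex = NULL,
                            age_range = c(15, 90), ltf_rate = 0,
                            study_end = max(periods) + 5) {
  stopifnot(inherits(truth, "true_trend"))
  if (n_per_period < 1) stop("simulate_cohort(): n_per_period must be >= 1")
  if (ltf_rate < 0) stop("simulate_cohort(): ltf_rate must be >= 0")
  gl <- strsplit(truth$group, "/", fixed = TRUE)[[1]]
  if (is.null(country)) country <- gl[1]
  if (is.null(sex)) sex <- if (length(gl) > 1) gl[2] else "all"
  h <- as.numeric(sub("y", "", truth$horizon))
  set.seed(as.integer(seed))

  n <- n_per_period * length(periods)
  dx_year <- rep(periods, each = n_per_period) +
    stats::runif(n, 0, 5)
  dx_year <- pmin(dx_year, study_end - 1e-9)
  age_dx <- stats::runif(n, age_range[1], age_range[2])
  surv <- trend_value(truth, dx_year)           # validates (0, 1]
  lam_e <- -log(surv) / h

  rec0 <- data.frame(id = seq_len(n), country = country, sex = sex,
                     age_dx = age_dx, dx_year = dx_year, futime = 1,
                     status = "censored", stringsAsFactors = FALSE)
  t_admin <- study_end - dx_year
  K <- max(ceiling(max(t_admin)), 1L)
  # population hazards per follow-up year; calendar years are clamped to
  # the table span, which only affects cells beyond a subject's
  # administrative censoring time (never used)
  ymax <- max(life_table$years)
  lam_p <- matrix(0, n, K)
  a0 <- floor(age_dx); y0 <- floor(dx_year)
  for (k in seq_len(K) - 1L)
    lam_p[, k + 1L] <- lt_hazard(life_table, pmin(y0 + k, ymax), a0 + k)
  cum <- lam_p %*% outer(seq_len(K), seq_len(K), "<=")   # row cumsums
  # inverse-transform sampling of the piecewise-constant background time
  Ep <- stats::rexp(n)
  kdx <- rowSums(cum < Ep)                      # completed whole years
  t_pop <- ifelse(kdx >= K, Inf,
                  kdx + (Ep - ifelse(kdx > 0, cum[cbind(1:n, pmax(kdx, 1))], 0)) /
                    lam_p[cbind(1:n, pmin(kdx + 1L, K))])
  t_exc <- ifelse(lam_e > 0, stats::rexp(n) / lam_e, Inf)
  t_death <- pmin(t_pop, t_exc)
  t_cens <- if (ltf_rate > 0) pmin(t_admin, stats::rexp(n) / ltf_rate) else
    t_admin
  futime <- pmin(t_death, t_cens)
  status <- ifelse(t_death <= t_cens, "died", "censored")
  out <- rec0
  out$futime <- futime
  out$status <- status
  out <- as_records(out, max_age = max(89, age_range[2] - 1))
  attr(out, "truth") <- truth
  attr(out, "study_end") <- study_end
  out
}

#' Simulate period-wise survival estimates with known noise
#'
#' Emulates a registry-database export directly: one observation per group
#' and 5-year period, placed at the period's middle year, equal to
#' `100 * truth(midyear)` plus Gaussian noise with the stated standard
#' error (the identity-link observation model of the trend stage). Values
#' are clipped to [0, 100]; clipping is counted in the `"n_clipped"`
#' attribute and messaged.
#'
#' @param truth a [true_trend()] or (named) list of them, one per group.
#' @param se_level standard error(s) in percent: scalar or one per period.
#' @param periods period start years (default ten periods 1971-2020).
#' @param seed integer seed.
#' @param site site label for the points (default `"colon"`).
#' @return `survival_points` data frame (one row per group x period).
#' @export
simulate_survival_points <- function(truth, se_level = 1,
                                     periods = seq(1971, 2016, by = 5),
                                     seed, site = "colon") {
  if (inherits(truth, "true_trend")) truth <- list(truth)
  if (any(se_level < 0))
    stop("simulate_survival_points(): se_level must be >= 0")
  se <- rep_len(se_level, length(periods))
  set.seed(as.integer(seed))
  n_clip <- 0L
  rows <- lapply(truth, function(tr) {
    mid <- periods + 2
    mu <- 100 * trend_value(tr, mid)
    y <- mu + stats::rnorm(length(mid), 0, se)
    clip <- y < 0 | y > 100
    n_clip <<- n_clip + sum(clip)
    y <- pmin(pmax(y, 0), 100)
    design <- ifelse(periods == max(periods), "hybrid", "cohort")
    data.frame(group = tr$group, site = site, period_start = periods,
               period_end = periods + 4, midyear = mid,
               horizon = tr$horizon, estimate = y, se = se,
               ci_low = y - 1.959964 * se, ci_high = y + 1.959964 * se,
               design = design, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("survival_points", "data.frame")
  if (n_clip > 0)
    message("simulate_survival_points(): ", n_clip,
            " value(s) clipped to [0, 100]")
  attr(out, "n_clipped") <- n_clip
  out
}
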