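#' Standard error from a 95% confidence interval
#'
#' Registry exports publish symmetric 95% CIs on the percent scale;
#' the implied standard error is `(high - low) / (2 * 1.959964)`.
#'
#' @param ci numeric pair `c(low, high)` in percent, `high >= low`.
#' @return standard error in percent.
#' @examples
#' se_from_ci(c(68.04, 71.96))   # 1.0
#' @export
se_from_ci <- function(ci) {
  if (length(ci) != 2 || any(!is.finite(ci)))
    stop("se_from_ci(): ci must be a finite (low, high) pair")
  if (ci[2] < ci[1])
    stop("se_from_ci(): reversed bounds (low > high)")
  (ci[2] - ci[1]) / (2 * 1.959964)
}

# One survival point row; collections are data frames of class
# "survival_points" in the column layout of the trend-model input.
survival_point <- function(group, site, period, horizon, estimate, se,
                           ci_low, ci_high, design) {
  d <- data.frame(group = group, site = site,
                  period_start = period[1], period_end = period[2],
                  midyear = period[1] + 2, horizon = horizon,
                  estimate = estimate, se = se,
                  ci_low = ci_low, ci_high = ci_high, design = design,
                  stringsAsFactors = FALSE)
  class(d) <- c("survival_points", "data.frame")
  d
}

#' Period-wise net survival estimates (cohort / hybrid design)
#'
#' Estimates 1- and 5-year net survival for one calendar window of
#' diagnoses. The cohort design includes patients diagnosed within the
#' window with their full follow-up. The hybrid design additionally uses
#' recent information: patients whose potential `max(horizons)`-year
#' follow-up is complete by `study_end` contribute cohort-style, later
#' diagnoses contribute their observed (administratively censored)
#' follow-up with delayed entry at `max(0, window_start - dx_year)`;
#' eligibility extends back to `window_start - max(horizons)` so that late
#' follow-up times are informed by pre-window diagnoses.
#'
#' @param records [as_records()] data frame.
#' @param life_table a `life_table` or keyed list.
#' @param window integer pair `c(start_year, end_year)` labelling a 5-year
#'   period (diagnoses in `[start, end + 1)`); midyear is `start + 2`.
#' @param design `"cohort"` or `"hybrid"`.
#' @param horizons follow-up horizons in years (default `c(1, 5)`).
#' @param weights optional [standard_weights()] for age standardization;
#'   `NULL` gives the crude (unstandardized) estimate.
#' @param study_end end of follow-up as a decimal year (default: end of the
#'   window, `window[2] + 1`); only used by the hybrid design.
#' @param group,site labels carried into the output.
#' @return `survival_points` data frame, one row per horizon, with
#'   `estimate`, `se`, `ci_low`, `ci_high` on the percent scale.
#' @export
period_window_estimate <- function(records, life_table, window,
                                   design = c("cohort", "hybrid"),
                                   horizons = c(1, 5), weights = NULL,
                                   study_end = window[2] + 1,
                                   group = "all", site = "all") {
  design <- match.arg(design)
  records <- as_records(records)
  ws <- window[1]; we_excl <- window[2] + 1
  hmax <- max(horizons)
  if (design == "cohort") {
    sel <- records$dx_year >= ws & records$dx_year < we_excl
    sub <- records[sel, , drop = FALSE]
    sub$entry <- rep(0, nrow(sub))
  } else {
    sel <- records$dx_year >= ws - hmax & records$dx_year < we_excl
    sub <- records[sel, , drop = FALSE]
    complete <- sub$dx_year + hmax <= study_end
    sub$entry <- ifelse(complete, 0, pmax(0, ws - sub$dx_year))
    sub <- sub[sub$entry < sub$futime, , drop = FALSE]
  }
  if (nrow(sub) == 0)
    stop("period_window_estimate(): no eligible records in window ",
         ws, "-", window[2], " (", design, " design)")
  grid <- sort(unique(c(0, horizons)))
  curve <- if (is.null(weights)) {
    pohar_perme(sub, life_table, grid)
  } else {
    idx <- band_index(sub$age_dx, weights)
    if (anyNA(idx))
      stop("period_window_estimate(): ages outside the weight bands")
    labs <- band_labels(weights)
    curves <- stats::setNames(vector("list", nrow(weights)), labs)
    for (b in unique(idx))
      curves[[labs[b]]] <- pohar_perme(sub[idx == b, , drop = FALSE],
                                       life_table, grid)
    age_standardize(curves, weights)
  }
  out <- do.call(rbind, lapply(horizons, function(h) {
    i <- match(h, curve$time)
    est <- 100 * curve$estimate[i]
    se <- 100 * sqrt(curve$variance[i])
    ci <- net_survival_ci(curve, i)
    survival_point(group, site, window, paste0(h, "y"),
                   est, se, 100 * ci[1], 100 * ci[2], design)
  }))
  class(out) <- c("survival_points", "data.frame")
  out
}

# 95% CI for one grid point of a net_survival_curve: log cumulative excess
# hazard scale when the cumulative excess hazard is positive (keeps bounds
# plausible), linear on the survival scale otherwise (net survival > 1).
net_survival_ci <- function(curve, i, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  lam <- curve$cum_excess_hazard[i]
  vl <- curve$var_cum_excess_hazard[i]
  if (is.finite(lam) && lam > 0 && vl > 0) {
    f <- exp(z * sqrt(vl) / lam)
    sort(c(exp(-lam * f), exp(-lam / f)))
  } else {
    s <- curve$estimate[i]
    se <- sqrt(curve$variance[i])
    c(max(s - z * se, 0), s + z * se)
  }
}
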