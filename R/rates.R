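#' Age-specific rate tables
#'
#' Case counts and person-years by age band, used for age-standardized
#' rates and cumulative risks. Interchange CSV dialect: columns
#' `group,year,age_lo,age_hi,cases,person_years`.
#'
#' @param df data frame with columns `group`, `year`, `age_lo`, `age_hi`,
#'   `cases`, `person_years` (bands `[lo, hi)` disjoint per group x year).
#' @return validated data frame of class `age_rate_table`.
#' @export
age_rate_table <- function(df) {
  need <- c("group", "year", "age_lo", "age_hi", "cases", "person_years")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("age_rate_table(): missing columns: ", paste(miss, collapse = ", "))
  if (any(df$cases < 0) || any(df$cases != round(df$cases)))
    stop("age_rate_table(): cases must be non-negative integers")
  if (any(df$person_years <= 0))
    stop("age_rate_table(): person_years must be positive")
  if (any(df$age_hi <= df$age_lo))
    stop("age_rate_table(): bands need age_hi > age_lo")
  for (key in split(df, paste(df$group, df$year))) {
    o <- order(key$age_lo)
    if (any(key$age_lo[o][-1] < key$age_hi[o][-nrow(key)]))
      stop("age_rate_table(): overlapping bands for group ", key$group[1],
           ", year ", key$year[1])
  }
  class(df) <- c("age_rate_table", "data.frame")
  df
}

#' @rdname age_rate_table
#' @param path CSV path.
#' @export
read_age_rate_table <- function(path) {
  age_rate_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname age_rate_table
#' @param table an `age_rate_table` to serialize.
#' @export
write_age_rate_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Age-standardized rate per 100,000 person-years
#'
#' `sum_a w_a * (cases_a / person_years_a) * 1e5`, with standard weights
#' matched to the table's bands by their `[lo, hi)` bounds and normalized
#' over the contributing bands.
#'
#' @param table one group x year slice of an [age_rate_table()] (or any
#'   subset whose bands are unique).
#' @param weights a [standard_weights()] table covering the table's bands.
#' @return rate per 100,000 person-years.
#' @examples
#' tab <- age_rate_table(data.frame(group = "g", year = 2000,
#'   age_lo = c(0, 45), age_hi = c(45, 90), cases = c(10, 30),
#'   person_years = c(1e5, 1e5)))
#' asr(tab, standard_weights(c(0, 45), c(45, 90), c(0.6, 0.4)))
#' @export
asr <- function(table, weights) {
  stopifnot(inherits(weights, "standard_weights"))
  key <- paste(table$age_lo, table$age_hi)
  wkey <- paste(weights$age_lo, weights$age_hi)
  wi <- match(key, wkey)
  if (anyNA(wi))
    stop("asr(): no standard weight for band(s) ",
         paste(key[is.na(wi)], collapse = ", "))
  if (any(table$person_years == 0 & table$cases > 0))
    stop("asr(): zero person-years with nonzero cases")
  w <- weights$weight[wi]
  w <- w / sum(w)
  sum(w * table$cases / table$person_years) * 1e5
}

#' Cumulative risk up to an age limit
#'
#' `100 * (1 - exp(-sum_a width_a * rate_a))` over bands fully below
#' `upper_age`, rates on the per-person-year scale. The usual registry
#' headline is the 0-74 cumulative risk (`upper_age = 75`).
#'
#' @inheritParams asr
#' @param upper_age exclusive age limit (default 75).
#' @return cumulative risk in percent.
#' @export
cumulative_risk <- function(table, upper_age = 75) {
  sel <- table$age_hi <= upper_age
  t2 <- table[sel, , drop = FALSE]
  o <- order(t2$age_lo)
  t2 <- t2[o, , drop = FALSE]
  covered <- nrow(t2) > 0 && t2$age_lo[1] == 0 &&
    all(t2$age_lo[-1] == t2$age_hi[-nrow(t2)]) &&
    t2$age_hi[nrow(t2)] == upper_age
  if (!covered) {
    have <- paste0("[", t2$age_lo, ",", t2$age_hi, ")", collapse = " ")
    stop("cumulative_risk(): bands do not cover [0, ", upper_age,
         ") contiguously; present: ", if (nzchar(have)) have else "none")
  }
  rate <- t2$cases / t2$person_years
  100 * (1 - exp(-sum((t2$age_hi - t2$age_lo) * rate)))
}

#' Cubic smoothing-spline display smoother
#'
#' Visualization-only smoothing of annual rate series with
#' [stats::smooth.spline()] (smoothing parameter `spar` 0.4, 15 knots by
#' default, as used for the incidence/mortality display curves). Never
#' feeds inference. With fewer than 4 distinct points the input is
#' returned unchanged with a warning.
#'
#' @param years,values the series to smooth.
#' @param spar smoothing parameter (default 0.4).
#' @param knots number of knots (default 15, reduced to the number of
#'   distinct years when smaller).
#' @param grid_step output grid spacing in years (default 0.25).
#' @return data frame with columns `year`, `value`.
#' @export
smooth_series <- function(years, values, spar = 0.4, knots = 15,
                          grid_step = 0.25) {
  stopifnot(length(years) == length(values))
  if (length(unique(years)) < 4) {
    warning("smooth_series(): fewer than 4 distinct years; returning input")
    return(data.frame(year = years, value = values))
  }
  nk <- min(knots, length(unique(years)))
  fit <- stats::smooth.spline(years, values, spar = spar, nknots = nk,
                              cv = NA, keep.data = FALSE)
  grid <- seq(min(years), max(years), by = grid_step)
  data.frame(year = grid, value = stats::predict(fit, grid)$y)
}
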