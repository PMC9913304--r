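#' Standard weight tables
#'
#' External weight standards used for age standardization: a survival
#' standard (five broad age bands, used to weight band-specific net
#' survival curves) and the world standard population (eighteen 5-year
#' bands, used for incidence/mortality rates). Both ship as replaceable
#' CSV assets under `inst/extdata/` with columns `age_lo,age_hi,weight`;
#' weights must be non-negative and are normalized to sum to 1.
#'
#' @param path CSV file with columns `age_lo`, `age_hi`, `weight`.
#' @param label name stored with the standard.
#' @return data frame of class `standard_weights` with columns `age_lo`,
#'   `age_hi`, `weight` (summing to 1 within 1e-12).
#' @export
read_standard_weights <- function(path, label = basename(path)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("age_lo", "age_hi", "weight"), names(d))
  if (length(miss))
    stop("read_standard_weights(): missing columns: ",
         paste(miss, collapse = ", "))
  standard_weights(d$age_lo, d$age_hi, d$weight, label = label)
}

#' @rdname read_standard_weights
#' @param age_lo,age_hi band bounds, `[lo, hi)`, disjoint and increasing.
#' @param weight non-negative band weights (normalized internally).
#' @export
standard_weights <- function(age_lo, age_hi, weight, label = "custom") {
  o <- order(age_lo)
  age_lo <- age_lo[o]; age_hi <- age_hi[o]; weight <- weight[o]
  if (any(weight < 0) || all(weight == 0))
    stop("standard_weights(): weights must be non-negative, not all zero")
  if (any(age_hi <= age_lo) || any(age_lo[-1] < age_hi[-length(age_hi)]))
    stop("standard_weights(): bands must be disjoint with hi > lo")
  d <- data.frame(age_lo = age_lo, age_hi = age_hi,
                  weight = weight / sum(weight))
  attr(d, "label") <- label
  class(d) <- c("standard_weights", "data.frame")
  d
}

#' @rdname read_standard_weights
#' @export
default_survival_weights <- function() {
  read_standard_weights(
    system.file("extdata", "icss_weights.csv", package = "survtrend",
                mustWork = TRUE),
    label = "icss_5band")
}

#' @rdname read_standard_weights
#' @export
world_standard_weights <- function() {
  read_standard_weights(
    system.file("extdata", "world_std_weights.csv", package = "survtrend",
                mustWork = TRUE),
    label = "world_standard")
}

# Band label "lo-hi" used to key per-band curve lists
band_labels <- function(weights) {
  paste0(weights$age_lo, "-", weights$age_hi)
}

# Band index (row of `weights`) for each age; NA when no band covers it
band_index <- function(age, weights) {
  idx <- rep(NA_integer_, length(age))
  for (b in seq_len(nrow(weights)))
    idx[age >= weights$age_lo[b] & age < weights$age_hi[b]] <- b
  idx
}

#' Age-standardize band-specific net survival curves
#'
#' Weighted average of band-specific net survival at each grid point, with
#' variance combined as `sum(w^2 var)`. Bands without a curve (e.g. empty
#' in a small cohort) are dropped and the remaining weights renormalized,
#' with a warning.
#'
#' @param curves named list of [pohar_perme()] curves, keyed by band label
#'   `"lo-hi"` (see bands of `weights`); `NULL` entries mark empty bands.
#' @param weights a [standard_weights()] table.
#' @return a `net_survival_curve` on the common grid.
#' @export
age_standardize <- function(curves, weights) {
  stopifnot(inherits(weights, "standard_weights"))
  if (abs(sum(weights$weight) - 1) > 1e-12)
    stop("age_standardize(): weights must sum to 1")
  labs <- band_labels(weights)
  got <- labs %in% names(curves) &
    !vapply(labs, function(l) is.null(curves[[l]]), logical(1))
  if (!any(got)) stop("age_standardize(): no band has a curve")
  if (!all(got)) {
    warning("age_standardize(): empty band(s) ",
            paste(labs[!got], collapse = ", "),
            " dropped; remaining weights renormalized")
  }
  w <- weights$weight[got] / sum(weights$weight[got])
  cl <- curves[labs[got]]
  grid <- cl[[1]]$time
  for (cu in cl)
    if (!isTRUE(all.equal(cu$time, grid)))
      stop("age_standardize(): band curves must share one time grid")
  est <- Reduce(`+`, Map(function(cu, wi) wi * cu$estimate, cl, w))
  va <- Reduce(`+`, Map(function(cu, wi) wi^2 * cu$variance, cl, w))
  lam <- Reduce(`+`, Map(function(cu, wi) wi * cu$cum_excess_hazard, cl, w))
  vl <- Reduce(`+`, Map(function(cu, wi) wi^2 * cu$var_cum_excess_hazard,
                        cl, w))
  nr <- Reduce(`+`, lapply(cl, `[[`, "n_risk"))
  out <- data.frame(time = grid, estimate = est, variance = va,
                    cum_excess_hazard = lam, var_cum_excess_hazard = vl,
                    n_risk = nr)
  class(out) <- c("net_survival_curve", "data.frame")
  attr(out, "n") <- sum(vapply(cl, attr, numeric(1), "n"))
  attr(out, "weights") <- attr(weights, "label")
  out
}
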