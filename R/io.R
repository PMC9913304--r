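#' Read a registry-export CSV of period survival estimates
#'
#' Pinned dialect (UTF-8, header required): columns `country`, `sex`,
#' `site`, `period` (`"1971-1975"`), `horizon` (`"1y"`/`"5y"`),
#' `estimate`, `ci_low`, `ci_high` (percent), optional `design`. Other
#' column namings can be adapted via `column_map`. Standard errors are
#' derived from the confidence intervals with [se_from_ci()]. Malformed
#' rows (unparseable period, non-finite values, reversed CI) are rejected
#' and reported with their line numbers; row count is conserved:
#' rows in = points out + rejects.
#'
#' @param path CSV file.
#' @param column_map optional named character vector mapping dialect names
#'   to the file's names, e.g. `c(estimate = "rs", ci_low = "lo")`.
#' @return `survival_points` data frame; rejected rows (with `line` and
#'   `reason`) in attribute `"rejects"`.
#' @export
read_nordcan_export <- function(path, column_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    for (std in names(column_map)) {
      i <- match(column_map[[std]], names(d))
      if (!is.na(i)) names(d)[i] <- std
    }
  need <- c("country", "sex", "site", "period", "horizon", "estimate",
            "ci_low", "ci_high")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_nordcan_export(): missing columns: ",
         paste(miss, collapse = ", "))
  if (nrow(d) == 0) {
    out <- data.frame(group = character(), site = character(),
                      period_start = numeric(), period_end = numeric(),
                      midyear = numeric(), horizon = character(),
                      estimate = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      design = character(), stringsAsFactors = FALSE)
    class(out) <- c("survival_points", "data.frame")
    attr(out, "rejects") <- data.frame(line = integer(), reason = character())
    return(out)
  }
  pp <- regmatches(d$period, regexec("^([0-9]{4})[-_]([0-9]{4})$", d$period))
  p_start <- vapply(pp, function(m) if (length(m) == 3)
    as.numeric(m[2]) else NA_real_, numeric(1))
  p_end <- vapply(pp, function(m) if (length(m) == 3)
    as.numeric(m[3]) else NA_real_, numeric(1))
  est <- suppressWarnings(as.numeric(d$estimate))
  lo <- suppressWarnings(as.numeric(d$ci_low))
  hi <- suppressWarnings(as.numeric(d$ci_high))
  reason <- rep(NA_character_, nrow(d))
  reason[is.na(p_start)] <- "unparseable period"
  reason[is.na(reason) & (!is.finite(est) | !is.finite(lo) |
                            !is.finite(hi))] <- "non-numeric value"
  reason[is.na(reason) & hi < lo] <- "reversed confidence interval"
  reason[is.na(reason) & !(d$horizon %in% c("1y", "5y", "5/1y"))] <-
    "unknown horizon"
  ok <- is.na(reason)
  rejects <- data.frame(line = which(!ok) + 1L, reason = reason[!ok])
  if (nrow(rejects) > 0)
    message("read_nordcan_export(): rejected ", nrow(rejects),
            " row(s) at line(s) ", paste(rejects$line, collapse = ", "))
  design <- if ("design" %in% names(d)) d$design else
    rep("cohort", nrow(d))
  out <- data.frame(
    group = paste(d$country[ok], d$sex[ok], sep = "/"),
    site = d$site[ok], period_start = p_start[ok], period_end = p_end[ok],
    midyear = p_start[ok] + 2, horizon = d$horizon[ok],
    estimate = est[ok],
    se = (hi[ok] - lo[ok]) / (2 * 1.959964),
    ci_low = lo[ok], ci_high = hi[ok], design = design[ok],
    stringsAsFactors = FALSE)
  class(out) <- c("survival_points", "data.frame")
  attr(out, "rejects") <- rejects
  out
}

#' @rdname read_nordcan_export
#' @param points `survival_points` to serialize (dialect above; `group`
#'   is split into `country`/`sex` on the first `/`).
#' @export
write_survival_points <- function(points, path) {
  gs <- strsplit(points$group, "/", fixed = TRUE)
  utils::write.csv(
    data.frame(
      country = vapply(gs, `[`, "", 1),
      sex = vapply(gs, function(x) if (length(x) > 1) x[2] else "all", ""),
      site = points$site,
      period = paste0(points$period_start, "-", points$period_end),
      horizon = points$horizon, estimate = points$estimate,
      ci_low = points$ci_low, ci_high = points$ci_high,
      design = points$design),
    path, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Fully serializable (JSON) configuration for the staged pipeline; the
#' config hash and seed are embedded in every output artifact.
#'
#' @param seed integer seed for all randomness.
#' @param outdir output directory.
#' @param periods period start years (default ten periods 1971-2020).
#' @param se_level simulated per-point SE (percent).
#' @param sites site labels to simulate.
#' @param groups named list: per group, a list with `trend_5y` and
#'   `trend_1y`, each `list(family =, parameters =)` (see [true_trend()]).
#' @param estimation list: `enabled` (simulate cohorts and re-estimate the
#'   period points instead of direct point simulation), `n_per_period`,
#'   `makeham` parameters for the synthetic life table.
#' @param model named overrides for [trend_model_spec()].
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, outdir = tempfile("survtrend_run_"),
                       periods = seq(1971, 2016, by = 5), se_level = 1,
                       sites = "colon",
                       groups = default_demo_groups(),
                       estimation = list(enabled = FALSE,
                                         n_per_period = 2000,
                                         makeham = c(5e-4, 3e-5, 0.09)),
                       model = list()) {
  cfg <- list(seed = as.integer(seed), outdir = outdir, periods = periods,
              se_level = se_level, sites = sites, groups = groups,
              estimation = estimation, model = model)
  class(cfg) <- "run_config"
  cfg
}

# Two sexes with mildly different logistic improvements; the demo world.
default_demo_groups <- function() {
  list(
    "DK/male" = list(
      trend_5y = list(family = "logistic",
                      parameters = list(lower = 0.35, upper = 0.70,
                                        midpoint = 2000, rate = 0.15)),
      trend_1y = list(family = "logistic",
                      parameters = list(lower = 0.60, upper = 0.85,
                                        midpoint = 1998, rate = 0.15))),
    "DK/female" = list(
      trend_5y = list(family = "logistic",
                      parameters = list(lower = 0.37, upper = 0.72,
                                        midpoint = 1999, rate = 0.14)),
      trend_1y = list(family = "logistic",
                      parameters = list(lower = 0.62, upper = 0.86,
                                        midpoint = 1997, rate = 0.14))))
}

#' @rdname run_config
#' @param path JSON path.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$groups) || length(cfg$groups) == 0) {
    cfg$groups <- NULL        # fall back to the default demo groups
  } else {
    cfg$groups <- lapply(cfg$groups, function(g)
      lapply(g, function(tr) list(family = tr$family,
                                  parameters = as.list(tr$parameters))))
  }
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

#' @rdname run_config
#' @param config a `run_config` to serialize.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  spec_hash(structure(list(s = as.character(s)), class = "x"))
}
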