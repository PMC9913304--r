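# derived sub-seeds for independent pipeline stages (kept under 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 10007 * k) %% (.Machine$integer.max - 1)) + 1L
}

#' Run the staged trend-analysis pipeline
#'
#' Executes simulate -> (estimate) -> trend -> features -> report on a
#' [run_config()]. By default period-wise survival points are simulated
#' directly from the configured trends; with `config$estimation$enabled`,
#' individual cohorts are simulated and the points re-estimated with the
#' Pohar Perme stage (cohort design for all but the last period, hybrid
#' for the last). Supplying `points` skips simulation/estimation entirely
#' (stage isolation): trend outputs are then identical to a full run on
#' the same points and seed.
#'
#' All artifacts (points CSV, per-metric feature JSON/CSV, per-group
#' figure panels) carry the config hash and seed.
#'
#' @param config a [run_config()].
#' @param points optional `survival_points` (skips the simulation stage).
#' @param stages character subset of
#'   `c("simulate", "trend", "features", "report")`; earlier stages are
#'   always run when later ones need them.
#' @return invisible list with `points`, `fits`, `features`, `paths`,
#'   `config_hash`.
#' @export
run_pipeline <- function(config, points = NULL,
                         stages = c("simulate", "trend", "features",
                                    "report")) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- do.call(trend_model_spec, config$model)
  paths <- character(0)

  ## stage: simulate / estimate -------------------------------------------
  if (is.null(points)) {
    points <- do.call(rbind, lapply(seq_along(config$sites), function(si) {
      site <- config$sites[si]
      if (isTRUE(config$estimation$enabled))
        estimate_site_points(config, site, si)
      else simulate_site_points(config, site, si)
    }))
    rownames(points) <- NULL
    class(points) <- c("survival_points", "data.frame")
  }
  pts_path <- file.path(config$outdir, "survival_points.csv")
  write_survival_points(points, pts_path)
  paths <- c(paths, pts_path)
  if (!any(c("trend", "features", "report") %in% stages))
    return(invisible(list(points = points, paths = paths,
                          config_hash = hash)))

  ## stage: trend ----------------------------------------------------------
  fits <- list()
  for (site in unique(points$site)) {
    sp <- points[points$site == site, , drop = FALSE]
    f1 <- fit_trend(sp[sp$horizon == "1y", , drop = FALSE], spec,
                    seed = derive_seed(config$seed, 701))
    f5 <- fit_trend(sp[sp$horizon == "5y", , drop = FALSE], spec,
                    seed = derive_seed(config$seed, 709))
    fits[[site]] <- list("1y" = f1, "5y" = f5,
                         "5/1y" = conditional_ratio(f5, f1))
  }
  if (!any(c("features", "report") %in% stages))
    return(invisible(list(points = points, fits = fits, paths = paths,
                          config_hash = hash)))

  ## stage: features -------------------------------------------------------
  features <- lapply(fits, function(site_fits)
    lapply(site_fits, trend_features))
  for (site in names(features))
    for (metric in names(features[[site]])) {
      feat <- features[[site]][[metric]]
      feat$provenance$config_hash <- hash
      feat$provenance$seed <- config$seed
      stub <- file.path(config$outdir,
                        paste0("features_", site, "_",
                               gsub("/", "", metric)))
      write_trend_features(feat, paste0(stub, ".json"),
                           paste0(stub, ".csv"))
      features[[site]][[metric]] <- feat
      paths <- c(paths, paste0(stub, ".json"), paste0(stub, ".csv"))
    }
  if (!("report" %in% stages))
    return(invisible(list(points = points, fits = fits,
                          features = features, paths = paths,
                          config_hash = hash)))

  ## stage: report (figures) ----------------------------------------------
  for (site in names(fits))
    for (g in fits[[site]][["1y"]]$groups) {
      fig <- file.path(config$outdir,
                       paste0("panel_", site, "_", gsub("/", "_", g)))
      p <- plot_trend_panel(fits[[site]], features[[site]], g,
                            file_stub = fig,
                            title = paste(site, g, sep = " / "))
      paths <- c(paths, p)
    }
  invisible(list(points = points, fits = fits, features = features,
                 paths = paths, config_hash = hash))
}

simulate_site_points <- function(config, site, si) {
  rows <- lapply(seq_along(config$groups), function(gi) {
    gname <- names(config$groups)[gi]
    gcfg <- config$groups[[gi]]
    do.call(rbind, lapply(c("1y", "5y"), function(h) {
      tcfg <- gcfg[[paste0("trend_", sub("y", "y", h))]]
      tr <- true_trend(gname, h, tcfg$family, tcfg$parameters)
      simulate_survival_points(
        tr, se_level = config$se_level, periods = config$periods,
        seed = derive_seed(config$seed, 100 * si + 10 * gi +
                             (h == "5y")),
        site = site)
    }))
  })
  do.call(rbind, rows)
}

estimate_site_points <- function(config, site, si) {
  periods <- config$periods
  study_end <- max(periods) + 5
  rows <- lapply(seq_along(config$groups), function(gi) {
    gname <- names(config$groups)[gi]
    gcfg <- config$groups[[gi]]
    tr5 <- true_trend(gname, "5y", gcfg$trend_5y$family,
                      gcfg$trend_5y$parameters)
    gl <- strsplit(gname, "/", fixed = TRUE)[[1]]
    lt <- make_life_table(gl[1], if (length(gl) > 1) gl[2] else "all",
                          (min(periods) - 1):(study_end + 6),
                          config$estimation$makeham)
    rec <- simulate_cohort(tr5, lt, config$estimation$n_per_period,
                           periods,
                           seed = derive_seed(config$seed, 500 * si + gi),
                           study_end = study_end)
    do.call(rbind, lapply(periods, function(ps) {
      design <- if (ps == max(periods)) "hybrid" else "cohort"
      period_window_estimate(rec, lt, c(ps, ps + 4), design = design,
                             study_end = study_end, group = gname,
                             site = site)
    }))
  })
  do.call(rbind, rows)
}

#' Panel figure: survival curves, breakpoints and annual change
#'
#' Mirrors the analysis's panel layout: posterior-median survival curves
#' for the 1-year, 5/1-year and 5-year metrics (solid over plausible-trend
#' intervals, dashed elsewhere), vertical lines at detected breakpoints,
#' and an annual-change strip with 95% credible ribbons underneath.
#'
#' @param site_fits list of `posterior_curveset`s keyed `"1y"`, `"5y"`,
#'   `"5/1y"`.
#' @param site_features matching list of [trend_features()].
#' @param group group label to plot.
#' @param file_stub output path without extension; PNG is attempted,
#'   falling back to PDF when no bitmap device is available.
#' @param title plot title.
#' @return the path written, invisibly.
#' @export
plot_trend_panel <- function(site_fits, site_features, group,
                             file_stub, title = group) {
  dev_path <- paste0(file_stub, ".png")
  opened <- tryCatch({
    grDevices::png(dev_path, width = 900, height = 700); TRUE
  }, error = function(e) FALSE)
  if (!opened) {
    dev_path <- paste0(file_stub, ".pdf")
    grDevices::pdf(dev_path, width = 9, height = 7)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  cols <- c("1y" = "#1b9e77", "5/1y" = "#7570b3", "5y" = "#d95f02")
  metrics <- intersect(names(cols), names(site_fits))
  graphics::layout(matrix(1:2, 2, 1), heights = c(2, 1))
  old <- graphics::par(mar = c(2, 4, 3, 1)); on.exit(graphics::par(old),
                                                     add = TRUE)
  grid <- site_fits[[1]]$grid
  sums <- lapply(site_fits[metrics], function(f) {
    s <- curve_summary(f, "f"); s[s$group == group, ]
  })
  ylim <- range(unlist(lapply(sums, function(s) c(s$lo, s$hi))))
  graphics::plot(NA, xlim = range(grid), ylim = ylim, xlab = "",
                 ylab = "Relative survival (%)", main = title)
  for (m in metrics) {
    s <- sums[[m]]
    graphics::polygon(c(s$year, rev(s$year)), c(s$lo, rev(s$hi)),
                      col = grDevices::adjustcolor(cols[m], 0.15),
                      border = NA)
    graphics::lines(s$year, s$median, col = cols[m], lty = 2)
    pi <- site_features[[m]]$plausible_intervals
    pi <- pi[pi$group == group, , drop = FALSE]
    for (i in seq_len(nrow(pi))) {
      seg <- s[s$year >= pi$start_year[i] & s$year <= pi$end_year[i], ]
      graphics::lines(seg$year, seg$median, col = cols[m], lwd = 3)
    }
    bp <- site_features[[m]]$breakpoints
    bp <- bp[bp$group == group, , drop = FALSE]
    if (nrow(bp)) graphics::abline(v = bp$year, col = cols[m], lty = 3)
  }
  graphics::legend("bottomright", legend = metrics, col = cols[metrics],
                   lwd = 2, bty = "n")
  graphics::par(mar = c(4, 4, 1, 1))
  acs <- lapply(site_features[metrics], function(f) {
    a <- f$annual_change; a[a$group == group, ]
  })
  ylim2 <- range(unlist(lapply(acs, function(a) c(a$lo, a$hi))))
  graphics::plot(NA, xlim = range(grid), ylim = ylim2,
                 xlab = "Calendar year", ylab = "Annual change (%/yr)")
  graphics::abline(h = 0, col = "grey60")
  for (m in metrics) {
    a <- acs[[m]]
    graphics::polygon(c(a$year, rev(a$year)), c(a$lo, rev(a$hi)),
                      col = grDevices::adjustcolor(cols[m], 0.15),
                      border = NA)
    graphics::lines(a$year, a$median, col = cols[m])
  }
  invisible(dev_path)
}
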