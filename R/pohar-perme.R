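#' Pohar Perme net survival estimator
#'
#' Estimates net (relative) survival from individual records and a
#' population life table. Each subject's at-risk and event contributions
#' are weighted by the inverse of their expected survival
#' `w_i(t) = 1 / S_Pi(t)`; the cumulative excess hazard is
#' `Lambda_E(t) = sum over event times of [w dN / sum(w Y)]
#'  - integral of [sum(w Y lambda_P) / sum(w Y)]`, and
#' `S_E(t) = exp(-Lambda_E(t))`. Net survival may exceed 1.
#'
#' Numerical conventions (documented in the methods vignette): population
#' hazards are piecewise constant over whole follow-up years (attained age
#' and calendar year advance together at anniversaries), and the weights
#' are frozen within each follow-up year at their mid-year value
#' `w = exp(H(k) + lambda_k / 2)`. Left-truncated entry is supported via an
#' optional `entry` column (years since diagnosis; default 0). Tied times:
#' events precede censorings. Variance is the Poisson-type sum
#' `sum(w^2 dN) / (sum(w Y))^2` of the weighted excess-hazard increments.
#'
#' @param records validated [as_records()] data frame; an optional `entry`
#'   column gives delayed-entry times (must be `< futime`).
#' @param life_table a `life_table` or named list keyed `"country/sex"`.
#' @param grid increasing time grid starting at 0 (years since diagnosis).
#' @return object of class `net_survival_curve`: data frame with columns
#'   `time`, `estimate` (net survival fraction), `variance` (of the
#'   estimate), `cum_excess_hazard`, `var_cum_excess_hazard`, `n_risk`.
#' @examples
#' rec <- as_records(data.frame(id = 1:3, country = "NO", sex = "male",
#'   age_dx = c(60, 70, 55), dx_year = 2000,
#'   futime = c(1, 3, 5), status = c("died", "died", "censored")))
#' pohar_perme(rec, zero_life_table(), grid = 0:5)
#' @export
pohar_perme <- function(records, life_table, grid = seq(0, 5, by = 0.25)) {
  records <- as_records(records)
  if (nrow(records) == 0) stop("pohar_perme(): no records")
  if (grid[1] != 0 || is.unsorted(grid, strictly = TRUE))
    stop("pohar_perme(): grid must be strictly increasing and start at 0")
  entry <- if ("entry" %in% names(records)) records$entry else
    rep(0, nrow(records))
  if (any(entry < 0) || any(entry >= records$futime))
    stop("pohar_perme(): entry times must satisfy 0 <= entry < futime")
  tmax <- max(grid)
  K <- max(ceiling(tmax), 1L)
  lam <- annual_pop_hazards(records, life_table, K)
  Mstrict <- outer(seq_len(K), seq_len(K), "<") * 1   # H before year k
  Hbefore <- lam %*% Mstrict
  wmat <- exp(Hbefore + 0.5 * lam)        # n x K, weight used within year k

  Tt <- records$futime
  died <- records$status == "died"

  ev_t <- numeric(0); ev_jump <- numeric(0); ev_var <- numeric(0)
  iv_end <- numeric(0); iv_val <- numeric(0)

  base_pts <- sort(unique(c(grid, 0:K, entry[entry < tmax],
                            Tt[Tt <= tmax])))
  for (k in seq_len(K) - 1L) {
    ylo <- k; yhi <- min(k + 1, tmax)
    if (ylo >= yhi) break
    P <- base_pts[base_pts >= ylo & base_pts <= yhi]
    w <- wmat[, k + 1L]
    wl <- w * lam[, k + 1L]
    e_eff <- pmax(entry, ylo)
    # subjects already exited by the year start never contribute here
    ei <- match(e_eff, P)
    ei[e_eff > yhi | Tt <= ylo] <- NA
    xi <- rep(NA_integer_, length(Tt))
    in_year_exit <- Tt > ylo & Tt <= yhi & !is.na(ei)
    xi[in_year_exit] <- match(Tt[in_year_exit], P)
    np <- length(P)
    ent_le <- cumsum(tab_sum(ei, w, np))
    ext_le <- cumsum(tab_sum(xi, w, np))
    ent_le_wl <- cumsum(tab_sum(ei, wl, np))
    ext_le_wl <- cumsum(tab_sum(xi, wl, np))
    # interval (P[p], P[p+1]): at-risk weight sums at left endpoint
    if (np > 1) {
      p <- seq_len(np - 1)
      Sw <- ent_le[p] - ext_le[p]
      Swl <- ent_le_wl[p] - ext_le_wl[p]
      dt <- diff(P)
      contrib <- ifelse(Sw > 0, Swl / Sw * dt, 0)
      iv_end <- c(iv_end, P[-1]); iv_val <- c(iv_val, contrib)
    }
    # deaths at tau in (ylo, yhi]
    dsel <- died & Tt > ylo & Tt <= yhi
    if (any(dsel)) {
      di <- match(Tt[dsel], P)
      wd <- tab_sum(di, w[dsel], np)
      wd2 <- tab_sum(di, (w^2)[dsel], np)
      dp <- which(wd > 0)            # always >= 2: deaths lie in (ylo, yhi]
      SW <- ent_le[dp - 1] - ext_le[dp - 1]       # e < tau and T >= tau
      ev_t <- c(ev_t, P[dp])
      ev_jump <- c(ev_jump, wd[dp] / SW)
      ev_var <- c(ev_var, wd2[dp] / SW^2)
    }
  }

  Lam <- vapply(grid, function(g)
    sum(ev_jump[ev_t <= g]) - sum(iv_val[iv_end <= g]), numeric(1))
  V <- vapply(grid, function(g) sum(ev_var[ev_t <= g]), numeric(1))
  nrisk <- vapply(grid, function(g) sum(entry <= g & Tt >= g), numeric(1))
  est <- exp(-Lam)
  out <- data.frame(time = grid, estimate = est, variance = est^2 * V,
                    cum_excess_hazard = Lam, var_cum_excess_hazard = V,
                    n_risk = nrisk)
  class(out) <- c("net_survival_curve", "data.frame")
  attr(out, "n") <- nrow(records)
  out
}

# sum `val` into bins given by index vector `idx` (NAs dropped), length np
tab_sum <- function(idx, val, np) {
  out <- numeric(np)
  keep <- !is.na(idx)
  if (!any(keep)) return(out)
  agg <- rowsum(val[keep], idx[keep])
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.net_survival_curve <- function(x, ...) {
  cat("<net_survival_curve> n =", attr(x, "n"), "subjects,",
      nrow(x), "grid points, S_E(max t) =",
      signif(x$estimate[nrow(x)], 4), "\n")
  invisible(x)
}
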