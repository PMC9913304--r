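# Brute-force oracle for the Pohar Perme estimator: explicit loops over a
# sorted event-time partition, implementing the same definitional scheme
# as the package (annual population hazards advancing at follow-up
# anniversaries, weights frozen at mid-follow-up-year) via an independent
# code path. Only intended for tiny cohorts.
pp_oracle <- function(records, life_table, grid) {
  entry <- if ("entry" %in% names(records)) records$entry else
    rep(0, nrow(records))
  tmax <- max(grid)
  K <- max(ceiling(tmax), 1)
  n <- nrow(records)
  lam <- matrix(0, n, K)
  for (i in 1:n) for (k in 0:(K - 1)) {
    lt <- if (inherits(life_table, "life_table")) life_table else
      life_table[[paste(records$country[i], records$sex[i], sep = "/")]]
    lam[i, k + 1] <- lt_hazard(lt, floor(records$dx_year[i]) + k,
                               floor(records$age_dx[i]) + k)
  }
  w <- matrix(0, n, K)
  for (i in 1:n) for (k in 1:K)
    w[i, k] <- exp(sum(lam[i, seq_len(k - 1)]) + 0.5 * lam[i, k])
  Tt <- records$futime
  died <- records$status == "died"
  pts <- sort(unique(c(grid, 0:K, entry[entry < tmax], Tt[Tt <= tmax])))
  pts <- pts[pts <= tmax]
  Lam <- 0; V <- 0
  outL <- numeric(length(grid)); outV <- numeric(length(grid))
  for (m in seq_len(length(pts) - 1)) {
    a <- pts[m]; b <- pts[m + 1]
    k <- floor(a) + 1
    Sw <- 0; Swl <- 0
    for (i in 1:n) if (entry[i] <= a && Tt[i] >= b) {
      Sw <- Sw + w[i, k]
      Swl <- Swl + w[i, k] * lam[i, k]
    }
    if (Sw > 0) Lam <- Lam - Swl / Sw * (b - a)
    kb <- ceiling(b)                       # weight year for a death at b
    SW <- 0; wd <- 0; wd2 <- 0
    for (i in 1:n) {
      if (entry[i] < b && Tt[i] >= b) SW <- SW + w[i, kb]
      if (died[i] && Tt[i] == b) {
        wd <- wd + w[i, kb]
        wd2 <- wd2 + w[i, kb]^2
      }
    }
    if (wd > 0) {
      Lam <- Lam + wd / SW
      V <- V + wd2 / SW^2
    }
    gi <- which(grid == b)
    if (length(gi)) {
      outL[gi] <- Lam
      outV[gi] <- V
    }
  }
  list(estimate = exp(-outL), cum_excess_hazard = outL,
       var_cum_excess_hazard = outV)
}

# random small cohort for oracle-equivalence tests
random_cohort <- function(n, seed) {
  set.seed(seed)
  as_records(data.frame(
    id = seq_len(n), country = "NO", sex = "male",
    age_dx = stats::runif(n, 40, 85),
    dx_year = stats::runif(n, 1975, 2010),
    futime = round(stats::runif(n, 0.05, 6), 3),
    status = sample(c("died", "censored"), n, replace = TRUE)))
}

# synthetic life table with moderate old-age mortality, wide span
test_life_table <- function() {
  make_life_table("NO", "male", 1960:2030, c(2e-3, 1e-4, 0.08))
}

# hand-built posterior_curveset whose draws are exact linear functions
# f_d(t) = a_d + b_d * (t - t0); degenerate (zero-variance) posteriors are
# allowed and give point-mass credible intervals
linear_curveset <- function(grid, a, b, group = "G", metric = "5y") {
  t0 <- grid[1]
  f <- outer(a, rep(1, length(grid))) + outer(b, grid - t0)
  d1 <- outer(b, rep(1, length(grid)))
  d2 <- matrix(0, length(a), length(grid))
  posterior_curveset(metric, grid,
                     stats::setNames(list(list(f = f, d1 = d1, d2 = d2)),
                                     group))
}
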