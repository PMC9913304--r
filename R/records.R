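#' Individual-level registry records
#'
#' Records are plain data frames with columns `id`, `country`, `sex`,
#' `age_dx` (years at diagnosis, in [0, 89]), `dx_year` (decimal calendar
#' year), `futime` (years of follow-up, > 0) and `status`
#' (`"died"` / `"censored"`). [as_records()] validates an existing data
#' frame; [read_records()] / [write_records()] use the interchange CSV
#' dialect (`id,country,sex,age_dx,dx_date,futime_years,status` with
#' ISO-8601 diagnosis dates and status in `dead`/`censored`).
#'
#' @param df data frame carrying the columns above.
#' @param max_age maximum admissible whole age at diagnosis (default 89;
#'   continuous ages below `max_age + 1` belong to the top band).
#' @return validated data frame of class `c("survtrend_records","data.frame")`.
#' @export
as_records <- function(df, max_age = 89) {
  need <- c("id", "country", "sex", "age_dx", "dx_year", "futime", "status")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("as_records(): missing columns: ", paste(miss, collapse = ", "))
  if (any(df$age_dx < 0 | df$age_dx >= max_age + 1))
    stop("as_records(): age_dx outside [0, ", max_age, "]")
  if (any(df$futime <= 0))
    stop("as_records(): follow-up must be positive")
  if (!all(df$status %in% c("died", "censored")))
    stop("as_records(): status must be 'died' or 'censored'")
  class(df) <- unique(c("survtrend_records", class(df)))
  df
}

#' @rdname as_records
#' @param path CSV path in the interchange dialect.
#' @export
read_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "country", "sex", "age_dx", "dx_date", "futime_years",
            "status")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_records(): missing columns: ", paste(miss, collapse = ", "))
  dx <- as.Date(d$dx_date)
  if (anyNA(dx)) stop("read_records(): unparseable dx_date values")
  year <- as.integer(format(dx, "%Y"))
  start <- as.Date(paste0(year, "-01-01"))
  len <- as.numeric(as.Date(paste0(year + 1, "-01-01")) - start)
  dx_year <- year + as.numeric(dx - start) / len
  status <- ifelse(d$status == "dead", "died", d$status)
  as_records(data.frame(id = d$id, country = d$country, sex = d$sex,
                        age_dx = d$age_dx, dx_year = dx_year,
                        futime = d$futime_years, status = status,
                        stringsAsFactors = FALSE))
}

#' @rdname as_records
#' @param records validated records to serialize.
#' @export
write_records <- function(records, path) {
  records <- as_records(records)
  year <- floor(records$dx_year)
  start <- as.Date(paste0(year, "-01-01"))
  len <- as.numeric(as.Date(paste0(year + 1, "-01-01")) - start)
  dx_date <- start + round((records$dx_year - year) * len)
  utils::write.csv(
    data.frame(id = records$id, country = records$country,
               sex = records$sex, age_dx = records$age_dx,
               dx_date = format(dx_date, "%Y-%m-%d"),
               futime_years = records$futime,
               status = ifelse(records$status == "died", "dead", "censored")),
    path, row.names = FALSE)
  invisible(path)
}

# Resolve the life table for each record: `life_table` may be a single
# life_table (applied to everyone) or a named list keyed "country/sex".
resolve_life_tables <- function(records, life_table) {
  if (inherits(life_table, "life_table"))
    return(rep(list(life_table), nrow(records)))
  key <- paste(records$country, records$sex, sep = "/")
  out <- life_table[key]
  if (any(vapply(out, is.null, logical(1))))
    stop("no life table supplied for group(s): ",
         paste(unique(key[vapply(out, is.null, logical(1))]), collapse = ", "))
  out
}

# Per-subject annual population hazards for follow-up years 0..(nyears-1).
# Convention (documented in the methods vignette): during follow-up year k,
# attained age = floor(age_dx) + k (capped at the table's top age) and
# calendar year = floor(dx_year) + k, so the hazard is piecewise constant
# over whole years of follow-up.
annual_pop_hazards <- function(records, life_table, nyears) {
  n <- nrow(records)
  lam <- matrix(0, n, nyears)
  a0 <- floor(records$age_dx)
  y0 <- floor(records$dx_year)
  if (inherits(life_table, "life_table")) {
    for (k in seq_len(nyears) - 1L)
      lam[, k + 1L] <- lt_hazard(life_table, y0 + k, a0 + k)
    return(lam)
  }
  lts <- resolve_life_tables(records, life_table)
  grp <- paste(records$country, records$sex, sep = "/")
  for (g in unique(grp)) {
    i <- which(grp == g)
    lt <- lts[[i[1]]]
    for (k in seq_len(nyears) - 1L)
      lam[i, k + 1L] <- lt_hazard(lt, y0[i] + k, a0[i] + k)
  }
  lam
}

# Cumulative expected hazard H_i(t) for each record at a common time t
# (piecewise-constant annual hazards). `lam` from annual_pop_hazards().
cum_expected_hazard <- function(lam, t) {
  k <- floor(t)
  full <- if (k >= 1) rowSums(lam[, seq_len(min(k, ncol(lam))), drop = FALSE]) else 0
  frac <- if (k < ncol(lam)) (t - k) * lam[, k + 1L] else 0
  full + frac
}

#' Expected (background) survival from a life table
#'
#' Integrates the population hazard along follow-up for one subject:
#' `S_P(t) = exp(-integral of lambda_P)`, with attained age and calendar
#' year advancing together at whole years of follow-up.
#'
#' @param record one-row data frame with `age_dx`, `dx_year` (and
#'   `country`, `sex` when `life_table` is a keyed list).
#' @param life_table a [make_life_table()] object or named list keyed
#'   `"country/sex"`.
#' @param t follow-up times in years (vectorized).
#' @return expected survival fractions in (0, 1]; `expected_survival(, 0) == 1`.
#' @export
expected_survival <- function(record, life_table, t) {
  stopifnot(nrow(record) == 1, all(t >= 0))
  nyears <- max(ceiling(max(t)), 1)
  lam <- annual_pop_hazards(record, life_table, nyears)
  vapply(t, function(ti) exp(-cum_expected_hazard(lam, ti)), numeric(1))
}
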