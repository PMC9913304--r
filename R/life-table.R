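#' Population life tables
#'
#' A `life_table` stores annual all-cause mortality hazards (per person-year)
#' for one country x sex, indexed by calendar year and whole age. It supplies
#' the expected (background) survival used by relative/net survival
#' estimation. [make_life_table()] builds a synthetic table from a
#' Gompertz-Makeham law, hazard(age) = a + b * exp(c * age), optionally
#' improving by a fixed factor per calendar year; real tables can be read
#' from CSV with [read_life_table()].
#'
#' @param country,sex labels stored with the table.
#' @param years integer calendar years the table spans.
#' @param makeham_params numeric triple `c(a, b, c)` with `a >= 0`,
#'   `b >= 0`, `c >= 0` (b or c may be zero, giving constant hazard).
#' @param ages integer ages covered (default 0:99).
#' @param annual_improvement multiplicative hazard change per calendar year
#'   relative to the first year (e.g. 0.995 for a 0.5%/yr decline);
#'   default 1 (no secular change). Deterministic: no randomness anywhere.
#' @return object of class `life_table` with fields `country`, `sex`,
#'   `years`, `ages` and `hazard` (matrix years x ages).
#' @examples
#' lt <- make_life_table("NO", "male", 1971:2020, c(5e-4, 3e-5, 0.09))
#' lt_hazard(lt, 2000, 70)
#' @export
make_life_table <- function(country, sex, years,
                            makeham_params = c(5e-4, 3e-5, 0.09),
                            ages = 0:99, annual_improvement = 1) {
  p <- as.numeric(makeham_params)
  if (length(p) != 3 || any(!is.finite(p)))
    stop("make_life_table(): makeham_params must be a finite numeric triple")
  if (p[1] < 0 || p[2] < 0 || (p[2] > 0 && p[3] < 0))
    stop("make_life_table(): makeham_params must satisfy a >= 0, b >= 0, ",
         "and c >= 0 whenever b > 0")
  if (!is.finite(annual_improvement) || annual_improvement <= 0)
    stop("make_life_table(): annual_improvement must be a positive finite scalar")
  years <- sort(unique(as.integer(years)))
  ages <- sort(unique(as.integer(ages)))
  base <- p[1] + p[2] * exp(p[3] * ages)
  fac <- annual_improvement^(years - years[1])
  hazard <- outer(fac, base)
  dimnames(hazard) <- list(year = years, age = ages)
  structure(list(country = country, sex = sex, years = years, ages = ages,
                 hazard = hazard),
            class = "life_table")
}

#' Look up annual mortality hazards
#'
#' @param lt a `life_table`.
#' @param year,age integer vectors (recycled to common length). Ages above
#'   the table's last age are capped at it (open-ended top age class);
#'   years or negative ages outside the span raise an error naming the
#'   missing cell.
#' @return numeric hazard vector (per person-year).
#' @export
lt_hazard <- function(lt, year, age) {
  stopifnot(inherits(lt, "life_table"))
  n <- max(length(year), length(age))
  year <- rep_len(as.integer(year), n)
  age <- rep_len(as.integer(age), n)
  age <- pmin(age, max(lt$ages))
  yi <- match(year, lt$years)
  ai <- match(age, lt$ages)
  bad <- is.na(yi) | is.na(ai)
  if (any(bad)) {
    k <- which(bad)[1]
    stop("lt_hazard(): no life-table cell for (year=", year[k],
         ", age=", age[k], ") in table ", lt$country, "/", lt$sex)
  }
  lt$hazard[cbind(yi, ai)]
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> ", x$country, "/", x$sex, ", years ",
      min(x$years), "-", max(x$years), ", ages ", min(x$ages), "-",
      max(x$ages), "\n", sep = "")
  invisible(x)
}

#' Read / write life tables as CSV
#'
#' Dialect: UTF-8, header required, columns `country,sex,year,age,hazard`
#' (one row per cell).
#'
#' @param path CSV file path.
#' @return `read_life_table()` returns a list of `life_table` objects, one
#'   per country x sex present in the file, named `"country/sex"`.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("country", "sex", "year", "age", "hazard")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_life_table(): missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(d$hazard)) || any(d$hazard < 0))
    stop("read_life_table(): hazards must be finite and non-negative")
  split_d <- split(d, paste(d$country, d$sex, sep = "/"))
  lapply(split_d, function(s) {
    years <- sort(unique(s$year)); ages <- sort(unique(s$age))
    h <- matrix(NA_real_, length(years), length(ages),
                dimnames = list(year = years, age = ages))
    h[cbind(match(s$year, years), match(s$age, ages))] <- s$hazard
    if (anyNA(h))
      stop("read_life_table(): incomplete year x age grid for ",
           s$country[1], "/", s$sex[1])
    structure(list(country = s$country[1], sex = s$sex[1], years = years,
                   ages = ages, hazard = h),
              class = "life_table")
  })
}

#' @rdname read_life_table
#' @param lt a `life_table` (or list of them) to serialize.
#' @export
write_life_table <- function(lt, path) {
  lts <- if (inherits(lt, "life_table")) list(lt) else lt
  rows <- do.call(rbind, lapply(lts, function(x) {
    g <- expand.grid(year = x$years, age = x$ages)
    data.frame(country = x$country, sex = x$sex, year = g$year, age = g$age,
               hazard = as.vector(x$hazard[cbind(match(g$year, x$years),
                                                 match(g$age, x$ages))]))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Zero-mortality life table (testing convenience)
#'
#' @inheritParams make_life_table
#' @export
zero_life_table <- function(country = "ZZ", sex = "all", years = 1960:2030,
                            ages = 0:99) {
  make_life_table(country, sex, years, c(0, 0, 0), ages = ages)
}
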