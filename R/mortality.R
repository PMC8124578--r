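#' Mortality schedule by smoking status
#'
#' Annual death probabilities for never and current smokers by gender,
#' single age and calendar year. Former-smoker rates are not stored: they
#' are derived on demand from the smoker RR through the years-quit ladder
#' (see [former_death_rate()]).
#'
#' @param d_never,d_current Numeric arrays with dimensions gender (2) x
#'   age (100) x year; all values in \[0, 1\] with
#'   `d_current >= d_never` cellwise.
#' @param years Integer vector of calendar years covered (third dimension).
#' @return An object of class `mortality_schedule`.
#' @export
mortality_schedule <- function(d_never, d_current, years) {
  years <- as.integer(years)
  dn <- list(gender = GENDERS, age = as.character(AGES),
             year = as.character(years))
  for (nm in c("d_never", "d_current")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), c(2L, 100L, length(years)))) {
      stop(nm, " must be a 2 x 100 x ", length(years), " array")
    }
    if (any(a < 0 | a > 1)) stop(nm, " must lie in [0, 1]")
  }
  if (any(d_current < d_never)) {
    stop("d_current must be >= d_never in every cell")
  }
  dimnames(d_never) <- dn
  dimnames(d_current) <- dn
  structure(list(d_never = d_never, d_current = d_current, years = years),
            class = "mortality_schedule")
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat("<mortality_schedule> years", min(x$years), "-", max(x$years), "\n")
  invisible(x)
}

#' Smoker relative risk implied by a mortality schedule
#'
#' @param mortality A [mortality_schedule()].
#' @param year Calendar year.
#' @return Matrix (gender x age) of `d_current / d_never`; NA where
#'   `d_never` is zero.
#' @export
smoker_rr <- function(mortality, year) {
  r <- rates_for_year(mortality, year)
  rr <- r$d_current / r$d_never
  rr[r$d_never == 0] <- NA_real_
  rr
}

# Rates for one calendar year, as gender x age matrices for every status.
# Returns list(d_never, d_current, d_former = list by bin).
rates_for_year <- function(mortality, year, ladder = rr_ladder()) {
  yk <- as.character(year)
  if (!yk %in% dimnames(mortality$d_never)$year) {
    stop("mortality schedule does not cover year ", year)
  }
  dn <- mortality$d_never[, , yk]
  dc <- mortality$d_current[, , yk]
  d_former <- lapply(QUIT_BINS, function(b) {
    m <- dn
    pos <- dn > 0
    m[pos] <- former_death_rate(dn[pos], dc[pos], b, ladder)
    # d_never == 0 forces d_current == 0 (validated), so former rate is 0
    m[!pos] <- 0
    m
  })
  names(d_former) <- QUIT_BINS
  list(d_never = dn, d_current = dc, d_former = d_former)
}

#' Constant-in-time mortality schedule from age profiles
#'
#' Convenience constructor: replicates gender x age rate matrices across a
#' span of years.
#'
#' @param d_never,d_current Matrices (gender x age) of annual death
#'   probabilities.
#' @param years Years to cover.
#' @return A [mortality_schedule()].
#' @export
constant_mortality <- function(d_never, d_current, years) {
  mk <- function(m) array(rep(m, length(years)),
                          dim = c(2, 100, length(years)))
  mortality_schedule(mk(d_never), mk(d_current), years)
}

#' Read a mortality schedule from a delimited table
#'
#' Expects a CSV with columns `year, gender, age, status, value`, where
#' `status` is `never` or `current` and `value` is the annual death
#' probability. Every year x gender x age x status cell must be present.
#'
#' @param path Path to the CSV file.
#' @return A [mortality_schedule()].
#' @export
read_mortality_schedule <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "gender", "age", "status", "value")
  if (!identical(sort(names(d)), sort(need))) {
    stop("mortality table must have exactly the columns: ",
         paste(need, collapse = ", "))
  }
  if (!all(d$status %in% c("never", "current"))) {
    stop("mortality status must be 'never' or 'current'")
  }
  years <- sort(unique(d$year))
  grid <- expand.grid(year = years, gender = GENDERS, age = AGES,
                      status = c("never", "current"))
  if (nrow(d) != nrow(grid)) {
    stop("mortality table must cover every year x gender x age x status cell")
  }
  arr <- function(status) {
    a <- array(NA_real_, dim = c(2, 100, length(years)),
               dimnames = list(GENDERS, as.character(AGES),
                               as.character(years)))
    dd <- d[d$status == status, ]
    a[cbind(dd$gender, as.character(dd$age), as.character(dd$year))] <- dd$value
    a
  }
  mortality_schedule(arr("never"), arr("current"), years)
}
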