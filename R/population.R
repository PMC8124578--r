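#' Population state by gender, single age and smoking status
#'
#' The model population for one calendar year: fractional person counts
#' indexed by gender (male, female), single year of age (0-99) and smoking
#' status (never, current, and former smokers split by years-quit bin).
#' Counts are deterministic expected values, not stochastic agents.
#'
#' @param year Calendar year of the state.
#' @param counts A numeric array with dimensions gender (2) x age (100) x
#'   status (8), dimnames as produced by [empty_population()]. All counts
#'   must be non-negative.
#' @param min_smoking_age Youngest age at which current/former smokers may
#'   exist (default 10, the first age of net initiation).
#' @return An object of class `population_state`.
#' @export
population_state <- function(year, counts, min_smoking_age = 10) {
  dn <- list(gender = GENDERS, age = as.character(AGES), status = STATUSES)
  if (!is.array(counts) || !identical(dim(counts), c(2L, 100L, 8L))) {
    stop("counts must be a 2 x 100 x 8 array (gender x age x status)")
  }
  dimnames(counts) <- dn
  if (any(counts < 0)) stop("population counts must be non-negative")
  if (min_smoking_age > 0) {
    young <- counts[, AGES < min_smoking_age, setdiff(STATUSES, "never"),
                    drop = FALSE]
    if (any(young > 0)) {
      stop("current/former smokers present below the first initiation age")
    }
  }
  structure(list(year = as.integer(year), counts = counts,
                 min_smoking_age = min_smoking_age),
            class = "population_state")
}

#' Empty population state
#'
#' @inheritParams population_state
#' @return A `population_state` with all counts zero.
#' @export
empty_population <- function(year) {
  counts <- array(0, dim = c(2, 100, 8),
                  dimnames = list(gender = GENDERS, age = as.character(AGES),
                                  status = STATUSES))
  population_state(year, counts)
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> year", x$year,
      "| total", format(round(total_population(x))),
      "| adult smoking prevalence",
      sprintf("%.1f%% (m) / %.1f%% (f)\n",
              100 * smoking_prevalence(x, gender = "male"),
              100 * smoking_prevalence(x, gender = "female")))
  invisible(x)
}

#' Total population of a state
#'
#' @param state A [population_state()].
#' @param gender Optional gender filter.
#' @param ages Optional vector of single ages to include.
#' @return Total person count.
#' @export
total_population <- function(state, gender = NULL, ages = AGES) {
  g <- gender %||% GENDERS
  sum(state$counts[g, as.character(ages), , drop = FALSE])
}

#' Smoking prevalence from a population state
#'
#' Current-smoker prevalence over an age range, derived from counts.
#'
#' @inheritParams total_population
#' @param ages Ages to include (default 18-99, the adult range).
#' @param status Status (or statuses) counted in the numerator
#'   (default `"current"`).
#' @return Prevalence in \[0, 1\] (NaN if the denominator is empty).
#' @export
smoking_prevalence <- function(state, ages = 18:99, gender = NULL,
                               status = "current") {
  g <- gender %||% GENDERS
  num <- sum(state$counts[g, as.character(ages), status, drop = FALSE])
  den <- sum(state$counts[g, as.character(ages), , drop = FALSE])
  num / den
}

#' Prevalence by gender and reporting age group
#'
#' @param state A [population_state()].
#' @param groups Named list of age vectors (default the reporting groups
#'   18+, 18-24, 25-44, 45-64, 65+).
#' @return A data frame: year, gender, age_group, prevalence.
#' @export
prevalence_table <- function(state, groups = AGE_GROUPS) {
  rows <- expand.grid(gender = GENDERS, age_group = names(groups),
                      stringsAsFactors = FALSE)
  rows$year <- state$year
  rows$prevalence <- mapply(function(g, ag) {
    smoking_prevalence(state, ages = groups[[ag]], gender = g)
  }, rows$gender, rows$age_group)
  rows[, c("year", "gender", "age_group", "prevalence")]
}

#' @export
as.data.frame.population_state <- function(x, ...) {
  d <- as.data.frame.table(x$counts, responseName = "count",
                           stringsAsFactors = FALSE)
  d$age <- as.integer(d$age)
  d$year <- x$year
  d[, c("year", "gender", "age", "status", "count")]
}

#' Read a population state from a delimited table
#'
#' Expects a CSV with columns `year, gender, age, status, value` (strictly
#' validated); one year per file. Missing cells default to zero.
#'
#' @param path Path to the CSV file.
#' @return A [population_state()].
#' @export
read_population_state <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "gender", "age", "status", "value")
  if (!identical(sort(names(d)), sort(need))) {
    stop("population table must have exactly the columns: ",
         paste(need, collapse = ", "))
  }
  if (length(unique(d$year)) != 1) stop("one calendar year per file")
  bad <- !d$gender %in% GENDERS | !d$status %in% STATUSES |
    !d$age %in% AGES
  if (any(bad)) stop("invalid gender/age/status values in population table")
  st <- empty_population(d$year[1])
  counts <- st$counts
  counts[cbind(d$gender, as.character(d$age), d$status)] <- d$value
  population_state(d$year[1], counts)
}
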