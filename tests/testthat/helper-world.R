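# Shared toy-world builders for the test suite. All helpers are
# deterministic given their arguments.

toy_ages <- function() 28:32

# A small population with mass on a handful of adult ages only.
toy_state <- function(year = 2000, ages = toy_ages(), seed = NULL) {
  st <- empty_population(year)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    fill <- function() matrix(runif(2 * length(ages), 10, 1000),
                              2, length(ages))
  } else {
    fill <- function() matrix(100, 2, length(ages))
  }
  idx <- as.character(ages)
  st$counts[, idx, "never"] <- fill()
  st$counts[, idx, "current"] <- fill()
  for (b in paste0("former_", quit_bins()$bin)) {
    st$counts[, idx, b] <- fill() / 10
  }
  population_state(year, st$counts)
}

# Flat mortality over the given years: d_never = dn, d_current = dc.
toy_mortality <- function(years, dn = 0.01, dc = 0.02) {
  constant_mortality(matrix(dn, 2, 100), matrix(dc, 2, 100), years)
}

# Random-but-bounded transition rates on all ages.
toy_rates <- function(seed = 1, peak_age = c(male = 22, female = 25)) {
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  transition_rates(
    net_initiation = matrix(runif(200, 0, 0.2), 2, 100),
    cessation = matrix(runif(200, 0, 0.2), 2, 100),
    relapse = array(runif(1200, 0, 0.2), dim = c(2, 100, 6)),
    peak_age = peak_age
  )
}
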