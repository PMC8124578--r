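#' Births and net migration drivers
#'
#' @param births Matrix (gender x year) of newborn counts, or NULL for
#'   none. Columns named by calendar year.
#' @param net_migration Array (gender x age x year) of net migrants (may
#'   be negative), or NULL for none.
#' @param years Years covered.
#' @return An object of class `demography_drivers`.
#' @export
demography_drivers <- function(births = NULL, net_migration = NULL,
                               years) {
  years <- as.integer(years)
  if (is.null(births)) {
    births <- matrix(0, 2, length(years))
  }
  dimnames(births) <- list(GENDERS, as.character(years))
  if (any(births < 0)) stop("births must be non-negative")
  if (is.null(net_migration)) {
    net_migration <- array(0, dim = c(2, 100, length(years)))
  }
  dimnames(net_migration) <- list(GENDERS, as.character(AGES),
                                  as.character(years))
  structure(list(births = births, net_migration = net_migration,
                 years = years),
            class = "demography_drivers")
}

# Survivors and deaths for one year of status-specific mortality.
# Returns list(survivors = counts array, deaths = counts array).
apply_mortality <- function(counts, rates) {
  dr <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  dr[, , "never"] <- rates$d_never
  dr[, , "current"] <- rates$d_current
  for (b in QUIT_BINS) dr[, , paste0("former_", b)] <- rates$d_former[[b]]
  deaths <- counts * dr
  list(survivors = counts - deaths, deaths = deaths)
}

# Advance former smokers one years-quit bin boundary. Assuming a uniform
# distribution of quit times within each bin, the fraction leaving a bin
# of width w each year is 1/w; the terminal bin is absorbing.
advance_quit_bins <- function(counts) {
  former <- counts[, , FORMER_STATUSES, drop = FALSE]
  out <- former
  for (i in seq_along(QUIT_BINS)) {
    w <- QUIT_BIN_WIDTHS[i]
    if (!is.finite(w)) next
    moving <- former[, , i] / w
    out[, , i] <- out[, , i] - moving
    out[, , i + 1] <- out[, , i + 1] + moving
  }
  counts[, , FORMER_STATUSES] <- out
  counts
}

# Shift every cell up one year of age; the terminal age (99) is closed:
# survivors reaching it remain there until death. Newborns enter at age 0
# as never smokers; net migrants adopt the smoking-status mix of their
# destination age/gender cell (empty cells receive never smokers).
age_and_migrate <- function(counts, year_next, drivers = NULL) {
  aged <- array(0, dim = dim(counts), dimnames = dimnames(counts))
  aged[, 2:100, ] <- counts[, 1:99, ]
  aged[, 100, ] <- aged[, 100, ] + counts[, 100, ]
  if (!is.null(drivers)) {
    yk <- as.character(year_next)
    if (!yk %in% colnames(drivers$births)) {
      stop("demography drivers do not cover year ", year_next)
    }
    aged[, 1, "never"] <- aged[, 1, "never"] + drivers$births[, yk]
    mig <- drivers$net_migration[, , yk]
    if (any(mig != 0)) {
      for (g in 1:2) for (a in 1:100) {
        m <- mig[g, a]
        if (m == 0) next
        tot <- sum(aged[g, a, ])
        share <- if (tot > 0) aged[g, a, ] / tot else
          setNames(c(1, rep(0, 7)), STATUSES)
        newcell <- aged[g, a, ] + m * share
        if (any(newcell < -1e-9)) {
          stop("net out-migration would drive a population cell negative")
        }
        aged[g, a, ] <- pmax(newcell, 0)
      }
    }
  }
  aged
}

#' Evolve a population one year (mortality, aging, births, migration)
#'
#' Applies status- and quit-bin-specific mortality, advances every cell
#' one year of age (the terminal age 99 is closed: survivors stay there),
#' moves surviving former smokers across years-quit bin boundaries, adds
#' newborns as never smokers, and applies net migration proportionally
#' across smoking statuses. Smoking-status transitions are handled
#' separately by [markov_step()].
#'
#' @param state A [population_state()] for year y.
#' @param mortality A [mortality_schedule()] covering year y.
#' @param drivers Optional [demography_drivers()] covering year y+1.
#' @param ladder An [rr_ladder()].
#' @return The [population_state()] for year y+1, with a `deaths`
#'   attribute (gender x age x status array of deaths during the year).
#' @export
#' @examples
#' st <- empty_population(2000)
#' st$counts["male", "30", "never"] <- 1000
#' dn <- matrix(0.1, 2, 100); dc <- matrix(0.2, 2, 100)
#' ms <- constant_mortality(dn, dc, 2000:2001)
#' st2 <- evolve_population(st, ms)
#' st2$counts["male", "31", "never"]  # 900 survivors, aged one year
evolve_population <- function(state, mortality, drivers = NULL,
                              ladder = rr_ladder()) {
  rates <- rates_for_year(mortality, state$year, ladder)
  m <- apply_mortality(state$counts, rates)
  counts <- advance_quit_bins(m$survivors)
  counts <- age_and_migrate(counts, state$year + 1L, drivers)
  out <- population_state(state$year + 1L, counts,
                          min_smoking_age = 0)
  out$min_smoking_age <- state$min_smoking_age
  attr(out, "deaths") <- m$deaths
  out
}
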