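#' Smoking-status transition rates
#'
#' First-order Markov rates: net initiation (never to current, applied up
#' to the gender-specific peak-prevalence age), cessation (current to
#' former, applied from the age after the peak), and relapse (former to
#' current, by years-quit bin). Net initiation is initiation net of early
#' cessation; the cessation measure is understood as quit in the last
#' year but not the last three months (a labelling contract on input
#' data).
#'
#' @param net_initiation Matrix (gender x age) of annual probabilities;
#'   used only for ages up to `peak_age`.
#' @param cessation Matrix (gender x age) of annual quit probabilities;
#'   used only for ages strictly above `peak_age`.
#' @param relapse Array (gender x age x quit bin) of annual relapse
#'   probabilities.
#' @param peak_age Named vector: age at which smoking prevalence peaks,
#'   by gender (defaults 22 for males, 25 for females).
#' @return An object of class `transition_rates`.
#' @export
transition_rates <- function(net_initiation = matrix(0, 2, 100),
                             cessation = matrix(0, 2, 100),
                             relapse = array(0, dim = c(2, 100, 6)),
                             peak_age = c(male = 22, female = 25)) {
  dimnames(net_initiation) <- list(GENDERS, as.character(AGES))
  dimnames(cessation) <- list(GENDERS, as.character(AGES))
  dimnames(relapse) <- list(GENDERS, as.character(AGES), QUIT_BINS)
  for (nm in c("net_initiation", "cessation", "relapse")) {
    v <- get(nm)
    if (any(v < 0 | v > 1)) stop(nm, " rates must lie in [0, 1]")
  }
  if (!all(GENDERS %in% names(peak_age))) {
    stop("peak_age must be named by gender")
  }
  if (any(peak_age <= 10 | peak_age >= 99)) {
    stop("peak_age must lie strictly between 10 and 99")
  }
  structure(list(net_initiation = net_initiation, cessation = cessation,
                 relapse = relapse, peak_age = peak_age),
            class = "transition_rates")
}

#' Net initiation rates from a cross-sectional prevalence curve
#'
#' Estimates net initiation from differences in cross-sectional smoking
#' prevalence between consecutive ages:
#' `rate(a+1) = (prev(a+1) - prev(a)) / never(a)`,
#' e.g. initiation at age 16 equals the age-16 minus age-15 smoking
#' prevalence divided by the age-15 never-smoking prevalence. Rates are
#' produced for ages 11 up to the peak age (supply age 9 or 10 with zero
#' prevalence to anchor the youngest rate). Negative raw differences
#' (sampling dips in a net measure) are clipped to zero with a warning.
#'
#' @param prev Named numeric vector of current-smoking prevalence by age
#'   (names are ages; must cover consecutive ages up to `peak_age`).
#' @param never Named numeric vector of never-smoking prevalence for the
#'   same ages; must be positive below the peak age.
#' @param peak_age Last age of net initiation.
#' @return Named vector of net initiation rates by age.
#' @export
#' @examples
#' net_initiation_from_cross_section(
#'   prev = c(`15` = 0.10, `16` = 0.13),
#'   never = c(`15` = 0.88, `16` = 0.85), peak_age = 16)
net_initiation_from_cross_section <- function(prev, never, peak_age) {
  ages <- as.integer(names(prev))
  if (is.null(names(prev)) || is.null(names(never)) ||
      !identical(names(prev), names(never))) {
    stop("prev and never must be named by the same ages")
  }
  if (any(prev < 0 | prev > 1 | never < 0 | never > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  use <- ages < peak_age & (ages + 1) %in% ages
  if (any(never[use] == 0)) {
    stop("never-smoking prevalence must be positive below the peak age")
  }
  from <- which(use)
  to <- match(ages[from] + 1L, ages)
  raw <- (prev[to] - prev[from]) / never[from]
  if (any(raw < 0)) {
    warning("negative raw net-initiation difference clipped to 0 at age(s) ",
            paste(ages[to][raw < 0], collapse = ", "))
    raw <- pmax(raw, 0)
  }
  setNames(pmin(raw, 1), ages[to])
}

#' Calibration multipliers for initiation rates
#'
#' Scales net initiation rates by gender-specific multipliers (defaults
#' +30% for males, +15% for females, reflecting rising young-adult
#' smoking in the mid-1990s); cessation and relapse are unchanged.
#' Scaled rates exceeding 1 are clipped with a warning.
#'
#' @param rates A [transition_rates()].
#' @param multipliers Named positive vector by gender.
#' @return The calibrated [transition_rates()].
#' @export
apply_calibration <- function(rates,
                              multipliers = c(male = 1.30, female = 1.15)) {
  if (any(multipliers <= 0)) stop("multipliers must be positive")
  ni <- rates$net_initiation
  for (g in GENDERS) ni[g, ] <- ni[g, ] * multipliers[[g]]
  if (any(ni > 1)) {
    warning("calibrated initiation rate(s) clipped to 1")
    ni <- pmin(ni, 1)
  }
  rates$net_initiation <- ni
  rates
}

#' One year of smoking-status transitions
#'
#' Moves persons between smoking statuses within each gender/age cell:
#' never to current via net initiation (ages up to the peak age), current
#' to former (quit < 1 year bin) via cessation (ages above the peak), and
#' former to current via bin-specific relapse. All flows are computed
#' from the same starting state, so counts are conserved within each
#' cell. Policy deltas scale the base rates as
#' `effective = base * (1 + delta)`, clipped to \[0, 1\].
#'
#' @param state A [population_state()].
#' @param rates A [transition_rates()] for the same year.
#' @param deltas Optional list with numeric vectors `initiation_delta`
#'   and `cessation_delta` of length 100 (fractional rate changes by
#'   age), as produced by [schedule_to_deltas()] for one year.
#' @return The transitioned [population_state()] (same year).
#' @export
markov_step <- function(state, rates, deltas = NULL) {
  counts <- state$counts
  di <- deltas$initiation_delta %||% rep(0, 100)
  dc <- deltas$cessation_delta %||% rep(0, 100)
  for (g in GENDERS) {
    peak <- rates$peak_age[[g]]
    init <- pmin(pmax(rates$net_initiation[g, ] * (1 + di), 0), 1)
    cess <- pmin(pmax(rates$cessation[g, ] * (1 + dc), 0), 1)
    init[AGES > peak] <- 0
    cess[AGES <= peak] <- 0   # cessation starts after the last initiation age
    if (any(is.na(init)) || any(is.na(cess))) {
      stop("non-finite effective transition rate")
    }
    init_flow <- counts[g, , "never"] * init
    cess_flow <- counts[g, , "current"] * cess
    rel_flow <- counts[g, , FORMER_STATUSES] * rates$relapse[g, , ]
    counts[g, , "never"] <- counts[g, , "never"] - init_flow
    counts[g, , "current"] <- counts[g, , "current"] + init_flow -
      cess_flow + rowSums(rel_flow)
    counts[g, , FORMER_STATUSES] <- counts[g, , FORMER_STATUSES] - rel_flow
    counts[g, , "former_<1"] <- counts[g, , "former_<1"] + cess_flow
  }
  out <- state
  out$counts <- counts
  out
}
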