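#' Bundle simulation inputs
#'
#' Collects everything a scenario run needs: the initial population, the
#' mortality schedule, transition rates, optional policy deltas,
#' optional demography drivers, the quit-bin ladder and the simulated
#' year range.
#'
#' @param initial_state A [population_state()] for the first year.
#' @param mortality A [mortality_schedule()] covering all years.
#' @param transitions A [transition_rates()] object (year-invariant base
#'   rates; policy deltas supply the time variation).
#' @param deltas Optional [schedule_to_deltas()] object.
#' @param drivers Optional [demography_drivers()].
#' @param ladder An [rr_ladder()].
#' @param years Simulated calendar years (contiguous, starting at the
#'   initial state's year).
#' @return An object of class `sim_inputs`.
#' @export
sim_inputs <- function(initial_state, mortality, transitions,
                       deltas = NULL, drivers = NULL,
                       ladder = rr_ladder(),
                       years = mortality$years) {
  years <- as.integer(years)
  if (years[1] != initial_state$year) {
    stop("years must start at the initial state's year")
  }
  if (any(diff(years) != 1)) stop("years must be contiguous")
  missing_y <- setdiff(years, mortality$years)
  if (length(missing_y)) {
    stop("mortality schedule missing years: ",
         paste(missing_y, collapse = ", "))
  }
  structure(list(initial_state = initial_state, mortality = mortality,
                 transitions = transitions, deltas = deltas,
                 drivers = drivers, ladder = ladder, years = years),
            class = "sim_inputs")
}

# One year of model dynamics, in the fixed within-year order:
# mortality -> smoking-status transitions -> quit-bin advancement and
# aging (with births/migration). The first-year policy prevalence shock
# for the arrival year is applied by the caller.
step_year <- function(state, inputs, deltas_t) {
  rates_m <- rates_for_year(inputs$mortality, state$year, inputs$ladder)
  m <- apply_mortality(state$counts, rates_m)
  st <- state
  st$counts <- m$survivors
  st <- markov_step(st, inputs$transitions, deltas_t)
  counts <- advance_quit_bins(st$counts)
  counts <- age_and_migrate(counts, state$year + 1L, inputs$drivers)
  out <- population_state(state$year + 1L, counts, min_smoking_age = 0)
  out$min_smoking_age <- state$min_smoking_age
  attr(out, "deaths") <- m$deaths
  out
}

# Run the dynamics over `years`, optionally post-processing each arrived
# state (adjust_fn(state) -> state); returns the list of states.
simulate_years <- function(inputs, from_state, years, adjust_fn = NULL) {
  states <- vector("list", length(years))
  names(states) <- as.character(years)
  states[[1]] <- from_state
  peak <- inputs$transitions$peak_age
  for (i in seq_along(years)[-1]) {
    t <- years[i]
    d <- deltas_for_year(inputs$deltas, t)
    st <- step_year(states[[i - 1]], inputs, d)
    if (any(d$prevalence_shock != 0)) {
      st <- apply_prevalence_shock(st, d$prevalence_shock, peak)
    }
    if (!is.null(adjust_fn)) st <- adjust_fn(st)
    states[[i]] <- st
  }
  states
}

#' Run a scenario (e.g. the no-vaping counterfactual)
#'
#' Evolves the population deterministically over the input years:
#' status-specific mortality, Markov smoking transitions scaled by the
#' policy deltas, quit-bin advancement, aging, births/migration, and
#' first-year policy prevalence shocks. Re-running with the same inputs
#' reproduces the trajectory exactly.
#'
#' @param inputs A [sim_inputs()] bundle (or a `sim_world` from
#'   [gen_world()]).
#' @param label Scenario label.
#' @return An object of class `scenario_result`: `label`, `years`,
#'   `states` (list of yearly [population_state()]s), `prevalence`
#'   (data frame year x gender x age group), `sads` (data frame of
#'   yearly smoking-attributable deaths by gender), and the `inputs`.
#' @export
run_counterfactual <- function(inputs, label = "counterfactual") {
  inputs <- as_sim_inputs(inputs)
  states <- simulate_years(inputs, inputs$initial_state, inputs$years)
  scenario_result(label, inputs, states)
}

as_sim_inputs <- function(x) {
  if (inherits(x, "sim_inputs")) return(x)
  if (inherits(x, "sim_world")) return(x$inputs)
  stop("expected a sim_inputs or sim_world object")
}

scenario_result <- function(label, inputs, states) {
  prevalence <- do.call(rbind, lapply(states, prevalence_table))
  rownames(prevalence) <- NULL
  sads <- do.call(rbind, lapply(states, function(st) {
    s <- compute_sads(st, inputs$mortality, inputs$ladder)
    data.frame(year = st$year, gender = GENDERS, sads = unname(s),
               stringsAsFactors = FALSE)
  }))
  rownames(sads) <- NULL
  structure(list(label = label, years = inputs$years, states = states,
                 prevalence = prevalence, sads = sads, inputs = inputs),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result>", x$label, "| years", min(x$years), "-",
      max(x$years), "\n")
  p <- x$prevalence
  p <- p[p$age_group == "18+" & p$year %in% range(x$years), ]
  for (g in GENDERS) {
    pr <- p$prevalence[p$gender == g]
    cat(sprintf("  %s adult prevalence: %.1f%% -> %.1f%%\n", g,
                100 * pr[1], 100 * pr[2]))
  }
  invisible(x)
}
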