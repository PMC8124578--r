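#' Smoking-attributable deaths for one population state
#'
#' Excess deaths among current and former smokers: the number in each
#' gender/age/status cell times its excess mortality risk over never
#' smokers (`d_status - d_never`), summed over current smokers and every
#' former-smoker years-quit bin.
#'
#' @param state A [population_state()].
#' @param mortality A [mortality_schedule()] covering the state's year.
#' @param ladder An [rr_ladder()].
#' @return Named numeric vector of deaths, by gender.
#' @export
#' @examples
#' st <- empty_population(2000)
#' st$counts["male", "60", "current"] <- 1000
#' ms <- constant_mortality(matrix(0.01, 2, 100), matrix(0.02, 2, 100), 2000)
#' compute_sads(st, ms)  # 10 male SADs
compute_sads <- function(state, mortality, ladder = rr_ladder()) {
  r <- rates_for_year(mortality, state$year, ladder)
  excess <- r$d_current - r$d_never
  out <- rowSums(state$counts[, , "current"] * excess)
  for (b in QUIT_BINS) {
    out <- out + rowSums(state$counts[, , paste0("former_", b)] *
                           (r$d_former[[b]] - r$d_never))
  }
  out
}

#' Annual smoking-attributable-death ledger of a scenario
#'
#' @param scenario A [run_counterfactual()] result.
#' @return Data frame `year, gender, sads`.
#' @export
sad_ledger <- function(scenario) {
  scenario$sads
}

#' Apply annual vaping adjustors to a counterfactual scenario
#'
#' Re-runs the scenario dynamics, reducing current-smoker prevalence in
#' each adjusted gender/age cell by its annual adjustor `a` every year
#' of the adjustment window, so that by `t` the cell has compounded an
#' extra `(1 - a)^(t - start_year)` relative decline. Removed smokers
#' are transferred to never smokers below age 25 and to the quit < 1
#' year former bin at 25 and above, after which they are subject to
#' normal mortality and relapse dynamics. Negative adjustors increase
#' prevalence symmetrically (drawn back from the recipient statuses).
#' After `end_year` the accumulated adjustment is held (no further
#' annual reductions) and the population evolves normally.
#'
#' @param baseline A [run_counterfactual()] result covering the horizon.
#' @param adjustors Data frame `gender, age_group, a` of annual relative
#'   reductions (fractions per year; `age_group` one of 18+, 18-24,
#'   25-44, 45-64, 65+ — finer groups take precedence over 18+).
#' @param start_year First year of the window (the adjustment first
#'   applies to the year after it).
#' @param end_year Last adjusted year.
#' @param max_age If set (e.g. 44), only persons at or below this age at
#'   the time of each annual adjustment are adjusted; the affected
#'   cohorts are then followed as they age.
#' @param label Scenario label.
#' @return A `scenario_result` for the adjusted scenario.
#' @export
apply_nvp_adjustment <- function(baseline, adjustors, start_year = 2012,
                                 end_year = 2018, max_age = NULL,
                                 label = "nvp-adjusted") {
  if (any(adjustors$a >= 1)) stop("annual adjustors must be < 1")
  inputs <- baseline$inputs
  if (!start_year %in% inputs$years) {
    stop("start_year outside the scenario horizon")
  }
  a_by_age <- adjustor_age_profile(adjustors)
  if (!is.null(max_age)) {
    for (g in GENDERS) a_by_age[g, AGES > max_age] <- 0
  }
  adjust_fn <- function(st) {
    if (st$year > start_year && st$year <= end_year) {
      st <- adjust_current_smokers(st, a_by_age)
    }
    st
  }
  years <- inputs$years[inputs$years >= start_year]
  from <- baseline$states[[as.character(start_year)]]
  states <- simulate_years(inputs, from, years, adjust_fn)
  pre <- baseline$states[inputs$years < start_year]
  inputs2 <- inputs
  out <- scenario_result(label, inputs2, c(pre, states))
  out
}

# Expand per-age-group adjustors to a gender x age matrix; finer groups
# override "18+"; ages outside every group are unadjusted.
adjustor_age_profile <- function(adjustors) {
  need <- c("gender", "age_group", "a")
  if (!all(need %in% names(adjustors))) {
    stop("adjustors must have columns gender, age_group, a")
  }
  bad <- !adjustors$age_group %in% names(AGE_GROUPS)
  if (any(bad)) {
    stop("unknown age_group: ",
         paste(unique(adjustors$age_group[bad]), collapse = ", "))
  }
  m <- matrix(0, 2, 100, dimnames = list(GENDERS, as.character(AGES)))
  ord <- order(adjustors$age_group == "18+", decreasing = TRUE)
  for (i in ord) {
    r <- adjustors[i, ]
    m[r$gender, AGE_GROUPS[[r$age_group]] + 1] <- r$a
  }
  m
}

# Remove a fraction a(age) of current smokers per gender/age cell;
# recipients: never smokers below age 25, quit < 1y former bin at >= 25.
# Negative a draws people back from the recipient statuses (bounded).
adjust_current_smokers <- function(state, a_by_age) {
  counts <- state$counts
  under25 <- AGES < 25
  for (g in GENDERS) {
    cur <- counts[g, , "current"]
    moved <- cur * a_by_age[g, ]
    leaving <- pmax(moved, 0)
    counts[g, , "current"] <- cur - leaving
    counts[g, , "never"] <- counts[g, , "never"] + leaving * under25
    counts[g, , "former_<1"] <- counts[g, , "former_<1"] +
      leaving * !under25
    returning <- pmax(-moved, 0)
    if (any(returning > 0)) {
      from_never <- pmin(returning, counts[g, , "never"]) * under25
      from_former <- pmin(returning, counts[g, , "former_<1"]) * !under25
      counts[g, , "never"] <- counts[g, , "never"] - from_never
      counts[g, , "former_<1"] <- counts[g, , "former_<1"] - from_former
      counts[g, , "current"] <- counts[g, , "current"] + from_never +
        from_former
    }
  }
  state$counts <- counts
  state
}

#' Deaths averted between two scenarios
#'
#' Per-year difference in smoking-attributable deaths between a baseline
#' and an adjusted scenario, by gender, with running cumulative totals.
#' Any cohort/age restriction is applied when constructing the adjusted
#' scenario (see `max_age` in [apply_nvp_adjustment()]); uncertainty
#' ranges come from re-running the adjustment with bound adjustors.
#'
#' @param baseline_ledger,adjusted_ledger Ledgers from [sad_ledger()]
#'   (data frames `year, gender, sads`) covering the same years.
#' @return Data frame `year, gender, sads_baseline, sads_adjusted,
#'   averted, cum_averted`.
#' @export
deaths_averted <- function(baseline_ledger, adjusted_ledger) {
  m <- merge(baseline_ledger, adjusted_ledger,
             by = c("year", "gender"), suffixes = c("_baseline",
                                                    "_adjusted"),
             all = FALSE)
  if (nrow(m) != nrow(baseline_ledger) ||
      nrow(m) != nrow(adjusted_ledger)) {
    stop("ledgers must cover the same years and genders")
  }
  m <- m[order(m$gender, m$year), ]
  m$averted <- m$sads_baseline - m$sads_adjusted
  m$cum_averted <- ave(m$averted, m$gender, FUN = cumsum)
  rownames(m) <- NULL
  m
}

#' Summarize deaths averted over reporting windows
#'
#' @param averted A [deaths_averted()] data frame.
#' @param windows Named list of `c(start, end)` year pairs.
#' @return Data frame `window, gender, averted` with a `both` gender row
#'   per window (male + female).
#' @export
averted_summary <- function(averted,
                            windows = list(`2012-2018` = c(2012, 2018),
                                           `2012-2052` = c(2012, 2052))) {
  rows <- lapply(names(windows), function(w) {
    yr <- windows[[w]]
    d <- averted[averted$year >= yr[1] & averted$year <= yr[2], ]
    by_g <- tapply(d$averted, d$gender, sum)
    data.frame(window = w, gender = c(names(by_g), "both"),
               averted = c(unname(by_g), sum(by_g)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
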