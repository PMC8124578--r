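#' Validate scenario projections against survey series
#'
#' For every survey x gender x age group x period: the projected and
#' survey prevalence levels at the period endpoints, the relative
#' reductions, their difference, and whether the projected end-year
#' level falls inside the survey's 95% CI (closed interval).
#'
#' @param sim Data frame `year, gender, age_group, prevalence` (e.g. a
#'   scenario's `prevalence` table, or a published projection series).
#' @param surveys A [read_survey_series()] data frame (may contain
#'   several surveys).
#' @param periods List of `c(start, end)` year pairs.
#' @return A data frame report; serialize with [write_report_json()].
#' @export
validate_report <- function(sim,
                            surveys,
                            periods = list(c(1998, 2010),
                                           c(1998, 2012))) {
  overlap <- intersect(unique(sim$year), unique(surveys$year))
  if (!length(overlap)) stop("no overlapping years between sim and surveys")
  cells <- unique(surveys[, c("survey", "gender", "age_group")])
  rows <- list()
  for (p in periods) {
    for (i in seq_len(nrow(cells))) {
      cl <- cells[i, ]
      sv <- surveys[surveys$survey == cl$survey &
                      surveys$gender == cl$gender &
                      surveys$age_group == cl$age_group, ]
      sm <- sim[sim$gender == cl$gender & sim$age_group == cl$age_group, ]
      gp <- function(d, y) d$prevalence[d$year == y][1]
      sp0 <- gp(sm, p[1]); sp1 <- gp(sm, p[2])
      vp0 <- gp(sv, p[1]); vp1 <- gp(sv, p[2])
      if (any(is.na(c(sp0, sp1, vp0, vp1)))) next
      ci1 <- c(sv$ci_lower[sv$year == p[2]][1],
               sv$ci_upper[sv$year == p[2]][1])
      rows[[length(rows) + 1]] <- data.frame(
        survey = cl$survey, gender = cl$gender,
        age_group = cl$age_group,
        period_start = p[1], period_end = p[2],
        sim_p_start = sp0, sim_p_end = sp1,
        sim_R = relative_reduction(sp0, sp1),
        survey_p_start = vp0, survey_p_end = vp1,
        survey_R = relative_reduction(vp0, vp1),
        diff_R = relative_reduction(vp0, vp1) -
          relative_reduction(sp0, sp1),
        sim_level_outside_ci = if (!any(is.na(ci1))) {
          outside_ci_flag(sp1, ci1)
        } else NA,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no survey cells cover the requested periods")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report data frame as JSON
#'
#' @param report A data frame (e.g. from [validate_report()] or
#'   [infer_nvp()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Sensitivity of projected prevalence to policy-effect bounds
#'
#' Re-projects a period under policy scenarios: no policy change (all
#' levels frozen at the period start), each policy changing alone at its
#' central, lower and upper effect sizes, and all policies together.
#' Bounds default to +/-25% of the price elasticities and +/-50% of the
#' other policies' effect sizes. Each scenario starts from the
#' baseline's period-start population (history is shared) and reports
#' adult relative reductions and the difference from the no-change
#' scenario.
#'
#' @param baseline A [run_counterfactual()] result covering the period
#'   (its inputs supply mortality, transitions, drivers).
#' @param schedule The [read_policy_schedule()] the scenarios vary.
#' @param bounds List with `price` and `other` fractional half-widths.
#' @param period `c(start, end)` years.
#' @param effects Central [effect_size_table()].
#' @return Data frame `scenario, range, gender, p_start, p_end,
#'   relative_reduction, diff_from_no_policy`.
#' @export
sensitivity_sweep <- function(baseline, schedule,
                              bounds = list(price = 0.25, other = 0.50),
                              period = c(2012, 2018),
                              effects = effect_size_table()) {
  policies <- c("price", "smoke_free_air", "media", "marketing",
                "cessation_treatment", "youth_access")
  run_one <- function(sched, eff) {
    inputs <- baseline$inputs
    years <- period[1]:period[2]
    inputs$deltas <- schedule_to_deltas(sched, eff)
    inputs$years <- years
    from <- baseline$states[[as.character(period[1])]]
    if (is.null(from)) stop("baseline does not cover the period start")
    states <- simulate_years(inputs, from, years)
    last <- states[[length(states)]]
    vapply(GENDERS, function(g) {
      c(p_start = smoking_prevalence(from, gender = g),
        p_end = smoking_prevalence(last, gender = g))
    }, numeric(2))
  }
  half <- function(p) if (p == "price") bounds$price else bounds$other
  frozen <- freeze_schedule(schedule, period[1])
  rows <- list()
  add <- function(scenario, range_lbl, res, base_R = NULL) {
    for (g in GENDERS) {
      R <- relative_reduction(res["p_start", g], res["p_end", g])
      rows[[length(rows) + 1]] <<- data.frame(
        scenario = scenario, range = range_lbl, gender = g,
        p_start = res["p_start", g], p_end = res["p_end", g],
        relative_reduction = R,
        diff_from_no_policy = if (is.null(base_R)) 0 else R - base_R[[g]],
        stringsAsFactors = FALSE)
    }
  }
  res0 <- run_one(frozen, effects)
  base_R <- lapply(setNames(GENDERS, GENDERS), function(g) {
    relative_reduction(res0["p_start", g], res0["p_end", g])
  })
  add("no_policy_change", "-", res0)
  scen_factors <- function(p) {
    b <- half(p)
    stats::setNames(c(1, 1 - b, 1 + b),
                    c("0%", sprintf("-%d%%", round(100 * b)),
                      sprintf("+%d%%", round(100 * b))))
  }
  for (p in policies) {
    sched_p <- freeze_schedule(schedule, period[1], setdiff(policies, p))
    for (lbl in names(scen_factors(p))) {
      f <- scen_factors(p)[[lbl]]
      add(paste0(p, "_alone"), lbl,
          run_one(sched_p, scale_effects(effects, f, p)), base_R)
    }
  }
  all_lbls <- c("0%",
                sprintf("-%d%%/-%d%%", round(100 * bounds$price),
                        round(100 * bounds$other)),
                sprintf("+%d%%/+%d%%", round(100 * bounds$price),
                        round(100 * bounds$other)))
  all_factors <- list(c(price = 1, other = 1),
                      c(price = 1 - bounds$price, other = 1 - bounds$other),
                      c(price = 1 + bounds$price, other = 1 + bounds$other))
  for (k in seq_along(all_lbls)) {
    f <- all_factors[[k]]
    eff <- scale_effects(effects, f[["price"]], "price")
    eff <- scale_effects(eff, f[["other"]], setdiff(policies, "price"))
    add("all_policies", all_lbls[k], run_one(schedule, eff), base_R)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Record a reproducible run manifest
#'
#' @param label Scenario label.
#' @param seed Seed used for any randomness in the run.
#' @param config Named list or character vector of input identifiers
#'   (e.g. file paths).
#' @param outputs Named character vector of output files.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(label, seed, config = list(),
                         outputs = character()) {
  structure(list(label = label, seed = seed, config = config,
                 outputs = as.list(outputs),
                 version = as.character(packageVersion("smokesim")),
                 timestamp = format(Sys.time(), tz = "UTC",
                                    usetz = TRUE)),
            class = "run_manifest")
}

#' Write scenario outputs and a manifest to a run directory
#'
#' Writes the scenario's prevalence table and smoking-attributable-death
#' ledger as CSV plus a JSON manifest into a fresh per-run directory
#' (never overwriting an existing one).
#'
#' @param scenario A [run_counterfactual()] result.
#' @param dir Output directory (must not already exist).
#' @param seed Seed recorded in the manifest.
#' @return The manifest, invisibly.
#' @export
write_run_outputs <- function(scenario, dir, seed = NA_integer_) {
  if (dir.exists(dir)) stop("run directory already exists: ", dir)
  dir.create(dir, recursive = TRUE)
  paths <- c(prevalence = file.path(dir, "prevalence.csv"),
             sads = file.path(dir, "sads.csv"),
             manifest = file.path(dir, "manifest.json"))
  write.csv(scenario$prevalence, paths[["prevalence"]], row.names = FALSE)
  write.csv(scenario$sads, paths[["sads"]], row.names = FALSE)
  mf <- run_manifest(scenario$label, seed,
                     config = list(years = range(scenario$years)),
                     outputs = paths)
  jsonlite::write_json(unclass(mf), paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mf)
}
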