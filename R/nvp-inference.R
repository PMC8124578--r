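#' Relative reduction in prevalence over a period
#'
#' `(p_start - p_end) / p_start`, reported as a positive fraction for a
#' decline (the sign convention used throughout the package).
#'
#' @param p_start,p_end Prevalences in \[0, 1\]; `p_start` must be
#'   positive. Vectorized.
#' @return Fractional relative reduction (<= 1; negative for increases).
#' @export
#' @examples
#' relative_reduction(0.264, 0.205)  # NHIS-style 22.3% decline
relative_reduction <- function(p_start, p_end) {
  if (any(p_start <= 0)) stop("p_start must be positive")
  (p_start - p_end) / p_start
}

#' Interpolate a missing survey wave
#'
#' Weighted average of the surrounding waves; the default 60/40 weights
#' reconstruct a missing estimate from waves roughly 1-2 years before
#' and 2-3 years after (e.g. a 2012 value from 2010/11 and 2014/15
#' waves).
#'
#' @param p_before,p_after Prevalence in the earlier / later wave.
#' @param w_before,w_after Non-negative weights summing to 1.
#' @return Interpolated prevalence.
#' @export
#' @examples
#' interpolate_wave(0.172, 0.157)  # 0.166
interpolate_wave <- function(p_before, p_after, w_before = 0.6,
                             w_after = 0.4) {
  if (w_before < 0 || w_after < 0 || abs(w_before + w_after - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1")
  }
  w_before * p_before + w_after * p_after
}

#' Annualize a total relative reduction
#'
#' Converts a total relative reduction over `n_years` into the constant
#' annual relative reduction that compounds to it:
#' `1 - (1 - R)^(1/n_years)`. Compounding the result `n_years` times
#' recovers `R` exactly.
#'
#' @param R Total relative reduction (< 1; negative for an increase).
#' @param n_years Number of years in the period (default 6).
#' @return Annual relative reduction (fraction per year).
#' @export
#' @examples
#' annualize(0.122)  # ~2.1% per year
annualize <- function(R, n_years = 6) {
  if (any(R >= 1, na.rm = TRUE)) stop("relative reduction must be < 1")
  1 - (1 - R)^(1 / n_years)
}

#' Net vaping-associated impact on a relative reduction
#'
#' The difference between the survey-observed and the counterfactual
#' (no-vaping) projected relative reductions over the same period;
#' positive values indicate extra decline associated with vaping.
#'
#' @param sim_R Counterfactual projected relative reduction.
#' @param survey_R Survey-estimated relative reduction.
#' @return `survey_R - sim_R`.
#' @export
#' @examples
#' nvp_net_impact(0.122, 0.219)  # 0.097
nvp_net_impact <- function(sim_R, survey_R) {
  survey_R - sim_R
}

#' Annual vaping adjustor
#'
#' The difference of annualized relative reduction rates between survey
#' and counterfactual:
#' `annualize(survey_R, n) - annualize(sim_R, n)`, equivalently
#' `(1 - sim_R)^(1/n) - (1 - survey_R)^(1/n)` in survival-ratio form.
#' This is the constant annual extra relative decline applied to the
#' counterfactual to obtain the vaping-adjusted scenario.
#'
#' @inheritParams nvp_net_impact
#' @param n_years Period length in years (default 6).
#' @return Annual adjustor (fraction per year); antisymmetric in its
#'   arguments.
#' @export
#' @examples
#' nvp_adjustor(0.122, 0.219)  # ~1.9% per year
nvp_adjustor <- function(sim_R, survey_R, n_years = 6) {
  annualize(survey_R, n_years) - annualize(sim_R, n_years)
}

#' Propagate a survey confidence interval to a relative reduction
#'
#' Carries the end-year 95% CI of prevalence through the relative
#' reduction: the reduction's bounds are
#' `(p_start - upper) / p_start` and `(p_start - lower) / p_start`,
#' ordered low to high.
#'
#' @param p_start Start-year prevalence (> 0; treated as fixed).
#' @param ci_end Length-2 numeric `(lower, upper)` CI of the end-year
#'   prevalence.
#' @return List with `reduction` bounds `lower`/`upper` (fractions).
#' @export
#' @examples
#' propagate_bounds(0.166, c(0.126, 0.133))
propagate_bounds <- function(p_start, ci_end) {
  if (p_start <= 0) stop("p_start must be positive")
  if (length(ci_end) != 2 || ci_end[1] > ci_end[2]) {
    stop("ci_end must be an ordered (lower, upper) pair")
  }
  list(lower = (p_start - ci_end[2]) / p_start,
       upper = (p_start - ci_end[1]) / p_start)
}

#' Flag values outside a confidence interval
#'
#' TRUE when the simulated value falls strictly outside the closed
#' interval (boundary values count as inside).
#'
#' @param sim_value Simulated/projected value.
#' @param ci Length-2 `(lower, upper)` interval.
#' @return Logical.
#' @export
outside_ci_flag <- function(sim_value, ci) {
  if (length(ci) != 2 || ci[1] > ci[2]) {
    stop("ci must be an ordered (lower, upper) pair")
  }
  sim_value < ci[1] | sim_value > ci[2]
}

#' Read a survey prevalence series
#'
#' Expects a CSV with columns `survey, gender, age_group, year,
#' prevalence, ci_lower, ci_upper` (CI columns may be empty).
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `survey_series`.
#' @export
read_survey_series <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("survey", "gender", "age_group", "year", "prevalence",
            "ci_lower", "ci_upper")
  if (!all(need %in% names(d))) {
    stop("survey series must have columns: ", paste(need, collapse = ", "))
  }
  as_survey_series(d[, need])
}

#' Validate and class a survey-series data frame
#'
#' @param d Data frame with survey series columns.
#' @return The data frame with class `survey_series`.
#' @export
as_survey_series <- function(d) {
  ok <- is.na(d$prevalence) | (d$prevalence >= 0 & d$prevalence <= 1)
  if (!all(ok)) stop("prevalence must lie in [0, 1]")
  has_ci <- !is.na(d$ci_lower) & !is.na(d$ci_upper)
  bad <- has_ci & !(d$ci_lower <= d$prevalence & d$prevalence <= d$ci_upper)
  if (any(bad, na.rm = TRUE)) {
    stop("CI bounds must bracket the point estimate")
  }
  class(d) <- c("survey_series", "data.frame")
  d
}

#' Infer vaping impacts from counterfactual and survey trends
#'
#' For every survey x gender x age group, computes the survey and
#' counterfactual relative reductions over the period, the net vaping
#' impact, the annualized adjustor, CI-propagated bounds (from the
#' end-year survey CI), and whether the counterfactual reduction falls
#' outside the survey reduction's CI.
#'
#' @param sim Data frame `year, gender, age_group, prevalence` of
#'   counterfactual projections (e.g. a scenario's `prevalence` table).
#' @param survey A [read_survey_series()] data frame covering the period
#'   start and end years, with CIs in the end year.
#' @param period Length-2 vector `(start, end)` of calendar years.
#' @return A data frame with one row per survey x gender x age group:
#'   `sim_R`, `survey_R`, `survey_R_lo`, `survey_R_hi`, `net_impact`
#'   (+ bounds), `adjustor` (+ bounds), `outside_ci`.
#' @export
infer_nvp <- function(sim, survey, period = c(2012, 2018)) {
  n_years <- period[2] - period[1]
  cells <- unique(survey[, c("survey", "gender", "age_group")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sv <- survey[survey$survey == cl$survey & survey$gender == cl$gender &
                   survey$age_group == cl$age_group, ]
    sm <- sim[sim$gender == cl$gender & sim$age_group == cl$age_group, ]
    p0s <- sm$prevalence[sm$year == period[1]]
    p1s <- sm$prevalence[sm$year == period[2]]
    p0 <- sv$prevalence[sv$year == period[1]]
    p1 <- sv$prevalence[sv$year == period[2]]
    if (!length(p0s) || !length(p1s) || !length(p0) || !length(p1)) {
      stop("sim and survey must both cover the period endpoints for ",
           cl$survey, "/", cl$gender, "/", cl$age_group)
    }
    sim_R <- relative_reduction(p0s, p1s)
    survey_R <- relative_reduction(p0, p1)
    ci1 <- c(sv$ci_lower[sv$year == period[2]],
             sv$ci_upper[sv$year == period[2]])
    if (length(ci1) == 2 && !any(is.na(ci1))) {
      b <- propagate_bounds(p0, ci1)
    } else {
      b <- list(lower = NA_real_, upper = NA_real_)
    }
    data.frame(
      survey = cl$survey, gender = cl$gender, age_group = cl$age_group,
      sim_R = sim_R, survey_R = survey_R,
      survey_R_lo = b$lower, survey_R_hi = b$upper,
      net_impact = nvp_net_impact(sim_R, survey_R),
      net_impact_lo = nvp_net_impact(sim_R, b$lower),
      net_impact_hi = nvp_net_impact(sim_R, b$upper),
      adjustor = nvp_adjustor(sim_R, survey_R, n_years),
      adjustor_lo = nvp_adjustor(sim_R, b$lower, n_years),
      adjustor_hi = nvp_adjustor(sim_R, b$upper, n_years),
      outside_ci = if (!is.na(b$lower)) {
        outside_ci_flag(sim_R, c(b$lower, b$upper))
      } else NA,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
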