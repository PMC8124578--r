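#' Configuration for a synthetic world
#'
#' Parameters of a fully synthetic population with known ground truth:
#' cohort sizes, a cross-sectional smoking prevalence curve that rises
#' to a gender-specific peak age, plateaus and declines in old age,
#' Gompertz-like never-smoker mortality with an age-dependent smoker
#' relative risk, cessation/relapse rates, a true annual vaping adjustor
#' and survey sample sizes. All rates are fractions; the seed is
#' recorded in every derived artifact.
#'
#' @param seed Integer seed recorded in the world and used by survey
#'   sampling.
#' @param years Simulated calendar years.
#' @param persons_per_gender Total persons per gender (default 1e5,
#'   sized for fast deterministic tests; scale up via this knob).
#' @param peak_prev Named vector: current-smoking prevalence at the peak
#'   age, by gender.
#' @param peak_age Named vector of peak ages (defaults 22 male, 25
#'   female).
#' @param old_frac Prevalence at age 99 as a fraction of the peak.
#' @param former_slope,former_cap Former-smoker fraction grows linearly
#'   with age above the peak at `former_slope`/year, capped at
#'   `former_cap`.
#' @param gompertz_a,gompertz_b Never-smoker mortality
#'   `2e-4 + a * exp(b * age)`.
#' @param rr_max Smoker relative risk plateau (reached by age 55; RR is
#'   1 below age 30).
#' @param cessation_rate Annual quit probability above the peak age.
#' @param relapse_rates Annual relapse probabilities by years-quit bin
#'   (non-increasing).
#' @param a_star True annual vaping adjustor (fraction/year) injected
#'   into survey truth from `nvp_start_year`.
#' @param nvp_start_year First year of the injected vaping effect.
#' @param n_per_wave Survey sample size per wave and gender.
#' @return A list of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         years = 1993:2052,
                         persons_per_gender = 1e5,
                         peak_prev = c(male = 0.28, female = 0.24),
                         peak_age = c(male = 22, female = 25),
                         old_frac = 0.45,
                         former_slope = 0.011,
                         former_cap = 0.38,
                         gompertz_a = 1e-4,
                         gompertz_b = 0.085,
                         rr_max = 2.5,
                         cessation_rate = 0.045,
                         relapse_rates = c(0.10, 0.06, 0.03, 0.02,
                                           0.01, 0.005),
                         a_star = c(male = 0.02, female = 0.02),
                         nvp_start_year = 2012,
                         n_per_wave = 25000) {
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  if (any(peak_prev < 0 | peak_prev > 1)) {
    stop("peak_prev must lie in [0, 1]")
  }
  if (any(diff(relapse_rates) > 0)) {
    stop("relapse rates must be non-increasing across quit bins")
  }
  if (any(a_star >= 1)) stop("a_star must be < 1")
  if (n_per_wave <= 0) stop("n_per_wave must be positive")
  structure(cfg, class = "world_config")
}

# Cross-sectional current-smoking prevalence by single age for one gender.
synthetic_prev_curve <- function(cfg, gender) {
  peak <- cfg$peak_age[[gender]]
  pk <- cfg$peak_prev[[gender]]
  prev <- numeric(100)
  rise <- AGES >= 10 & AGES <= peak
  prev[rise] <- pk * (AGES[rise] - 9) / (peak - 9)
  plateau_end <- 45
  prev[AGES > peak & AGES <= plateau_end] <- pk
  old <- AGES > plateau_end
  prev[old] <- pk * (1 - (1 - cfg$old_frac) *
                       (AGES[old] - plateau_end) / (99 - plateau_end))
  prev
}

#' Generate a synthetic world with known ground truth
#'
#' Builds internally consistent model inputs: a population whose
#' cross-sectional prevalence follows the configured curve (former
#' smokers appearing above the peak age, split across years-quit bins),
#' a constant-in-time mortality schedule with `d_current >= d_never`,
#' and transition rates whose net initiation is derived from the
#' prevalence curve through the cross-sectional identity — so replaying
#' the generated rates on the age-10 never pool reproduces the curve up
#' to the peak age.
#'
#' @param config A [world_config()].
#' @return A list of class `sim_world` with elements `inputs` (a
#'   [sim_inputs()] ready for [run_counterfactual()]), `truth`
#'   (prevalence curves, configured adjustors) and `config`.
#' @export
gen_world <- function(config = world_config()) {
  cfg <- config
  years <- cfg$years
  # mortality
  d_never_age <- pmin(2e-4 + cfg$gompertz_a * exp(cfg$gompertz_b * AGES),
                      0.7)
  rr_age <- 1 + (cfg$rr_max - 1) * pmin(pmax((AGES - 30) / 25, 0), 1)
  dn <- rbind(male = d_never_age, female = d_never_age * 0.85)
  dc <- pmin(dn * rep(rr_age, each = 2), 1)
  mortality <- constant_mortality(dn, dc, years)
  # population and prevalence curve
  pyramid <- exp(-0.004 * AGES)
  pyramid <- pyramid / sum(pyramid) * cfg$persons_per_gender
  counts <- empty_population(years[1])$counts
  prev_curves <- list()
  for (g in GENDERS) {
    prev <- synthetic_prev_curve(cfg, g)
    peak <- cfg$peak_age[[g]]
    former <- ifelse(AGES > peak,
                     pmin(cfg$former_cap,
                          cfg$former_slope * (AGES - peak)), 0)
    former <- pmin(former, 1 - prev)
    never <- 1 - prev - former
    w <- c(0.05, 0.08, 0.12, 0.15, 0.15, 0.45)
    counts[g, , "never"] <- pyramid * never
    counts[g, , "current"] <- pyramid * prev
    counts[g, , FORMER_STATUSES] <- outer(pyramid * former, w)
    prev_curves[[g]] <- prev
  }
  initial_state <- population_state(years[1], counts)
  # transitions via the cross-sectional net-initiation identity
  ni <- matrix(0, 2, 100)
  cess <- matrix(0, 2, 100)
  for (g in GENDERS) {
    peak <- cfg$peak_age[[g]]
    prev <- prev_curves[[g]]
    idx <- as.character(9:peak)
    pv <- setNames(prev[9:peak + 1], idx)
    nv <- setNames(1 - prev[9:peak + 1], idx)   # no former below the peak
    rates <- net_initiation_from_cross_section(pv, nv, peak)
    # rate named a+1 acts on age-a persons: transitions precede aging
    ni[if (g == "male") 1 else 2, as.integer(names(rates))] <- rates
    cess[if (g == "male") 1 else 2, AGES > peak] <- cfg$cessation_rate
  }
  relapse <- array(rep(cfg$relapse_rates, each = 200), dim = c(2, 100, 6))
  transitions <- transition_rates(ni, cess, relapse,
                                  peak_age = cfg$peak_age)
  # stationary age-0 inflow keeps cohort sizes comparable over time
  births <- matrix(pyramid[1], 2, length(years))
  drivers <- demography_drivers(births, NULL, years)
  inputs <- sim_inputs(initial_state, mortality, transitions,
                       deltas = NULL, drivers = drivers, years = years)
  structure(list(inputs = inputs,
                 truth = list(prev_curves = prev_curves,
                              a_star = cfg$a_star,
                              nvp_start_year = cfg$nvp_start_year),
                 config = cfg, seed = cfg$seed),
            class = "sim_world")
}

#' @export
print.sim_world <- function(x, ...) {
  cat("<sim_world> seed", x$seed, "| years", min(x$config$years), "-",
      max(x$config$years), "|", format(x$config$persons_per_gender),
      "persons/gender\n")
  invisible(x)
}

#' Sample a noisy survey series around a true trajectory
#'
#' Draws binomial survey estimates around the true prevalence for each
#' row of the trajectory and attaches 95% confidence intervals (normal
#' approximation by default; Wilson intervals by flag).
#'
#' @param truth Data frame `year, gender, age_group, prevalence` of true
#'   prevalences (one wave per year present).
#' @param n_per_wave Respondents per row (per wave x gender x age
#'   group).
#' @param seed Integer seed.
#' @param survey Survey label for the output.
#' @param method `"normal"` or `"wilson"` interval construction.
#' @return A `survey_series` data frame with columns `survey, gender,
#'   age_group, year, prevalence, ci_lower, ci_upper, n`.
#' @export
gen_survey_series <- function(truth, n_per_wave, seed = 1L,
                              survey = "synthetic",
                              method = c("normal", "wilson")) {
  method <- match.arg(method)
  if (n_per_wave <= 0) stop("n_per_wave must be positive")
  out <- truth[, c("year", "gender", "age_group", "prevalence")]
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    code
  }
  x <- withr_seed(rbinom(nrow(out), n_per_wave, out$prevalence))
  phat <- x / n_per_wave
  z <- qnorm(0.975)
  if (method == "normal") {
    se <- sqrt(phat * (1 - phat) / n_per_wave)
    lo <- pmax(phat - z * se, 0)
    hi <- pmin(phat + z * se, 1)
  } else {
    denom <- 1 + z^2 / n_per_wave
    centre <- (phat + z^2 / (2 * n_per_wave)) / denom
    half <- z * sqrt(phat * (1 - phat) / n_per_wave +
                       z^2 / (4 * n_per_wave^2)) / denom
    lo <- pmax(centre - half, 0)
    hi <- pmin(centre + half, 1)
  }
  res <- data.frame(survey = survey, gender = out$gender,
                    age_group = out$age_group, year = out$year,
                    prevalence = phat, ci_lower = lo, ci_upper = hi,
                    n = n_per_wave, stringsAsFactors = FALSE)
  attr(res, "seed") <- seed
  as_survey_series(res)
}

#' Inject a vaping effect into a true prevalence trajectory
#'
#' Scales prevalence by `(1 - a_star)^(t - start_year)` from
#' `start_year` onward, the compounding ground truth against which the
#' inference pipeline's recovered adjustor is checked.
#'
#' @param truth Data frame with `year` and `prevalence` columns (and
#'   optionally `gender`), or a numeric vector named by year.
#' @param a_star Annual adjustor; a scalar, or a named vector by gender
#'   when `truth` has a `gender` column.
#' @param start_year First year of the effect (factor 1 at
#'   `start_year`).
#' @return `truth` with scaled prevalence.
#' @export
inject_nvp_effect <- function(truth, a_star, start_year) {
  if (any(a_star >= 1)) stop("a_star must be < 1")
  if (is.numeric(truth) && !is.null(names(truth))) {
    yrs <- as.integer(names(truth))
    f <- ifelse(yrs >= start_year, (1 - a_star)^(yrs - start_year), 1)
    return(truth * f)
  }
  a <- if (length(a_star) > 1 && "gender" %in% names(truth)) {
    unname(a_star[truth$gender])
  } else {
    rep_len(unname(a_star)[1], nrow(truth))
  }
  f <- ifelse(truth$year >= start_year,
              (1 - a)^(truth$year - start_year), 1)
  truth$prevalence <- truth$prevalence * f
  truth
}
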