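#' Policy effect-size constants
#'
#' The effect sizes applied by the policy engine, as used in established
#' tobacco-control policy simulation (SimSmoke-style) analyses of the US.
#' Each entry gives, per policy and level/component, the fractional
#' first-year prevalence reduction (`prevalence`), the ongoing fractional
#' initiation-rate reduction (`initiation`) and the ongoing fractional
#' cessation-rate increase (`cessation`). Price effects enter separately
#' through age-band elasticities.
#'
#' Cessation-treatment components carry a published full-package total
#' (-5.68% prevalence, +29.4% cessation) that the engine honours: the
#' multiplicative combination of coverage-scaled components is rescaled
#' so the fully implemented package reproduces the package totals
#' exactly.
#'
#' @return A nested list of class `effect_size_table`.
#' @export
effect_size_table <- function() {
  eff <- function(prevalence, initiation = prevalence,
                  cessation = prevalence) {
    list(prevalence = prevalence, initiation = initiation,
         cessation = cessation)
  }
  structure(list(
    smoke_free_air = list(
      # venue bans, scaled by population coverage; deflated by
      # enforcement (0-10) and publicity
      worksite   = eff(0.06),
      restaurant = eff(0.02),
      bar        = eff(0.01),
      other      = eff(0.01),
      # partial worksite bans: weight if smoking allowed in ventilated
      # areas (mid, 2/3 of full effect) or common areas (low, 1/3)
      worksite_weights = c(high = 1, mid = 2 / 3, low = 1 / 3)
    ),
    media = list(
      high     = eff(0.065),
      moderate = eff(0.0325),
      minimal  = eff(0.0163)
    ),
    marketing = list(
      comprehensive = eff(0.05, 0.08, 0.04),
      moderate      = eff(0.03, 0.04, 0.02),
      minimal       = eff(0.01, 0.01, 0)
    ),
    cessation_treatment = list(
      availability       = eff(0.01, 0, 0.04),
      financial_coverage = eff(0.0225, 0, 0.08),
      quitline           = eff(0.01, 0, 0.06),
      brief_intervention = eff(0.01, 0, 0.06),
      package_total      = eff(0.0568, 0, 0.294)
    ),
    youth_access = list(
      # initiation and prevalence reductions for youth age bands only
      strong   = list(`10-15` = 0.24, `16-17` = 0.16),
      moderate = list(`10-15` = 0.12, `16-17` = 0.08),
      low      = list(`10-15` = 0.03, `16-17` = 0.02),
      none     = list(`10-15` = 0, `16-17` = 0)
    ),
    elasticity = c(`14-17` = -0.6, `18-24` = -0.4, `25-34` = -0.2,
                   `35-64` = -0.1, `65+` = -0.2)
  ), class = "effect_size_table")
}

#' Price elasticity by single age
#'
#' Expands the age-band price elasticities to a vector over single ages
#' 0-99 (zero below age 14, where cigarette demand is not modelled).
#'
#' @param effects An [effect_size_table()].
#' @return Numeric vector of length 100 (ages 0-99).
#' @export
elasticity_by_age <- function(effects = effect_size_table()) {
  e <- rep(0, 100)
  bands <- list(`14-17` = 14:17, `18-24` = 18:24, `25-34` = 25:34,
                `35-64` = 35:64, `65+` = 65:99)
  for (b in names(bands)) e[bands[[b]] + 1] <- effects$elasticity[[b]]
  e
}

#' Scale policy effect sizes up or down
#'
#' Multiplies the prevalence/initiation/cessation effect constants of the
#' selected policies by a common factor (used for sensitivity bounds,
#' e.g. -50%/+50%); elasticities are scaled when `"price"` is selected.
#'
#' @param effects An [effect_size_table()].
#' @param factor Positive multiplier (1 leaves effects unchanged).
#' @param policies Character vector of policies to scale; default all of
#'   `price`, `smoke_free_air`, `media`, `marketing`,
#'   `cessation_treatment`, `youth_access`.
#' @return A modified [effect_size_table()].
#' @export
scale_effects <- function(effects, factor, policies = NULL) {
  if (factor < 0) stop("scale factor must be non-negative")
  policies <- policies %||% c("price", "smoke_free_air", "media",
                              "marketing", "cessation_treatment",
                              "youth_access")
  scale_rec <- function(x) {
    if (is.list(x)) lapply(x, scale_rec) else x * factor
  }
  for (p in setdiff(policies, "price")) {
    keep <- if (p == "smoke_free_air") "worksite_weights" else character()
    scaled <- scale_rec(effects[[p]][setdiff(names(effects[[p]]), keep)])
    effects[[p]][names(scaled)] <- scaled
  }
  if ("price" %in% policies) {
    effects$elasticity <- effects$elasticity * factor
  }
  effects
}
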