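#' Deflate a policy effect by enforcement and publicity
#'
#' Effect sizes assume strong enforcement and publicity; weaker
#' implementation deflates them by
#' `0.5 * (1 + 0.5 * publicity + 0.5 * enforcement/10)`, i.e. effects are
#' halved absent both. For policies with no publicity component (e.g.
#' marketing restrictions, "reduced 50% absent enforcement") pass
#' `publicity = NULL` to use `0.5 * (1 + enforcement/10)`.
#'
#' @param base_effect Fractional effect size in \[0, 1).
#' @param enforcement Enforcement level on a 0-10 scale (converted
#'   linearly to a fraction).
#' @param publicity 0/1 publicity indicator, or NULL for the
#'   enforcement-only deflator.
#' @return The deflated effect, bounded above by `base_effect`.
#' @export
#' @examples
#' deflate_effect(0.06, enforcement = 8, publicity = 1)  # 0.057
deflate_effect <- function(base_effect, enforcement, publicity = 1) {
  if (any(enforcement < 0 | enforcement > 10)) {
    stop("enforcement must lie in [0, 10]")
  }
  if (any(base_effect < 0 | base_effect >= 1)) {
    stop("base_effect must lie in [0, 1)")
  }
  defl <- if (is.null(publicity)) {
    0.5 * (1 + enforcement / 10)
  } else {
    if (any(!publicity %in% c(0, 1))) stop("publicity must be 0 or 1")
    0.5 * (1 + 0.5 * publicity + 0.5 * enforcement / 10)
  }
  base_effect * defl
}

#' Combine simultaneous policy effects multiplicatively
#'
#' Fractional reductions from policies simultaneously in effect combine
#' on the residual scale: `1 - prod(1 - e_i)`. The result is
#' order-invariant, at least as large as any single effect, and strictly
#' below 1. Negative elements (effect reversals on the same scale) are
#' accepted.
#'
#' @param effects Numeric vector of fractional reductions, each < 1.
#' @return Combined fractional reduction (0 for an empty vector).
#' @export
#' @examples
#' combine_effects(c(0.06, 0.02))  # 0.0788
combine_effects <- function(effects) {
  if (any(effects >= 1)) stop("each effect must be < 1")
  1 - prod(1 - effects)
}

#' Prevalence response to a cigarette price change
#'
#' Converts a price change into a relative change in smoking prevalence
#' through an age-specific price elasticity. The default functional form
#' is the year-on-year arc `elasticity * (price_new - price_old) /
#' price_old`; a log-ratio form `elasticity * log(price_new/price_old)`
#' is available.
#'
#' @param price_old,price_new Inflation-adjusted prices per pack (> 0).
#' @param elasticity Price elasticity of smoking prevalence (<= 0 for
#'   ordinary demand). Vectorized (e.g. over ages).
#' @param form `"relative"` (default) or `"log"`.
#' @return Fractional prevalence change (negative = reduction when price
#'   rises and elasticity is negative).
#' @export
#' @examples
#' price_effect(5.60, 6.60, -0.4)  # about -7.14%
price_effect <- function(price_old, price_new, elasticity,
                         form = c("relative", "log")) {
  form <- match.arg(form)
  if (any(price_old <= 0) || any(price_new <= 0)) {
    stop("prices must be positive")
  }
  switch(form,
         relative = elasticity * (price_new - price_old) / price_old,
         log = elasticity * log(price_new / price_old))
}

#' Incremental effect of moving between policy levels
#'
#' The first-year effect of a newly implemented policy is the increment
#' over the level already in place, on the residual scale:
#' `1 - (1 - effect_new) / (1 - effect_old)`. A rollback
#' (`effect_new < effect_old`) yields a negative increment, i.e. a
#' prevalence shock reversed on the same scale.
#'
#' @param effect_old,effect_new Fractional effects in \[0, 1).
#' @return Incremental fractional effect.
#' @export
#' @examples
#' incremental_effect(0.02, 0.06)  # about 0.0408
incremental_effect <- function(effect_old, effect_new) {
  if (any(effect_old < 0 | effect_old >= 1 |
          effect_new < 0 | effect_new >= 1)) {
    stop("effects must lie in [0, 1)")
  }
  1 - (1 - effect_new) / (1 - effect_old)
}

# Per-policy effect levels for one year ------------------------------------
# Each returns list(prevalence, initiation, cessation): scalars, except
# youth access which returns age-resolved vectors.

sfa_effect_level <- function(schedule, effects, year, publicity) {
  yk <- as.character(year)
  enf <- schedule$smoke_free_air$enforcement
  v <- schedule$smoke_free_air$venues
  ww <- effects$smoke_free_air$worksite_weights
  cov <- c(
    worksite = sum(ww * c(v$worksite$high[[yk]], v$worksite$mid[[yk]],
                          v$worksite$low[[yk]])),
    restaurant = v$restaurant[[yk]],
    bar = v$bar[[yk]],
    other = v$other[[yk]]
  )
  per_venue <- function(field) {
    vapply(names(cov), function(ven) {
      deflate_effect(effects$smoke_free_air[[ven]][[field]], enf,
                     publicity) * cov[[ven]]
    }, numeric(1))
  }
  list(prevalence = combine_effects(per_venue("prevalence")),
       initiation = combine_effects(per_venue("initiation")),
       cessation = prod(1 + per_venue("cessation")) - 1)
}

media_effect_level <- function(schedule, effects, year) {
  yk <- as.character(year)
  w <- vapply(schedule$media$weights, `[[`, numeric(1), yk)
  lvl <- function(field) {
    sum(w * vapply(names(w), function(l) effects$media[[l]][[field]],
                   numeric(1)))
  }
  list(prevalence = lvl("prevalence"), initiation = lvl("initiation"),
       cessation = lvl("cessation"))
}

marketing_effect_level <- function(schedule, effects, year) {
  yk <- as.character(year)
  enf <- schedule$marketing$enforcement
  w <- vapply(schedule$marketing$weights, `[[`, numeric(1), yk)
  lvl <- function(field) {
    base <- sum(w * vapply(names(w), function(l)
      effects$marketing[[l]][[field]], numeric(1)))
    deflate_effect(base, enf, publicity = NULL)
  }
  list(prevalence = lvl("prevalence"), initiation = lvl("initiation"),
       cessation = lvl("cessation"))
}

cessation_effect_level <- function(schedule, effects, year) {
  yk <- as.character(year)
  cmp <- effects$cessation_treatment
  comps <- setdiff(names(cmp), "package_total")
  cov <- vapply(schedule$cessation_treatment$components, `[[`, numeric(1),
                yk)[comps]
  scaled <- function(field, coverage) {
    vapply(comps, function(cc) cmp[[cc]][[field]], numeric(1)) * coverage
  }
  # rescale the multiplicative combination so a fully implemented package
  # reproduces the published package totals
  full_prev <- combine_effects(scaled("prevalence", 1))
  full_cess <- prod(1 + scaled("cessation", 1)) - 1
  list(
    prevalence = combine_effects(scaled("prevalence", cov)) *
      cmp$package_total$prevalence / full_prev,
    initiation = 0,
    cessation = (prod(1 + scaled("cessation", cov)) - 1) *
      cmp$package_total$cessation / full_cess
  )
}

youth_access_effect_level <- function(schedule, effects, year) {
  lvl <- schedule$youth_access[[as.character(year)]]
  e <- effects$youth_access[[lvl]]
  by_age <- rep(0, 100)
  by_age[10:15 + 1] <- e[["10-15"]]
  by_age[16:17 + 1] <- e[["16-17"]]
  list(prevalence = by_age, initiation = by_age, cessation = 0)
}

# Publicity indicator: 1 when media campaigns are at a medium level or
# above (moderate + high mixture weight >= 0.5).
publicity_indicator <- function(schedule, year) {
  yk <- as.character(year)
  w <- schedule$media$weights
  as.integer(w$moderate[[yk]] + w$high[[yk]] >= 0.5)
}

#' Translate a policy schedule into yearly model deltas
#'
#' For every year of the schedule, computes each policy's deflated,
#' coverage-weighted effect level and derives: the first-year prevalence
#' shock from incremental level changes (plus the elasticity-mediated
#' price shock), the ongoing fractional initiation-rate reduction, and
#' the ongoing fractional cessation-rate increase, each resolved by
#' single age (youth-access effects apply only to ages 10-15 and 16-17;
#' price effects follow the elasticity age bands; other policies apply
#' from age 10 up). Effects of simultaneous policies combine
#' multiplicatively. No shock is emitted for the first schedule year:
#' the initial prevalence is taken to embody the starting policy levels.
#'
#' @param schedule A [read_policy_schedule()] object.
#' @param effects An [effect_size_table()].
#' @param years Years to cover (default the schedule's span). Years past
#'   the schedule hold its final levels (no further shocks).
#' @return An object of class `policy_deltas`: a list with `years` and
#'   matrices `prevalence_shock`, `initiation_delta`, `cessation_delta`
#'   (year x age). Initiation deltas are negative fractions, cessation
#'   deltas positive.
#' @export
schedule_to_deltas <- function(schedule, effects = effect_size_table(),
                               years = schedule$years) {
  years <- as.integer(years)
  nm <- list(year = as.character(years), age = as.character(AGES))
  shock <- init_d <- cess_d <- matrix(
    0, length(years), 100, dimnames = nm)
  lvl_year <- function(y) {
    y <- min(max(y, min(schedule$years)), max(schedule$years))
    pub <- publicity_indicator(schedule, y)
    list(
      sfa = sfa_effect_level(schedule, effects, y, pub),
      media = media_effect_level(schedule, effects, y),
      marketing = marketing_effect_level(schedule, effects, y),
      cessation = cessation_effect_level(schedule, effects, y),
      youth = youth_access_effect_level(schedule, effects, y),
      price = schedule$price[[as.character(y)]]
    )
  }
  el_age <- elasticity_by_age(effects)
  smoking_ages <- AGES >= 10
  prev_lvl <- lvl_year(years[1])
  for (i in seq_along(years)) {
    lvl <- lvl_year(years[i])
    # ongoing deltas from active policy levels
    adult <- combine_effects(c(lvl$sfa$initiation, lvl$media$initiation,
                               lvl$marketing$initiation))
    init_red <- ifelse(smoking_ages,
                       1 - (1 - adult) * (1 - lvl$youth$initiation), 0)
    init_d[i, ] <- -init_red
    cess_up <- (1 + lvl$sfa$cessation) * (1 + lvl$media$cessation) *
      (1 + lvl$marketing$cessation) * (1 + lvl$cessation$cessation) - 1
    cess_d[i, ] <- ifelse(smoking_ages, cess_up, 0)
    # first-year shocks from incremental level changes
    if (i > 1) {
      s_scalar <- vapply(c("sfa", "media", "marketing", "cessation"),
                         function(p) incremental_effect(
                           prev_lvl[[p]]$prevalence, lvl[[p]]$prevalence),
                         numeric(1))
      s_youth <- 1 - (1 - lvl$youth$prevalence) /
        (1 - prev_lvl$youth$prevalence)
      s_price <- -price_effect(prev_lvl$price, lvl$price, el_age)
      comb <- 1 - (1 - combine_effects(s_scalar)) * (1 - s_youth) *
        (1 - s_price)
      shock[i, ] <- ifelse(smoking_ages, comb, 0)
    }
    prev_lvl <- lvl
  }
  structure(list(years = years, prevalence_shock = shock,
                 initiation_delta = init_d, cessation_delta = cess_d),
            class = "policy_deltas")
}

#' Extract one year's deltas
#'
#' @param deltas A [schedule_to_deltas()] object.
#' @param year Calendar year; years outside the covered span yield zero
#'   deltas.
#' @return List with `prevalence_shock`, `initiation_delta`,
#'   `cessation_delta` vectors over ages 0-99.
#' @export
deltas_for_year <- function(deltas, year) {
  if (is.null(deltas) || !year %in% deltas$years) {
    z <- rep(0, 100)
    return(list(prevalence_shock = z, initiation_delta = z,
                cessation_delta = z))
  }
  yk <- as.character(year)
  list(prevalence_shock = deltas$prevalence_shock[yk, ],
       initiation_delta = deltas$initiation_delta[yk, ],
       cessation_delta = deltas$cessation_delta[yk, ])
}

#' Apply a first-year prevalence shock to a population state
#'
#' Reduces current smokers at each age by the shock fraction, moving
#' them to never smokers below the gender's peak initiation age and to
#' the quit < 1 year former bin at or above it. Negative shocks (policy
#' rollback or a price fall) move people back into smoking, drawn from
#' the quit < 1 year bin (adults) or never smokers (below the peak age),
#' bounded by the source cell.
#'
#' @param state A [population_state()].
#' @param shock Numeric vector over ages 0-99 of fractional prevalence
#'   reductions (may be negative).
#' @param peak_age Named vector of peak initiation ages by gender.
#' @return The shocked [population_state()].
#' @export
apply_prevalence_shock <- function(state, shock,
                                   peak_age = c(male = 22, female = 25)) {
  if (any(shock >= 1)) stop("prevalence shock must be < 1")
  counts <- state$counts
  for (g in GENDERS) {
    young <- AGES < peak_age[[g]]
    cur <- counts[g, , "current"]
    moved <- cur * shock               # positive = leaving smoking
    leaving <- pmax(moved, 0)
    counts[g, , "current"] <- cur - leaving
    counts[g, , "never"] <- counts[g, , "never"] + leaving * young
    counts[g, , "former_<1"] <- counts[g, , "former_<1"] + leaving * !young
    returning <- pmax(-moved, 0)       # rollback: back into smoking
    if (any(returning > 0)) {
      from_never <- pmin(returning, counts[g, , "never"]) * young
      from_former <- pmin(returning, counts[g, , "former_<1"]) * !young
      counts[g, , "never"] <- counts[g, , "never"] - from_never
      counts[g, , "former_<1"] <- counts[g, , "former_<1"] - from_former
      counts[g, , "current"] <- counts[g, , "current"] + from_never +
        from_former
    }
  }
  state$counts <- counts
  state
}
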