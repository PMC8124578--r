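#' Read a policy schedule from a YAML configuration
#'
#' A schedule gives, per policy and calendar year, the policy level:
#' inflation-adjusted cigarette price per pack; smoke-free-air coverage
#' fractions per venue (worksite split into high/mid/low ban strength);
#' media-campaign level mixture weights (minimal/moderate/high, summing
#' to 1); marketing-restriction mixture weights; cessation-treatment
#' component coverages; and the youth-access enforcement level. Series
#' are written as year-keyed keyframes with `interp: linear` or
#' `interp: step` and expanded to every year in the schedule range.
#'
#' @param path Path to the YAML file.
#' @return An object of class `policy_schedule`.
#' @export
read_policy_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$years)) stop("schedule must declare years: {start, end}")
  years <- cfg$years$start:cfg$years$end
  series <- function(spec, what, numeric = TRUE) {
    if (is.null(spec)) stop("missing policy series: ", what)
    interp_keyframes(spec, years, what, numeric)
  }
  sfa <- cfg$smoke_free_air
  med <- cfg$media
  mkt <- cfg$marketing
  ces <- cfg$cessation_treatment
  sched <- structure(list(
    name = cfg$name %||% basename(path),
    years = years,
    price = series(cfg$price, "price"),
    smoke_free_air = list(
      enforcement = sfa$enforcement %||% 0,
      venues = list(
        worksite = list(
          high = series(sfa$venues$worksite$high, "worksite.high"),
          mid  = series(sfa$venues$worksite$mid, "worksite.mid"),
          low  = series(sfa$venues$worksite$low, "worksite.low")
        ),
        restaurant = series(sfa$venues$restaurant, "restaurant"),
        bar        = series(sfa$venues$bar, "bar"),
        other      = series(sfa$venues$other, "other")
      )
    ),
    media = list(weights = lapply(
      setNames(c("minimal", "moderate", "high"),
               c("minimal", "moderate", "high")),
      function(l) series(med$weights[[l]], paste0("media.", l))
    )),
    marketing = list(
      enforcement = mkt$enforcement %||% 0,
      weights = lapply(
        setNames(c("minimal", "moderate", "comprehensive"),
                 c("minimal", "moderate", "comprehensive")),
        function(l) series(mkt$weights[[l]], paste0("marketing.", l))
      )
    ),
    cessation_treatment = list(components = lapply(
      setNames(c("availability", "financial_coverage", "quitline",
                 "brief_intervention"),
               c("availability", "financial_coverage", "quitline",
                 "brief_intervention")),
      function(cmp) series(ces$components[[cmp]],
                           paste0("cessation.", cmp))
    )),
    youth_access = series(cfg$youth_access$level, "youth_access.level",
                          numeric = FALSE)
  ), class = "policy_schedule")
  validate_policy_schedule(sched)
  sched
}

# Expand year-keyed keyframes to a full named series over `years`.
interp_keyframes <- function(spec, years, what, numeric = TRUE) {
  vals <- spec$values
  if (is.null(vals)) stop("series ", what, " must have a values: map")
  ky <- as.integer(names(vals))
  if (any(is.na(ky))) stop("series ", what, " keys must be years")
  o <- order(ky)
  ky <- ky[o]
  kv <- unlist(vals, use.names = FALSE)[o]
  method <- spec$interp %||% "linear"
  if (!numeric || method == "step") {
    idx <- findInterval(years, ky)
    if (any(idx == 0)) stop("series ", what, " starts after schedule start")
    out <- kv[idx]
  } else if (method == "linear") {
    kv <- as.numeric(kv)
    out <- stats::approx(ky, kv, xout = pmin(pmax(years, min(ky)), max(ky)),
                         method = "linear", rule = 2)$y
  } else {
    stop("unknown interpolation method '", method, "' for ", what)
  }
  setNames(out, years)
}

validate_policy_schedule <- function(s) {
  yrs <- as.character(s$years)
  if (any(s$price <= 0)) stop("cigarette prices must be positive")
  chk01 <- function(v, what) {
    if (any(v < 0 | v > 1)) stop(what, " coverage fractions must lie in [0,1]")
  }
  w <- s$smoke_free_air$venues$worksite
  chk01(w$high + w$mid + w$low, "worksite ban")
  chk01(s$smoke_free_air$venues$restaurant, "restaurant ban")
  chk01(s$smoke_free_air$venues$bar, "bar ban")
  chk01(s$smoke_free_air$venues$other, "other-place ban")
  for (grp in list(s$media$weights, s$marketing$weights)) {
    tot <- Reduce(`+`, grp)
    if (any(abs(tot - 1) > 1e-6)) {
      stop("level mixture weights must sum to 1 in every year")
    }
    for (v in grp) chk01(v, "mixture")
  }
  for (v in s$cessation_treatment$components) chk01(v, "cessation component")
  for (enf in c(s$smoke_free_air$enforcement, s$marketing$enforcement)) {
    if (enf < 0 || enf > 10) stop("enforcement must lie in [0, 10]")
  }
  if (!all(s$youth_access %in% c("none", "low", "moderate", "strong"))) {
    stop("youth_access level must be none/low/moderate/strong")
  }
  invisible(s)
}

#' Packaged US policy schedule, 1993-2019
#'
#' The default US tobacco-control policy trajectory bundled with the
#' package: inflation-adjusted cigarette prices, smoke-free-air coverage
#' by venue, media-campaign and marketing-restriction level mixtures,
#' cessation-treatment component coverages and youth-access enforcement,
#' 1993-2019.
#'
#' @return A [read_policy_schedule()] object.
#' @export
default_policy_schedule <- function() {
  read_policy_schedule(system.file("extdata", "us_policy_1993_2019.yaml",
                                   package = "smokesim", mustWork = TRUE))
}

#' Freeze a policy schedule at a reference year
#'
#' Holds every policy series constant at its level in `at_year` for all
#' later years (the "no policy change" scenario convention), leaving
#' earlier years untouched.
#'
#' @param schedule A [read_policy_schedule()] object.
#' @param at_year Reference year.
#' @param policies Policies to freeze (default all; use to build
#'   "one policy changes alone" scenarios by freezing the others).
#' @return The modified schedule.
#' @export
freeze_schedule <- function(schedule, at_year,
                            policies = c("price", "smoke_free_air",
                                         "media", "marketing",
                                         "cessation_treatment",
                                         "youth_access")) {
  yk <- as.character(at_year)
  later <- schedule$years > at_year
  frz <- function(v) { v[later] <- v[[yk]]; v }
  if ("price" %in% policies) schedule$price <- frz(schedule$price)
  if ("smoke_free_air" %in% policies) {
    v <- schedule$smoke_free_air$venues
    v$worksite <- lapply(v$worksite, frz)
    v$restaurant <- frz(v$restaurant); v$bar <- frz(v$bar)
    v$other <- frz(v$other)
    schedule$smoke_free_air$venues <- v
  }
  if ("media" %in% policies) {
    schedule$media$weights <- lapply(schedule$media$weights, frz)
  }
  if ("marketing" %in% policies) {
    schedule$marketing$weights <- lapply(schedule$marketing$weights, frz)
  }
  if ("cessation_treatment" %in% policies) {
    schedule$cessation_treatment$components <-
      lapply(schedule$cessation_treatment$components, frz)
  }
  if ("youth_access" %in% policies) {
    schedule$youth_access <- frz(schedule$youth_access)
  }
  schedule
}

#' @export
print.policy_schedule <- function(x, ...) {
  cat("<policy_schedule>", x$name, "| years", min(x$years), "-",
      max(x$years), "\n")
  invisible(x)
}
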