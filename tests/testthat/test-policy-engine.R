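test_that("deflator algebra matches its two published forms", {
  # 0.5 * (1 + 0.5*publicity + 0.5*enforcement/10)
  expect_equal(deflate_effect(0.06, enforcement = 10, publicity = 1),
               0.06)
  expect_equal(deflate_effect(0.06, enforcement = 8, publicity = 1),
               0.06 * 0.5 * (1 + 0.5 + 0.5 * 0.8))
  expect_equal(deflate_effect(0.06, enforcement = 0, publicity = 0),
               0.03)
  # enforcement-only variant: 0.5 * (1 + enforcement/10)
  expect_equal(deflate_effect(0.05, enforcement = 9, publicity = NULL),
               0.05 * 0.5 * (1 + 0.9))
})

test_that("multiplicative combination is order-invariant and bounded", {
  e <- c(0.06, 0.02, 0.01, 0.01)
  expect_equal(combine_effects(e), 1 - prod(1 - e))
  for (seed in 1:10) {
    set.seed(seed)
    p <- sample(length(e))
    expect_equal(combine_effects(e[p]), combine_effects(e))
  }
  expect_lt(combine_effects(rep(0.5, 10)), 1)
  expect_equal(combine_effects(numeric(0)), 0)
  expect_error(combine_effects(c(0.5, 1)), "< 1")
  # negative components (policy rollback) are allowed
  expect_equal(combine_effects(c(0.1, -0.1)), 1 - 0.9 * 1.1)
})

test_that("price and incremental effects", {
  # relative form: elasticity * (p_new - p_old) / p_old
  expect_equal(price_effect(4, 5, -0.4), -0.4 * 0.25)
  expect_equal(price_effect(4, 5, -0.4, form = "log"),
               -0.4 * log(5 / 4))
  expect_equal(incremental_effect(0.2, 0.4), 1 - 0.6 / 0.8)
  expect_equal(incremental_effect(0.3, 0.3), 0)
  el <- elasticity_by_age()
  expect_length(el, 100)
  expect_equal(unname(el[15]), -0.6)  # age 14
  expect_equal(unname(el[20]), -0.4)  # age 19
  expect_equal(unname(el[70]), -0.2)  # age 69
  expect_equal(unname(el[10]), 0)     # below smoking ages
})

test_that("cessation package combination is rescaled to its stated total", {
  eff <- effect_size_table()
  s <- default_policy_schedule()
  # at full coverage the package must hit the stated package totals,
  # not the raw multiplicative combination of its components
  full <- s
  for (f in names(full$cessation_treatment$components)) {
    full$cessation_treatment$components[[f]][] <- 1
  }
  lvl <- smokesim:::cessation_effect_level(full, eff, max(full$years))
  expect_equal(lvl$prevalence, eff$cessation_treatment$package_total$prevalence)
  expect_equal(lvl$cessation, eff$cessation_treatment$package_total$cessation)
})

test_that("schedule deltas: no first-year shock, signs are coherent", {
  s <- default_policy_schedule()
  d <- schedule_to_deltas(s, effect_size_table(), years = s$years)
  expect_s3_class(d, "policy_deltas")
  expect_equal(max(abs(d$prevalence_shock[1, ])), 0)
  # strengthening policies cut initiation and raise cessation
  expect_true(all(d$initiation_delta <= 1e-12))
  expect_true(all(d$cessation_delta >= -1e-12))
})

test_that("prevalence monotonicity: stronger policies, lower prevalence", {
  w <- gen_world(world_config(seed = 21, years = 2008:2018))
  base <- run_counterfactual(w, "no_policy")
  eff <- effect_size_table()
  s <- default_policy_schedule()
  prev_end <- function(effects) {
    d <- schedule_to_deltas(s, effects, years = 2008:2018)
    inp <- w$inputs
    inp$deltas <- d
    sc <- run_counterfactual(inp, "policy")
    smoking_prevalence(sc$states[[length(sc$states)]])
  }
  p_base <- smoking_prevalence(base$states[[length(base$states)]])
  p_mid <- prev_end(eff)
  p_strong <- prev_end(scale_effects(eff, 1.5))
  p_weak <- prev_end(scale_effects(eff, 0.5))
  expect_lt(p_mid, p_base)
  expect_lt(p_strong, p_mid)
  expect_gt(p_weak, p_mid)
})

test_that("prevalence shock reallocates by age and rolls back boundedly", {
  st <- empty_population(2010)
  st$counts["male", "18", "never"] <- 50
  st$counts["male", "18", "current"] <- 100
  st$counts["male", "40", "current"] <- 100
  st$counts["male", "40", "former_<1"] <- 5
  shock <- rep(0, 100)
  shock[c(19, 41)] <- 0.10  # ages 18 and 40
  out <- apply_prevalence_shock(st, shock)
  # below the peak age the leavers return to never
  expect_equal(out$counts["male", "18", "current"], 90)
  expect_equal(out$counts["male", "18", "never"], 60)
  # at/above the peak they become recent quitters
  expect_equal(out$counts["male", "40", "current"], 90)
  expect_equal(out$counts["male", "40", "former_<1"], 15)
  # a rollback draws back from the shock pools, bounded by their size
  back <- rep(0, 100)
  back[41] <- -0.50
  out2 <- apply_prevalence_shock(out, back)
  expect_equal(out2$counts["male", "40", "former_<1"], 0)
  expect_equal(out2$counts["male", "40", "current"], 105)
  expect_true(all(out2$counts >= 0))
})

test_that("schedule IO: keyframe interpolation and freezing", {
  s <- default_policy_schedule()
  expect_s3_class(s, "policy_schedule")
  expect_equal(range(s$years), c(1993, 2019))
  # linear price keyframes 2002: 3.60 -> 2012: 5.60
  expect_equal(s$price[["2007"]], 4.60)
  f <- freeze_schedule(s, at_year = 2012)
  expect_equal(f$price[["2019"]], s$price[["2012"]])
  expect_equal(f$price[["2000"]], s$price[["2000"]])
})
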