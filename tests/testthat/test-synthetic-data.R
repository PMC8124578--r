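test_that("world config validates and records its seed", {
  expect_error(world_config(peak_prev = c(male = 1.2, female = 0.2)))
  expect_error(world_config(relapse_rates = c(0.1, 0.2, 0.1, 0.1, 0.1,
                                              0.1)))
  w <- gen_world(world_config(seed = 77, years = 2000:2005))
  expect_identical(w$seed, 77L)
})

test_that("generated world is internally consistent", {
  w <- gen_world(world_config(seed = 5, years = 2000:2010))
  st <- w$inputs$initial_state
  expect_true(all(st$counts >= 0))
  # initial cross-section matches the truth curve at every age
  for (g in c("male", "female")) {
    tot <- rowSums(st$counts[g, , ])
    prev <- ifelse(tot > 0, st$counts[g, , "current"] / tot, 0)
    expect_equal(unname(prev), w$truth$prev_curves[[g]],
                 tolerance = 1e-12)
  }
  # mortality respects d_current >= d_never
  expect_true(all(w$inputs$mortality$d_current >=
                    w$inputs$mortality$d_never))
})

test_that("net-initiation replay oracle reproduces the input curve", {
  w <- gen_world(world_config(seed = 7, years = 2000:2025))
  sc <- run_counterfactual(w, "baseline")
  for (yr in c(2001, 2010, 2025)) {
    st <- sc$states[[which(sc$years == yr)]]
    for (g in c("male", "female")) {
      peak <- w$config$peak_age[[g]]
      ages <- as.character(10:peak)
      tot <- rowSums(st$counts[g, ages, ])
      prev <- st$counts[g, ages, "current"] / tot
      expect_equal(unname(prev),
                   w$truth$prev_curves[[g]][10:peak + 1],
                   tolerance = 1e-9)
    }
  }
})

test_that("survey sampling is seeded, unbiased and leaves RNG alone", {
  truth <- data.frame(year = c(2012, 2018), gender = "male",
                      age_group = "18+", prevalence = c(0.20, 0.15))
  s1 <- gen_survey_series(truth, 25000, seed = 42)
  s2 <- gen_survey_series(truth, 25000, seed = 42)
  expect_identical(s1$prevalence, s2$prevalence)
  s3 <- gen_survey_series(truth, 25000, seed = 43)
  expect_false(identical(s1$prevalence, s3$prevalence))
  # the global RNG stream is restored around the draw
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(gen_survey_series(truth, 25000, seed = 99))
  expect_identical(runif(1), before)
  # CIs bracket the point estimate; Wilson intervals also valid
  expect_true(all(s1$ci_lower <= s1$prevalence &
                    s1$prevalence <= s1$ci_upper))
  sw <- gen_survey_series(truth, 400, seed = 7, method = "wilson")
  expect_true(all(sw$ci_lower <= sw$prevalence &
                    sw$prevalence <= sw$ci_upper))
  expect_true(all(sw$ci_lower >= 0 & sw$ci_upper <= 1))
})

test_that("injected vaping effect compounds from the start year", {
  truth <- data.frame(year = 2010:2015, gender = "male",
                      age_group = "18+", prevalence = 0.20)
  out <- inject_nvp_effect(truth, a_star = 0.02, start_year = 2012)
  expect_equal(out$prevalence[out$year == 2011], 0.20)
  expect_equal(out$prevalence[out$year == 2012], 0.20)
  expect_equal(out$prevalence[out$year == 2015], 0.20 * 0.98^3)
  # gender-specific adjustors via a named vector
  truth2 <- data.frame(year = 2013, gender = c("male", "female"),
                       age_group = "18+", prevalence = 0.2)
  out2 <- inject_nvp_effect(truth2, c(male = 0.05, female = 0.01), 2012)
  expect_equal(out2$prevalence, 0.2 * c(0.95, 0.99))
})
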