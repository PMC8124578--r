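test_that("SADs equal a brute-force loop over cells", {
  st <- toy_state(seed = 13)
  ms <- toy_mortality(2000:2001, dn = 0.012, dc = 0.035)
  got <- compute_sads(st, ms)
  want <- c(male = 0, female = 0)
  for (g in c("male", "female")) {
    for (a in as.character(0:99)) {
      dn <- 0.012
      dc <- 0.035
      want[g] <- want[g] + st$counts[g, a, "current"] * (dc - dn)
      for (b in quit_bins()$bin) {
        df <- former_death_rate(dn, dc, b)
        want[g] <- want[g] +
          st$counts[g, a, paste0("former_", b)] * (df - dn)
      }
    }
  }
  expect_equal(got, want)
  expect_true(all(got > 0))
})

test_that("a population of never smokers has zero SADs", {
  st <- empty_population(2000)
  st$counts[, , "never"] <- 500
  ms <- toy_mortality(2000:2001)
  expect_equal(compute_sads(st, ms), c(male = 0, female = 0))
})

test_that("NVP adjustment removes smokers, reallocates by age 25", {
  w <- gen_world(world_config(seed = 17, years = 2008:2022))
  base <- run_counterfactual(w, "baseline")
  adj <- data.frame(gender = c("male", "female"), age_group = "18+",
                    a = c(0.03, 0.03))
  scn <- apply_nvp_adjustment(base, adj, start_year = 2012,
                              end_year = 2018, label = "nvp")
  i2018 <- which(scn$years == 2018)
  # untouched before the adjustment starts; afterwards the adjusted
  # world has at least as many survivors (fewer smoker deaths)
  for (i in seq_along(scn$years)) {
    tb <- total_population(base$states[[i]])
    ta <- total_population(scn$states[[i]])
    if (scn$years[i] <= 2012) expect_equal(ta, tb) else expect_gte(ta, tb)
  }
  cur_b <- sum(base$states[[i2018]]$counts[, , "current"])
  cur_a <- sum(scn$states[[i2018]]$counts[, , "current"])
  expect_lt(cur_a, cur_b)
  # under-25 leavers return to never, 25+ to recent quitters
  d <- scn$states[[i2018]]$counts - base$states[[i2018]]$counts
  young <- as.character(10:24)
  old <- as.character(25:99)
  expect_true(all(d[, young, "never"] >= -1e-9))
  expect_lt(max(abs(d[, young, "former_<1"])), 1e-9)
  expect_true(all(d[, old, "former_<1"] >= -1e-9))
  expect_gt(sum(d[, old, "former_<1"]), 0)
})

test_that("adjustment is held after its end year (no further drawdown)", {
  w <- gen_world(world_config(seed = 18, years = 2008:2024))
  base <- run_counterfactual(w, "baseline")
  adj <- data.frame(gender = c("male", "female"), age_group = "18+",
                    a = c(0.02, 0.02))
  scn <- apply_nvp_adjustment(base, adj, start_year = 2012,
                              end_year = 2018, label = "nvp")
  prev_ratio <- function(yr) {
    i <- which(scn$years == yr)
    smoking_prevalence(scn$states[[i]]) /
      smoking_prevalence(base$states[[i]])
  }
  # the ratio falls while the adjustor applies, then roughly stabilizes
  expect_lt(prev_ratio(2018), prev_ratio(2014))
  expect_lt(abs(prev_ratio(2021) - prev_ratio(2019)), 0.02)
})

test_that("deaths averted ledger and windows", {
  w <- gen_world(world_config(seed = 19, years = 2008:2022))
  base <- run_counterfactual(w, "baseline")
  adj <- data.frame(gender = c("male", "female"), age_group = "18+",
                    a = c(0.03, 0.03))
  scn <- apply_nvp_adjustment(base, adj, label = "nvp")
  av <- deaths_averted(sad_ledger(base), sad_ledger(scn))
  expect_identical(av$averted, av$sads_baseline - av$sads_adjusted)
  # cumulative column is the running sum within gender
  m <- av[av$gender == "male", ]
  expect_equal(m$cum_averted, cumsum(m$averted))
  # the adjusted scenario has no more SADs than baseline from 2013 on
  expect_true(all(av$averted[av$year >= 2013] >= -1e-9))
  s <- averted_summary(av, windows = list(w1 = c(2012, 2018),
                                          w2 = c(2012, 2022)))
  both <- s$averted[s$gender == "both"]
  expect_equal(both[1],
               sum(av$averted[av$year >= 2012 & av$year <= 2018]))
  expect_gte(both[2], both[1])
})

test_that("age-filtered adjustment only touches younger cohorts", {
  w <- gen_world(world_config(seed = 23, years = 2008:2020))
  base <- run_counterfactual(w, "baseline")
  adj <- data.frame(gender = c("male", "female"), age_group = "18+",
                    a = c(0.03, 0.03))
  scn <- apply_nvp_adjustment(base, adj, start_year = 2012,
                              end_year = 2018, max_age = 44,
                              label = "nvp_young")
  i2013 <- which(scn$years == 2013)
  d <- scn$states[[i2013]]$counts - base$states[[i2013]]$counts
  # in the first adjusted year, ages above the filter are untouched
  expect_lt(max(abs(d[, as.character(46:99), ])), 1e-9)
  expect_gt(max(abs(d[, as.character(10:44), ])), 0)
})
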