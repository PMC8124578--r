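test_that("population_state validates shape and negatives", {
  st <- toy_state()
  expect_s3_class(st, "population_state")
  bad <- st$counts
  bad["male", "30", "never"] <- -1
  expect_error(population_state(2000, bad), "negative")
  expect_error(population_state(2000, st$counts[, 1:50, ]))
})

test_that("prevalence helpers agree with direct arithmetic", {
  st <- toy_state(seed = 4)
  idx <- as.character(18:99)
  cur <- sum(st$counts[, idx, "current"])
  tot <- sum(st$counts[, idx, ])
  expect_equal(smoking_prevalence(st), cur / tot)
  pt <- prevalence_table(st)
  expect_true(all(c("year", "gender", "age_group", "prevalence") %in%
                    names(pt)))
  m18 <- pt$prevalence[pt$gender == "male" & pt$age_group == "18+"]
  expect_equal(m18, smoking_prevalence(st, gender = "male"))
})

test_that("mortality removes the scheduled fraction from each status", {
  st <- toy_state(year = 2000, seed = 9)
  ms <- toy_mortality(2000:2001, dn = 0.01, dc = 0.05)
  out <- evolve_population(st, ms)
  deaths <- attr(out, "deaths")
  expect_equal(sum(deaths[, , "never"]),
               0.01 * sum(st$counts[, , "never"]))
  expect_equal(sum(deaths[, , "current"]),
               0.05 * sum(st$counts[, , "current"]))
  # former_<1 carries the full smoker excess, >15 nearly none
  d1 <- former_death_rate(0.01, 0.05, "<1")
  expect_equal(sum(deaths[, , "former_<1"]),
               d1 * sum(st$counts[, , "former_<1"]))
})

test_that("quit-bin advancement moves 1/width per bin and conserves", {
  st <- toy_state(seed = 2)
  ms <- toy_mortality(2000:2001, dn = 0, dc = 0)  # isolate the bins
  out <- evolve_population(st, ms)
  expect_equal(total_population(out), total_population(st))
  # with zero mortality, former totals are conserved across bins
  f_in <- sum(st$counts[, , paste0("former_", quit_bins()$bin)])
  f_out <- sum(out$counts[, , paste0("former_", quit_bins()$bin)])
  expect_equal(f_out, f_in)
  # a pulse in former_<1 fully leaves the 1-year bin after one year
  pulse <- empty_population(2000)
  pulse$counts["male", "40", "former_<1"] <- 60
  out2 <- evolve_population(pulse, ms)
  expect_equal(out2$counts["male", "41", "former_<1"], 0)
  expect_equal(out2$counts["male", "41", "former_1-2"], 60)
})

test_that("aging shifts ages, births enter at age 0, age 99 absorbs", {
  st <- empty_population(2000)
  st$counts["female", "98", "never"] <- 10
  st$counts["female", "99", "never"] <- 5
  births <- matrix(c(7, 8), 2, 1,
                   dimnames = list(c("male", "female"), "2001"))
  drv <- demography_drivers(births = births, years = 2001)
  ms <- toy_mortality(2000:2001, dn = 0, dc = 0)
  out <- evolve_population(st, ms, drivers = drv)
  expect_equal(out$counts["female", "99", "never"], 15)  # closed top age
  expect_equal(out$counts["male", "0", "never"], 7)
  expect_equal(out$counts["female", "0", "never"], 8)
})

test_that("conservation ledger holds to 1e-9 on randomized small worlds", {
  for (seed in 1:5) {
    set.seed(seed)
    n_ages <- sample(3:5, 1)
    ages <- sort(sample(15:90, n_ages))
    st <- toy_state(year = 2000, ages = ages, seed = seed + 100)
    ms <- constant_mortality(matrix(runif(200, 0, 0.1), 2, 100),
                             matrix(runif(200, 0.1, 0.3), 2, 100),
                             2000:2001)
    rates <- toy_rates(seed = seed)
    # transitions conserve every gender x age cell exactly
    tr <- markov_step(st, rates)
    before <- apply(st$counts, c(1, 2), sum)
    after <- apply(tr$counts, c(1, 2), sum)
    expect_lt(max(abs(after - before)), 1e-9)
    expect_true(all(tr$counts >= -1e-12))
    # a full year: persons in = survivors + deaths, to 1e-9
    out <- evolve_population(tr, ms)
    deaths <- attr(out, "deaths")
    expect_lt(abs(total_population(out) + sum(deaths) -
                    total_population(tr)), 1e-9)
  }
})

test_that("migration adopts the destination cell's status mix", {
  st <- empty_population(2000)
  st$counts["male", "30", "never"] <- 80
  st$counts["male", "30", "current"] <- 20
  mig <- array(0, dim = c(2, 100, 1),
               dimnames = list(c("male", "female"), as.character(0:99),
                               "2001"))
  mig["male", "31", 1] <- 10  # arrives at the cell aged 31 in 2001
  drv <- demography_drivers(net_migration = mig, years = 2001)
  ms <- toy_mortality(2000:2001, dn = 0, dc = 0)
  out <- evolve_population(st, ms, drivers = drv)
  expect_equal(out$counts["male", "31", "never"], 88)
  expect_equal(out$counts["male", "31", "current"], 22)
})
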