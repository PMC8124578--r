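test_that("validate_report compares projections to surveys per period", {
  w <- gen_world(world_config(seed = 11, years = 1995:2014))
  sc <- run_counterfactual(w, "baseline")
  p <- sc$prevalence[sc$prevalence$age_group == "18+", ]
  truth <- p[p$year %in% c(1998, 2010, 2012), ]
  svy <- gen_survey_series(truth, 25000, seed = 2, survey = "svy_a")
  rep <- validate_report(p, svy)
  expect_equal(nrow(rep), 4)  # 2 genders x 2 periods
  r <- rep[rep$gender == "male" & rep$period_end == 2010, ]
  expect_equal(r$sim_R,
               relative_reduction(r$sim_p_start, r$sim_p_end))
  expect_equal(r$diff_R, r$survey_R - r$sim_R)
  # simulated truth should rarely sit outside its own survey's CI
  expect_true(mean(rep$sim_level_outside_ci) <= 0.5)
})

test_that("report JSON round-trips", {
  w <- gen_world(world_config(seed = 11, years = 1995:2012))
  sc <- run_counterfactual(w, "baseline")
  p <- sc$prevalence[sc$prevalence$age_group == "18+", ]
  truth <- p[p$year %in% c(1998, 2010), ]
  svy <- gen_survey_series(truth, 10000, seed = 3, survey = "svy_a")
  rep <- validate_report(p, svy, periods = list(c(1998, 2010)))
  path <- file.path(tempdir(), "report.json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$sim_R, rep$sim_R)
  unlink(path)
})

test_that("sensitivity sweep spans scenarios and behaves monotonically", {
  w <- gen_world(world_config(seed = 5, years = 2006:2019))
  base <- run_counterfactual(w, "baseline")
  sw <- sensitivity_sweep(base, default_policy_schedule(),
                          period = c(2012, 2018))
  expect_true("no_policy_change" %in% sw$scenario)
  expect_true(all(c("price_alone", "all_policies") %in% sw$scenario))
  # no-policy rows anchor the differences at zero
  expect_equal(sw$diff_from_no_policy[sw$scenario == "no_policy_change"],
               c(0, 0))
  # each policy alone: larger effect sizes give at least as much decline
  for (g in c("male", "female")) {
    for (scen in setdiff(unique(sw$scenario), "no_policy_change")) {
      r <- sw[sw$scenario == scen & sw$gender == g, ]
      lo <- r$relative_reduction[grepl("^-", r$range)]
      mid <- r$relative_reduction[r$range == "0%"]
      hi <- r$relative_reduction[grepl("^\\+", r$range)]
      expect_lte(lo, mid + 1e-12)
      expect_lte(mid, hi + 1e-12)
    }
    # combined policies outdo every single policy at the same range
    all0 <- sw$relative_reduction[sw$scenario == "all_policies" &
                                    sw$range == "0%" & sw$gender == g]
    singles <- sw$relative_reduction[sw$scenario != "all_policies" &
                                       sw$scenario != "no_policy_change" &
                                       sw$range == "0%" & sw$gender == g]
    expect_true(all(all0 >= singles - 1e-12))
  }
  # every scenario starts from the same frozen 2012 state
  expect_equal(length(unique(round(sw$p_start[sw$gender == "male"], 12))),
               1)
})

test_that("run outputs and manifest are written once per directory", {
  w <- gen_world(world_config(seed = 9, years = 2010:2014))
  sc <- run_counterfactual(w, "demo")
  dir <- file.path(tempdir(), "smokesim-run-test")
  unlink(dir, recursive = TRUE)
  write_run_outputs(sc, dir, seed = 9)
  expect_true(file.exists(file.path(dir, "prevalence.csv")))
  expect_true(file.exists(file.path(dir, "sads.csv")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$seed, 9)
  expect_equal(man$label, "demo")
  prev <- read.csv(file.path(dir, "prevalence.csv"))
  expect_equal(sort(unique(prev$year)), 2010:2014)
  unlink(dir, recursive = TRUE)
})
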