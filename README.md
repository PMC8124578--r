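# smokesim

A SimSmoke-family simulation model of cigarette smoking prevalence and
smoking-attributable deaths (SADs), with an indirect-inference toolkit
for estimating the population impact of nicotine vaping products (NVPs)
from the divergence between a no-vaping counterfactual projection and
national survey trends (TUS-CPS, NHIS).

## The scientific problem

US adult smoking prevalence fell much faster after 2012 — the year NVP
use began to expand rapidly — than established tobacco-control policy
models projected. Because vaping's effects on initiation and cessation
are hard to measure directly, an *indirect* method is used:

1. Project a **no-NVP counterfactual**: a discrete-time compartmental
   model of never/current/former smokers, driven by demography and by
   the measured 1993–2019 tobacco-control policy environment (prices,
   smoke-free-air laws, media campaigns, marketing restrictions,
   cessation treatment, youth access), validated against surveys over
   1993–2012 (the pre-NVP era).
2. Compare the counterfactual's 2012–2018 relative reduction in smoking
   prevalence with the survey-observed reduction.
3. Attribute the excess decline to NVPs and convert it into an **annual
   vaping adjustor**, then re-run the model with the adjustor to count
   **deaths averted**.

## Core model

Population state: persons by gender × single year of age (0–99) ×
smoking status, with former smokers split into six years-quit bins
(<1, 1–2, 3–5, 6–10, 11–15, >15). Each simulated year applies, in
order: mortality → smoking-status transitions → quit-bin advancement →
aging/births/migration.

Key relationships (all implemented as small documented functions):

- **Former-smoker excess risk** decays on a log scale,
  `RR_former(b) = exp(X_b · ln RR_smoker)` with
  X = (1, 0.92, 0.79, 0.58, 0.325, 0.08) across the quit bins
  (`former_smoker_rr()`).
- **Net initiation** is identified from a cross-sectional prevalence
  curve: `rate(a+1) = (prev(a+1) − prev(a)) / never(a)` up to the
  gender-specific peak age (22 male, 25 female)
  (`net_initiation_from_cross_section()`).
- **Policy effects** enter as effect sizes deflated by enforcement and
  publicity, `0.5·(1 + 0.5·Publicity + 0.5·Enforcement/10)`, combined
  multiplicatively `1 − ∏(1 − e_i)`, with age-banded price
  elasticities (`deflate_effect()`, `combine_effects()`,
  `schedule_to_deltas()`).
- **NVP inference**: relative reduction `R = (p0 − p1)/p0`, annualized
  as `1 − (1 − R)^(1/6)`; the annual adjustor is the difference of the
  annualized survey and counterfactual rates (`annualize()`,
  `nvp_adjustor()`, `infer_nvp()`).
- **SADs** are excess deaths of current and former smokers over the
  never-smoker rate, summed over cells (`compute_sads()`), and deaths
  averted are the SAD difference between the counterfactual and the
  vaping-adjusted run (`apply_nvp_adjustment()`, `deaths_averted()`).

## Worked example

```r
library(smokesim)

# A synthetic world with known ground truth (annual adjustor 2%/yr)
w <- gen_world(world_config(seed = 1, years = 2005:2019))
baseline <- run_counterfactual(w, label = "no_nvp")
baseline
#> <scenario_result> no_nvp | years 2005 - 2019
#>   male adult prevalence: 23.0% -> 17.9%
#>   female adult prevalence: 19.4% -> 15.3%

# Counterfactual 18+ prevalence at the comparison endpoints
p <- baseline$prevalence
sim <- p[p$age_group == "18+" & p$year %in% c(2012, 2018), ]

# Observed world: inject the true vaping effect, sample a survey
truth <- transform(sim, survey = "survey")
truth <- inject_nvp_effect(truth, w$truth$a_star, 2012)
svy <- gen_survey_series(truth[, c("year", "gender", "age_group",
                                   "prevalence")],
                         n_per_wave = 25000, seed = 1, survey = "svy")

# Indirect inference of the vaping impact
infer_nvp(sim, svy, period = c(2012, 2018))[, c("gender", "sim_R",
                                                "survey_R", "adjustor")]
#>   gender      sim_R  survey_R   adjustor
#> 1   male 0.09381129 0.2125324 0.02275579
#> 2 female 0.08648438 0.1659585 0.01482980

# Deaths averted under the recovered adjustor
adj <- data.frame(gender = c("male", "female"), age_group = "18+",
                  a = c(0.0228, 0.0148))
adjusted <- apply_nvp_adjustment(baseline, adj, 2012, 2018, label = "nvp")
av <- deaths_averted(sad_ledger(baseline), sad_ledger(adjusted))
averted_summary(av, windows = list(`2012-2018` = c(2012, 2018)))
#>      window gender   averted
#> 1 2012-2018 female  5.028272
#> 2 2012-2018   male  8.855214
#> 3 2012-2018   both 13.883486
```

The bundled US policy schedule and published survey tables are
available via `default_policy_schedule()`, `us_survey_prevalence()`,
`us_printed_changes()` and `us_printed_reductions()`;
`sensitivity_sweep()` reproduces the marginal policy sensitivity
design and `validate_report()` the pre-NVP validation statistics.

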