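---
title: "smokesim: model, methods and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{smokesim: model, methods and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesim)
```

## Overview

`smokesim` implements a SimSmoke-family discrete-time compartmental
model of cigarette smoking and an indirect-inference method for
quantifying the impact of nicotine vaping products (NVPs) on smoking
prevalence and smoking-attributable deaths (SADs). The logic is:
project what smoking *would have done* after 2012 without vaping,
given the measured tobacco-control policy environment; compare with
what surveys observed; attribute the excess decline to NVPs.

## Population model

The state is a `population_state`: expected (fractional) person counts
by gender × single year of age (0–99) × smoking status, where former
smokers occupy six years-quit bins (<1, 1–2, 3–5, 6–10, 11–15, >15
years). Each simulated year applies, in this order:

1. **Mortality** — status-specific annual death probabilities. Former
   smokers use the excess-risk ladder: with smoker relative risk
   $RR = d_{cur}/d_{nev}$, a former smoker in bin $b$ has
   $RR_b = \exp(X_b \ln RR)$, $X = (1.00, 0.92, 0.79, 0.58, 0.325,
   0.08)$, so the death rate is $d_{nev} \cdot RR_b$
   (`former_death_rate()`).
2. **Smoking transitions** (`markov_step()`) — all flows computed from
   the same starting state: net initiation (never → current) up to the
   gender-specific peak-prevalence age (22 male, 25 female), cessation
   (current → former, quit <1 bin) above it, and bin-specific relapse
   (former → current). Policy deltas scale the base rates
   multiplicatively, clipped to [0, 1].
3. **Quit-bin advancement** — assuming quit times uniform within a
   bin, the fraction $1/w_b$ of a width-$w_b$ bin crosses into the
   next bin each year; the >15 bin is absorbing.
4. **Aging, births, migration** — everyone ages one year; age 99 is
   closed (survivors remain); newborns enter at age 0 as never
   smokers; net migrants adopt the smoking-status mix of their
   destination cell.

The ordering matters: transitions act on post-mortality counts, and a
rate indexed by "age $a{+}1$" (e.g. initiation derived from the
prevalence difference between ages $a$ and $a{+}1$) is applied to
age-$a$ persons *before* they age. The test suite pins this with an
exact forward-replay oracle (below).

### Net initiation from a cross-section

Direct initiation and early cessation are poorly identified
separately, so the model uses *net* initiation recovered from a
cross-sectional prevalence curve:

$$\text{rate}(a{+}1) = \frac{prev(a{+}1) - prev(a)}{never(a)},$$

applied for ages 10 through the peak age
(`net_initiation_from_cross_section()`). Negative sampling dips are
clipped to zero with a warning. Gender-specific calibration
multipliers (+30% male, +15% female, reflecting rising young-adult
smoking in the mid-1990s) scale initiation only
(`apply_calibration()`).

## Policy engine

A `policy_schedule` (YAML, year-keyed keyframes with linear or step
interpolation; the bundled `default_policy_schedule()` covers the US
1993–2019) is translated into yearly model deltas by
`schedule_to_deltas()`:

- Effect sizes are deflated for imperfect enforcement/publicity:
  $e \cdot 0.5(1 + 0.5\,Pub + 0.5\,Enf/10)$, or the enforcement-only
  variant $e \cdot 0.5(1 + Enf/10)$ for marketing restrictions
  (`deflate_effect()`).
- Simultaneous policies combine multiplicatively,
  $1 - \prod_i (1 - e_i)$ (`combine_effects()`); the combination is
  order-invariant and bounded below 1. The cessation-treatment
  components are rescaled so a fully implemented package reproduces
  its published package totals (−5.68% prevalence, +29.4% cessation)
  rather than the slightly smaller raw multiplicative combination.
- Price works through age-banded elasticities (−0.6 at 14–17, −0.4 at
  18–24, −0.2 at 25–34, −0.1 at 35–64, −0.2 at 65+) on relative price
  changes (`price_effect()`, `elasticity_by_age()`).
- A policy *change* produces a one-time prevalence shock in its first
  year (never applied in the schedule's first year) via the
  incremental effect $1 - (1-e_{new})/(1-e_{old})$, plus ongoing
  initiation reductions and cessation increases. Shock leavers below
  the peak age return to never smokers; at or above it they become
  recent quitters; negative shocks draw back boundedly
  (`apply_prevalence_shock()`).

`sensitivity_sweep()` reproduces the marginal sensitivity design:
every policy alone at central/low/high effect sizes (±25% price, ±50%
others) against a schedule frozen at the period start, plus the
all-policies scenario.

## NVP indirect inference

For a period $[y_0, y_1]$ (canonically 2012–2018, $n = 6$ years):

- relative reduction $R = (p_0 - p_1)/p_0$ (`relative_reduction()`);
- annualization $1 - (1 - R)^{1/n}$, exactly invertible by
  compounding (`annualize()`);
- the **annual vaping adjustor** is the difference of annualized
  survey and counterfactual rates (`nvp_adjustor()`);
- survey uncertainty propagates by carrying the end-year prevalence CI
  through the reduction, holding the start year fixed
  (`propagate_bounds()`); a projection is flagged when it falls
  strictly outside the closed interval (`outside_ci_flag()`);
- a missing survey wave is reconstructed as a 60/40 weighted average
  of the surrounding waves (`interpolate_wave()`).

`infer_nvp()` assembles these per survey × gender × age group.
`apply_nvp_adjustment()` re-runs the dynamics from the period start,
multiplying current smokers by $(1-a)$ each year of the adjustment
window; leavers under age 25 return to never smokers and those 25+
become recent quitters. After the window the adjustor is held (no
further drawdown, but its cumulative effect persists). An optional
`max_age` restricts the adjustment to younger cohorts. SADs are excess
deaths over the never-smoker rate (`compute_sads()`), and
`deaths_averted()` ledgers the difference between the counterfactual
and adjusted runs.

Note that when a *compounding* effect $(1-a^\*)^{t-2012}$ is injected
into a declining trajectory, the adjustor recovered from endpoint
reductions is exactly $a^\* (1 - R_{sim})^{1/6}$, slightly below
$a^\*$; the inference tests use this closed form.

## Synthetic worlds

`gen_world()` builds a fully synthetic population with known ground
truth: a prevalence curve rising linearly from age 10 to the peak,
plateauing to age 45, then declining; Gompertz-like never-smoker
mortality with a smoker relative risk ramping from 1 (age 30) to 2.5
(age 55+); cessation 4.5%/yr above the peak; non-increasing relapse by
quit bin. Net initiation is *derived from the curve through the
cross-sectional identity*, which yields the central oracle: replaying
the generated rates reproduces the input curve below the peak age to
machine precision. `gen_survey_series()` draws binomial survey waves
(seeded, RNG-state preserving, normal or Wilson CIs) and
`inject_nvp_effect()` compounds a known adjustor into the truth.

Passing the recovery test shows the *pipeline* is consistent — the
injected adjustor is recovered within binomial sampling error — not
that the substantive US estimates are correct: the synthetic world
shares the model's structural assumptions by construction.

## Parameter defaults and provenance

Defaults are the published SimSmoke-family values: the quit-bin RR
exponents; peak ages 22/25; calibration multipliers 1.30/1.15; the
policy effect-size table (smoke-free air by venue, media and marketing
level mixtures, cessation-treatment components with package totals,
youth-access by enforcement level); the elasticity age bands; the
60/40 wave interpolation; and the bundled US policy trajectory and
published 1993–2018 prevalence tables (`us_survey_prevalence()`,
`us_printed_changes()`, `us_printed_reductions()`). Synthetic-world
defaults (100k persons/gender, peak prevalence 28%/24%) are sized so
the full test suite runs in seconds while keeping survey sampling
error realistic at n = 25,000 per wave.

## Numerical choices

- Deterministic expected-value dynamics (fractional counts); the only
  randomness is survey sampling, always behind an explicit seed.
- Conservation is exact by construction: transition flows are computed
  from the starting state, and the tests pin a persons-in =
  survivors + deaths ledger at 1e-9 per cell.
- Annualization uses `1 - (1-R)^(1/n)` directly; the round-trip is
  exact to 1e-12.
- Published derived cells are regenerated from published inputs with a
  three-tier classification (exact at 1 decimal place; within ±0.15;
  within the interval implied by the inputs' printing precision),
  because the original authors computed from unrounded sources —
  low-prevalence cells can legitimately move several tenths of a
  point under input rounding.

## Open questions resolved during implementation

- **Within-year operation order** (mortality → transitions → bins →
  aging) and the age-indexing of cross-sectional initiation rates are
  not fully specified by the published description; the chosen
  convention is the one that makes the replay identity exact.
- **Quit-bin advancement** assumes a uniform within-bin distribution
  (fraction 1/width per year); the terminal age is closed rather than
  truncated.
- **Migration** status mix follows the destination cell, keeping
  migration neutral with respect to prevalence.
- **Cessation-package rescaling** resolves the mismatch between the
  multiplicative combination of the published component effects and
  the published package totals in favour of the totals.
- **"Held after 2018"**: the vaping adjustor stops compounding after
  the comparison window, but the accumulated displacement persists.

## Limitations

- The original model's survey-microdata initialization, cohort
  mortality schedules and relapse inputs are not published, so the
  full US numbers (prevalence levels, scenario tables, SAD counts) are
  not reproducible at desk scale; the acceptance suite substitutes
  exact printed-table arithmetic plus property-based tests.
- The indirect method attributes *all* unexplained post-2012 excess
  decline to NVPs; confounding trends are not modelled.
- NVP use carries its own (unmodelled) mortality risk; "deaths
  averted" counts only smoking-attributable deaths.
- Expected-value dynamics ignore demographic stochasticity; this is
  deliberate (the model tracks means, surveys contribute the noise).

## Problem sizes

Test and example worlds use 2 genders × 100 ages × 8 statuses
(~1,600 cells), 10–60 simulated years, and survey waves of n = 25,000;
a full counterfactual run takes ~0.1 s and the entire test suite —
including 200 adjustor-recovery replicates — under 10 s on one CPU.
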