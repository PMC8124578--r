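Package: smokesim
Title: Tobacco Control Policy Simulation and Indirect Inference of
    Vaping Impacts on Smoking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic compartmental Markov model of cigarette
    smoking in a national population: never, current and former smokers
    (by years since quitting) evolve under status-specific mortality,
    net initiation, cessation and relapse, with tobacco-control policies
    (taxes, smoke-free air laws, media campaigns, marketing restrictions,
    cessation treatment, youth access) translated into first-year
    prevalence shocks and ongoing initiation/cessation changes. On top of
    the simulator, the package implements an indirect method for gauging
    the impact of nicotine vaping products: project a no-vaping
    counterfactual, compare its relative prevalence reductions with
    national survey trends, derive annualized vaping adjustors with
    confidence-bound propagation, and project smoking-attributable
    deaths averted under the adjusted scenario. A synthetic-world
    generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
VignetteBuilder: knitr
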