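Package: tobaccoCEA
Title: Cost-Effectiveness of Population-Based Tobacco Control for CVD Prevention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-model cost-effectiveness framework for population-based
    tobacco control interventions in the prevention of cardiovascular disease,
    contextualised to Tanzania. A three-state smoking prevalence model
    (never/current/former) with status-specific mortality is calibrated to
    repeated cross-sectional survey prevalence by weighted least squares to
    estimate age- and sex-specific smoking initiation and cessation rates.
    These feed a four-state Markov cohort model of ischaemic heart disease and
    stroke in which intervention effects on smoking prevalence modify disease
    incidence through the potential impact fraction. The package computes
    discounted disability-adjusted life years (DALYs) averted, intervention
    costs (capital annuitisation, step-down allocation of shared costs,
    currency conversion), average and incremental cost-effectiveness ratios
    with dominance analysis, and layered Monte Carlo uncertainty analysis
    (Dirichlet, PERT, shifted-beta and lognormal parameter distributions).
    A synthetic-data generator provides internally consistent life tables,
    disease schedules, survey panels and cost ledgers with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
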