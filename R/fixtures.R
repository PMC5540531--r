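#' Packaged Tanzanian inputs and published base-case results
#'
#' Plain-text CSV fixtures bundled with the package: the observed smoking
#' prevalence surveys (2002 GYTS/STEPS-era and 2012 waves, never/current/
#' former by age band and sex), the published calibrated signed
#' initiation/cessation rates (mean and bootstrap SD; negative = annual
#' initiation, positive = annual cessation), smoker-vs-non-smoker disease
#' relative risks for IHD and stroke on broad age bands, intervention
#' effect sizes with their uncertainty distributions, the annual
#' intervention cost table by cost center (US$, base year 2013), and the
#' base-case cost-effectiveness results table.
#'
#' Two quirks of the published tables are shipped verbatim rather than
#' repaired: the female 25-34 cessation rate of 0.5088 is implausibly
#' large, and in the results table the package-labelling male + female
#' DALYs (44,903 + 11,269 = 56,172) differ from the printed total
#' (56,174) by 2. The tax prevalence elasticity's interval (-0.78, -0.37)
#' does not bracket its point estimate (-0.88) as printed; samplers fall
#' back to a PERT +/-20% spread for that row.
#'
#' @param normalize For the survey panel, renormalise each triple onto
#'   the simplex (the printed proportions round to +/-0.001 of 1).
#' @return A data frame (see each fixture's columns).
#' @name fixtures
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "tobaccoCEA")
  if (p == "") stop("fixture not found: ", file, call. = FALSE)
  p
}

#' @rdname fixtures
#' @export
tz_survey_prevalence <- function(normalize = TRUE) {
  df <- utils::read.csv(fixture_path("survey_prevalence_tz.csv"),
                        stringsAsFactors = FALSE)
  df$age_high <- as.numeric(df$age_high)
  if (normalize) {
    tot <- df$never + df$current + df$former
    df$never <- df$never / tot
    df$current <- df$current / tot
    df$former <- df$former / tot
  }
  df
}

#' @rdname fixtures
#' @export
tz_signed_rates <- function() {
  df <- utils::read.csv(fixture_path("signed_flow_rates_tz.csv"),
                        stringsAsFactors = FALSE)
  df$age_high <- as.numeric(df$age_high)
  df
}

#' @rdname fixtures
#' @export
tz_disease_rr <- function() {
  df <- utils::read.csv(fixture_path("disease_rr_smoking.csv"),
                        stringsAsFactors = FALSE)
  df$age_high <- as.numeric(df$age_high)
  df
}

#' @rdname fixtures
#' @export
tz_intervention_effects <- function() {
  utils::read.csv(fixture_path("intervention_effects.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname fixtures
#' @export
tz_intervention_costs <- function() {
  utils::read.csv(fixture_path("intervention_costs.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname fixtures
#' @export
tz_base_case_results <- function() {
  utils::read.csv(fixture_path("base_case_results.csv"),
                  stringsAsFactors = FALSE)
}

#' Analysis run configuration
#'
#' Named defaults for every analysis constant: 3% discounting of costs
#' and DALYs, 9.6% capital annuitisation, US$62 capital threshold,
#' Tshs 1605/US$ exchange rate, US$910 GDP per capita (the WTP ceiling),
#' a 10-year intervention effect horizon, a 5-year program costing span,
#' 2000 PSA iterations and 10,000 calibration-bootstrap iterations.
#' Override any field via `...`.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    base_year = 2013,
    discount_rate = 0.03,
    annuitization_rate = 0.096,
    capital_threshold_usd = 62,
    exchange_rate = 1605,
    wtp_gdp_per_capita = 910,
    effect_horizon_years = 10,
    cost_horizon_years = 5,
    psa_iterations = 2000,
    bootstrap_iterations = 10000,
    trajectory_years = 30,
    horizon_age = 100,
    seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown config field(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(over)] <- over
  cfg
}
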