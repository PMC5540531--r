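#' Synthetic Tanzanian-style model inputs with known ground truth
#'
#' The package's calibration and Markov stages need life tables, disease
#' schedules, population counts, demographic rates and survey panels that
#' in the original analysis came from external sources (census, national
#' life tables, GBD-style disease modelling, CPS-II relative risks). The
#' generators below produce internally consistent synthetic stand-ins in
#' the same magnitude regime (adult male smoking around 0.2-0.28), with
#' the generating parameters returned alongside so every stage can be
#' tested against known truth. They emulate structure, not the real
#' Tanzanian estimates.
#'
#' @name synthetic_data
NULL

# internal: Gompertz-plus-background mortality rate at single-year ages
gompertz_rate <- function(age, a0, b, background) {
  background + a0 * exp(b * age)
}

#' Generate a synthetic life table
#'
#' Gompertz mortality (plus a constant background rate) with a sex
#' differential; band rates are taken at band midpoints and residual life
#' expectancies are computed from the single-year rates themselves by
#' survivorship summation, so the table is internally consistent.
#'
#' @param scheme Stratum scheme data frame (see [age_scheme()]).
#' @param a0_male,a0_female Gompertz level parameters.
#' @param b Gompertz slope (per year of age).
#' @param background Age-constant background mortality rate.
#' @return Life table data frame (`sex, age_low, age_high, mortality_rate,
#'   life_expectancy`).
#' @export
make_lifetable <- function(scheme = markov_scheme(), a0_male = 8e-5,
                           a0_female = 6e-5, b = 0.085,
                           background = 0.003) {
  ages <- 0:110
  out <- scheme
  out$mortality_rate <- NA_real_
  out$life_expectancy <- NA_real_
  for (s in unique(scheme$sex)) {
    a0 <- if (s == "male") a0_male else a0_female
    m1 <- gompertz_rate(ages, a0, b, background)
    # survivorship within each year then residual expectancy by summation
    surv_year <- exp(-m1)
    le <- numeric(length(ages))
    for (k in rev(seq_along(ages))) {
      nxt <- if (k == length(ages)) 0 else le[k + 1]
      le[k] <- surv_year[k] * (1 + nxt)
    }
    rows <- which(out$sex == s)
    mid <- floor((out$age_low[rows] + pmin(out$age_high[rows], 100)) / 2)
    out$mortality_rate[rows] <- gompertz_rate(mid, a0, b, background)
    out$life_expectancy[rows] <- le[match(mid, ages)]
  }
  out
}

#' Generate a synthetic population pyramid
#'
#' Counts decay exponentially with age from the youngest band, with a
#' mild sex imbalance, scaled to `total` persons.
#'
#' @param scheme Stratum scheme.
#' @param total Total population across all strata.
#' @param decline Exponential decline rate per year of age.
#' @return Pyramid data frame (`sex, age_low, age_high, count`).
#' @export
make_pyramid <- function(scheme = markov_scheme(), total = 2e6,
                         decline = 0.035) {
  w <- exp(-decline * (scheme$age_low - min(scheme$age_low))) *
    ifelse(scheme$sex == "female", 1.02, 1)
  scheme$count <- total * w / sum(w)
  scheme
}

#' Synthetic mortality relative risks by smoking status
#'
#' Current-smoker mortality RR peaks in midlife and attenuates at older
#' ages; former smokers carry roughly a third of the excess. Includes
#' 95% CI columns for lognormal resampling.
#'
#' @param scheme Stratum scheme.
#' @param peak Current-smoker RR in midlife bands.
#' @return Data frame `sex, age_low, age_high, rr_current, rr_former` plus
#'   `_lci`/`_hci` columns.
#' @export
make_mortality_rrs <- function(scheme = survey_scheme(), peak = 2.2) {
  rr_c <- ifelse(scheme$age_low < 35, 1.4,
                 ifelse(scheme$age_low < 65, peak, 1.5))
  rr_f <- 1 + (rr_c - 1) / 3
  data.frame(scheme,
             rr_current = rr_c, rr_former = rr_f,
             rr_current_lci = rr_c * 0.85, rr_current_hci = rr_c * 1.18,
             rr_former_lci = rr_f * 0.9, rr_former_hci = rr_f * 1.12)
}

#' Synthetic disease schedules for IHD and stroke
#'
#' Incidence rises exponentially with age from age 30; prevalence is set
#' to the steady-state heuristic `incidence * duration` with duration
#' `1 / (case_fatality + background mortality)`, and population
#' cause-specific mortality to `prevalence * case_fatality`, kept
#' strictly below the all-cause rate of the supplied life table.
#'
#' @param lifetable Life table on the target scheme (provides all-cause
#'   rates and the scheme itself).
#' @param inc30_ihd,inc30_stroke Incidence at age 30, per person-year.
#' @param slope Exponential age slope of incidence.
#' @param fatality_ihd,fatality_stroke Case-fatality rates among prevalent
#'   cases, per person-year.
#' @return Data frame `disease, sex, age_low, age_high, incidence,
#'   prevalence, mortality`.
#' @export
make_disease_schedules <- function(lifetable, inc30_ihd = 4e-4,
                                   inc30_stroke = 2.5e-4, slope = 0.055,
                                   fatality_ihd = 0.05,
                                   fatality_stroke = 0.09) {
  one <- function(disease, inc30, fat) {
    mid <- floor((lifetable$age_low + pmin(lifetable$age_high, 100)) / 2)
    inc <- ifelse(mid < 30, inc30 / 10, inc30 * exp(slope * (mid - 30)))
    duration <- 1 / (fat + lifetable$mortality_rate)
    prev <- pmin(inc * duration, 0.5)
    csm <- pmin(prev * fat, 0.8 * lifetable$mortality_rate / 2)
    data.frame(disease = disease, sex = lifetable$sex,
               age_low = lifetable$age_low, age_high = lifetable$age_high,
               incidence = inc, prevalence = prev, mortality = csm)
  }
  rbind(one("IHD", inc30_ihd, fatality_ihd),
        one("stroke", inc30_stroke, fatality_stroke))
}

#' Synthetic smoker-vs-non-smoker disease relative risks
#'
#' Broad-band (35-64, 65+) disease RRs in the usual epidemiological
#' range, with CI columns for resampling.
#'
#' @return Data frame `disease, sex, age_low, age_high, rr, lci, hci`.
#' @export
make_disease_rrs <- function() {
  df <- expand.grid(disease = c("IHD", "stroke"),
                    sex = c("male", "female"),
                    age_low = c(35, 65),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$age_high <- ifelse(df$age_low == 35, 65, Inf)
  df$rr <- ifelse(df$age_low == 35, 2.5, 1.5)
  df$lci <- df$rr * 0.8
  df$hci <- df$rr * 1.2
  df
}

#' Full synthetic ground-truth bundle
#'
#' Assembles every input the analysis pipeline needs - schemes, pyramids,
#' life tables on both grouping schemes, mortality and disease RRs,
#' disease schedules, demographic rates, disability weights, true signed
#' initiation/cessation parameters and a base-year prevalence panel -
#' from one seed.
#'
#' @param seed Integer seed (perturbs the true flow parameters and the
#'   initial prevalence mildly so bundles differ across seeds).
#' @param base_year First survey/base calendar year.
#' @return A list of class `synthetic_truth`.
#' @export
make_truth <- function(seed = 1, base_year = 2002) {
  set.seed(seed)
  sch_s <- survey_scheme()
  sch_m <- markov_scheme()
  lt_s <- make_lifetable(sch_s)
  lt_m <- make_lifetable(sch_m)
  nb <- sum(sch_s$sex == "male")
  signed_male <- c(-0.03, -0.015, 0.01, 0.02, 0.03, 0.04, 0.05) +
    stats::runif(nb, -0.005, 0.005)
  signed_female <- c(-0.012, -0.005, 0.004, 0.008, 0.015, 0.02, 0.025) +
    stats::runif(nb, -0.002, 0.002)
  flows <- data.frame(sch_s,
                      signed_parameter = ifelse(sch_s$sex == "male",
                                                signed_male[match(sch_s$age_low,
                                                                  unique(sch_s$age_low))],
                                                signed_female[match(sch_s$age_low,
                                                                    unique(sch_s$age_low))]))
  cur <- ifelse(sch_s$sex == "male",
                0.10 + 0.03 * (match(sch_s$age_low, unique(sch_s$age_low)) - 1),
                0.02 + 0.008 * (match(sch_s$age_low, unique(sch_s$age_low)) - 1))
  cur <- cur + stats::runif(nrow(sch_s), -0.01, 0.01)
  fmr <- 0.5 * cur
  initial_prev <- data.frame(sch_s, never = 1 - cur - fmr, current = cur,
                             former = fmr)
  fert_bands <- unique(sch_s$age_low)
  fertility <- data.frame(sex = "female", age_low = fert_bands,
                          age_high = unique(sch_s$age_high),
                          fertility = c(0.17, 0.2, 0.1, 0, 0, 0, 0))
  structure(list(
    scheme_survey = sch_s, scheme_markov = sch_m,
    pyramid_survey = make_pyramid(sch_s), pyramid_markov = make_pyramid(sch_m),
    lifetable_survey = lt_s, lifetable_markov = lt_m,
    mortality_rrs = make_mortality_rrs(sch_s),
    schedules = make_disease_schedules(lt_m),
    disease_rrs = make_disease_rrs(),
    disability_weights = list(ihd = 0.08, stroke = 0.32),
    demo = list(fertility = fertility, sex_ratio = 1.03),
    flows = flows, initial_prev = initial_prev,
    base_year = base_year, seed = seed), class = "synthetic_truth")
}

#' Simulate survey panels from a synthetic truth
#'
#' Runs the true prevalence trajectory forward from the truth's base year
#' and draws multinomial samples of size `n_per_stratum` at each survey
#' year (or returns the exact model prevalences when `noiseless = TRUE`).
#'
#' @param truth A [make_truth()] bundle.
#' @param survey_years Calendar years to observe (>= the base year).
#' @param n_per_stratum Multinomial sample size per stratum.
#' @param seed Sampling seed.
#' @param noiseless If `TRUE`, return exact prevalences (`n_eff` still set
#'   to `n_per_stratum`).
#' @return Survey panel data frame (`sex, age_low, age_high, year, never,
#'   current, former, n_eff`).
#' @export
make_surveys <- function(truth, survey_years = truth$base_year + c(0, 10),
                         n_per_stratum = 1000, seed = truth$seed,
                         noiseless = FALSE) {
  stopifnot(all(survey_years >= truth$base_year))
  span <- max(survey_years) - truth$base_year
  initial <- truth$initial_prev
  key <- stratum_key(initial)
  cnt <- truth$pyramid_survey$count[match(key, stratum_key(truth$pyramid_survey))]
  initial$never <- initial$never * cnt
  initial$current <- initial$current * cnt
  initial$former <- initial$former * cnt
  sim <- simulate_prevalence(initial, truth$flows, truth$lifetable_survey,
                             truth$mortality_rrs, truth$demo,
                             years = max(1, span))
  set.seed(seed)
  panels <- list()
  for (y in survey_years) {
    sl <- sim[sim$year == y - truth$base_year, , drop = FALSE]
    p <- as.matrix(sl[, c("never", "current", "former")])
    if (!noiseless) {
      for (i in seq_len(nrow(p))) {
        p[i, ] <- stats::rmultinom(1, n_per_stratum, p[i, ]) / n_per_stratum
      }
    }
    panels[[as.character(y)]] <- data.frame(
      sex = sl$sex, age_low = sl$age_low, age_high = sl$age_high,
      year = y, never = p[, 1], current = p[, 2], former = p[, 3],
      n_eff = n_per_stratum)
  }
  out <- do.call(rbind, panels)
  rownames(out) <- NULL
  out
}

#' Synthetic intervention cost ledger
#'
#' With `preset = "tanzania"` returns a ledger whose direct recurrent
#' items reproduce the packaged cost-center table for the five
#' interventions exactly (a reconstruction: the original shared-cost
#' allocation keys are not published, so the packaged table is shipped
#' as already-allocated center amounts). Otherwise generates a random
#' ledger mixing capital/recurrent and direct/shared items with valid
#' allocation keys.
#'
#' @param seed Seed for the random ledger.
#' @param preset `NULL` (random) or `"tanzania"`.
#' @param interventions Intervention names for the random ledger.
#' @return A cost ledger: list with `items` and `allocation_keys` (see
#'   [step_down_allocate()]).
#' @export
make_cost_ledger <- function(seed = 1, preset = NULL,
                             interventions = c("advertisement_ban",
                                               "labelling", "smoke_free",
                                               "mass_media", "tobacco_tax")) {
  if (identical(preset, "tanzania")) {
    tab <- tz_intervention_costs()
    items <- NULL
    for (iv in setdiff(names(tab), "cost_center")) {
      nz <- tab[[iv]] > 0
      items <- rbind(items, data.frame(
        label = paste(iv, tab$cost_center[nz], sep = "_"),
        cost_center = tab$cost_center[nz], amount = tab[[iv]][nz],
        currency = "USD", price_year = 2013, kind = "recurrent",
        useful_life = NA_real_, shared = FALSE,
        allocation_key = NA_character_, intervention = iv))
    }
    return(list(items = items, allocation_keys = list()))
  }
  set.seed(seed)
  centers <- c("program_development", "human_resources",
               "promotion_media_advocacy", "program_supplies",
               "rent_equipment_office", "operations")
  n_direct <- 20; n_shared <- 8
  items <- data.frame(
    label = paste0("item", seq_len(n_direct + n_shared)),
    cost_center = sample(centers, n_direct + n_shared, replace = TRUE),
    amount = round(stats::rlnorm(n_direct + n_shared, log(5000), 1), 2),
    currency = "USD", price_year = 2013,
    kind = sample(c("capital", "recurrent"), n_direct + n_shared,
                  replace = TRUE, prob = c(0.3, 0.7)),
    useful_life = sample(c(5, 10, 30), n_direct + n_shared, replace = TRUE),
    shared = rep(c(FALSE, TRUE), c(n_direct, n_shared)),
    allocation_key = NA_character_, intervention = NA_character_)
  items$useful_life[items$kind == "recurrent"] <- NA_real_
  items$intervention[!items$shared] <-
    sample(interventions, n_direct, replace = TRUE)
  rand_w <- stats::runif(length(interventions))
  keys <- list(equal = stats::setNames(rep(1 / length(interventions),
                                           length(interventions)),
                                       interventions),
               staff_time = stats::setNames(rand_w / sum(rand_w),
                                            interventions))
  items$allocation_key[items$shared] <-
    sample(names(keys), n_shared, replace = TRUE)
  list(items = items, allocation_keys = keys)
}
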