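#' Potential impact fraction for a smoking prevalence change
#'
#' Proportional change in disease incidence implied by moving smoker
#' prevalence from `prev_base` to `prev_new`, with two exposure categories
#' (non-smoker, RR = 1; smoker, RR = `rr`; former smokers count as
#' non-smokers):
#' `PIF = (sum P_x RR_x - sum Phat_x RR_x) / sum P_x RR_x`.
#' Adjusted incidence is `incidence * (1 - PIF)`. The PIF is at most 1,
#' positive when smoker prevalence falls (for `rr > 1`) and zero when
#' nothing changes or `rr = 1`.
#'
#' @param prev_base Baseline smoker proportion(s) in `[0, 1]`.
#' @param prev_new Counterfactual smoker proportion(s).
#' @param rr Relative risk of disease for smokers vs non-smokers.
#' @return Dimensionless PIF (vectorised).
#' @examples
#' potential_impact_factor(0.28, 0.25, 2.6)  # 0.03315
#' @export
potential_impact_factor <- function(prev_base, prev_new, rr) {
  stopifnot(all(prev_base >= 0 & prev_base <= 1),
            all(prev_new >= 0 & prev_new <= 1), all(rr >= 0))
  denom <- prev_base * rr + (1 - prev_base)
  if (any(denom <= 0)) stop("zero denominator in PIF", call. = FALSE)
  num <- denom - (prev_new * rr + (1 - prev_new))
  num / denom
}

#' Annual transition matrix for the four-state CVD model
#'
#' States: S1 no history of CVD, S2 history of IHD, S3 history of stroke,
#' S4 dead (absorbing). Background mortality is the all-cause rate net of
#' the two cause-specific mortality rates (clipped at zero with a warning
#' if the causes exceed it). From S1, incident transitions use
#' PIF-adjusted incidence; from S2/S3, mortality is background plus the
#' disease's case fatality among prevalent cases.
#'
#' @param m_all All-cause mortality rate, per person-year.
#' @param inc_ihd,inc_stroke Disease incidence rates among the CVD-free.
#' @param csm_ihd,csm_stroke Population cause-specific mortality rates
#'   (subtracted from `m_all` to get background mortality).
#' @param fatality_ihd,fatality_stroke Excess mortality rate among
#'   prevalent cases (case fatality), per person-year.
#' @param pif_ihd,pif_stroke Potential impact fractions applied to the
#'   incidence rates.
#' @return A 4x4 row-stochastic matrix (rows = from-state S1..S4).
#' @export
build_transitions <- function(m_all, inc_ihd, inc_stroke,
                              csm_ihd = 0, csm_stroke = 0,
                              fatality_ihd = 0, fatality_stroke = 0,
                              pif_ihd = 0, pif_stroke = 0) {
  m_bg <- m_all - csm_ihd - csm_stroke
  if (m_bg < 0) {
    warning("cause-specific mortality exceeds all-cause; background clipped to 0",
            call. = FALSE)
    m_bg <- 0
  }
  p12 <- rate_to_prob(inc_ihd * (1 - pif_ihd))
  p13 <- rate_to_prob(inc_stroke * (1 - pif_stroke))
  p14 <- rate_to_prob(m_bg)
  p11 <- 1 - p12 - p13 - p14
  if (p11 < 0) {
    stop("transition probabilities from S1 exceed 1 (rates too large)",
         call. = FALSE)
  }
  p24 <- rate_to_prob(m_bg + fatality_ihd)
  p34 <- rate_to_prob(m_bg + fatality_stroke)
  matrix(c(p11, p12, p13, p14,
           0, 1 - p24, 0, p24,
           0, 0, 1 - p34, p34,
           0, 0, 0, 1),
         nrow = 4, byrow = TRUE,
         dimnames = list(c("S1", "S2", "S3", "S4"),
                         c("S1", "S2", "S3", "S4")))
}

#' Starting occupancy of a Markov cohort
#'
#' Members with prevalent disease start in the corresponding history state;
#' the remainder start CVD-free. Nobody starts dead.
#'
#' @param population Cohort size (persons).
#' @param prev_ihd,prev_stroke Prevalence proportions; their sum must not
#'   exceed 1.
#' @return Numeric vector `c(S1, S2, S3, S4)`.
#' @export
initialize_cohort <- function(population, prev_ihd = 0, prev_stroke = 0) {
  if (prev_ihd + prev_stroke > 1) {
    stop("disease prevalences sum to more than 1", call. = FALSE)
  }
  c(S1 = population * (1 - prev_ihd - prev_stroke),
    S2 = population * prev_ihd,
    S3 = population * prev_stroke,
    S4 = 0)
}

#' Run one Markov cohort
#'
#' Applies an age-updated annual transition matrix for `cycles` cycles,
#' recording state occupancy, incident IHD/stroke cases and deaths per
#' cycle. Persons are conserved (S1+S2+S3+S4 constant) and the dead state
#' is non-decreasing.
#'
#' @param init Starting occupancy, `c(S1, S2, S3, S4)`.
#' @param transition_fn Function of the cycle index (1-based) returning the
#'   4x4 transition matrix for that cycle; a single fixed matrix is also
#'   accepted.
#' @param cycles Number of annual cycles (>= 1).
#' @return An object of class `markov_trace`: list with `occupancy`
#'   (`cycles + 1` x 4 matrix, cycle 0 first), `cases_ihd`, `cases_stroke`
#'   and `deaths` (per-cycle vectors).
#' @export
run_cohort <- function(init, transition_fn, cycles) {
  stopifnot(cycles >= 1, length(init) == 4, all(init >= 0))
  if (is.matrix(transition_fn)) {
    tm <- transition_fn
    transition_fn <- function(t) tm
  }
  occ <- matrix(0, nrow = cycles + 1, ncol = 4,
                dimnames = list(NULL, c("S1", "S2", "S3", "S4")))
  occ[1, ] <- init
  cases_ihd <- cases_stroke <- deaths <- numeric(cycles)
  for (t in seq_len(cycles)) {
    P <- transition_fn(t)
    cur <- occ[t, ]
    cases_ihd[t] <- cur[1] * P[1, 2]
    cases_stroke[t] <- cur[1] * P[1, 3]
    nxt <- as.numeric(cur %*% P)
    deaths[t] <- nxt[4] - cur[4]
    occ[t + 1, ] <- nxt
  }
  structure(list(occupancy = occ, cases_ihd = cases_ihd,
                 cases_stroke = cases_stroke, deaths = deaths),
            class = "markov_trace")
}

# internal: look up a stratified value for a single-year age by band
# containment (first band whose [age_low, age_high) contains the age)
lookup_band <- function(df, sex, age, col) {
  rows <- df$sex == sex & df$age_low <= age & age < df$age_high
  v <- df[[col]][rows]
  if (length(v) == 0) return(NA_real_)
  v[1]
}

# internal: smoker prevalence from a trajectory data frame at (sex, age, year);
# years beyond the trajectory span hold the final value
traj_prevalence <- function(traj, sex, age, year) {
  ymax <- max(traj$year)
  y <- min(year, ymax)
  rows <- traj$sex == sex & traj$age_low <= age & age < traj$age_high &
    traj$year == y
  v <- traj$current[rows]
  if (length(v) == 0) stop("trajectory does not cover sex=", sex,
                           " age=", age, call. = FALSE)
  v[1]
}

# internal: disease RR for (disease, sex, age); ages below the youngest RR
# band get RR = 1 (no excess risk estimate)
disease_rr_at <- function(disease_rrs, disease, sex, age) {
  d <- disease_rrs[disease_rrs$disease == disease & disease_rrs$sex == sex, ]
  v <- d$rr[d$age_low <= age & age < d$age_high]
  if (length(v) == 0) 1 else v[1]
}

#' Run all Markov cohorts under paired smoking scenarios
#'
#' Simulates every 5-year cohort of the population under a base and an
#' intervention smoking-prevalence trajectory. The two runs share all
#' inputs; they differ only through the potential impact fraction computed,
#' per cycle, from the base-year smoker prevalence versus each scenario's
#' future prevalence. Each cohort is followed until its members reach
#' `horizon_age`.
#'
#' @param pyramid Population counts on the Markov scheme.
#' @param lifetable Life table on the Markov scheme (columns
#'   `mortality_rate`, `life_expectancy`).
#' @param schedules Disease schedules: data frame `disease, sex, age_low,
#'   age_high, incidence, prevalence, mortality` for IHD and stroke
#'   (`mortality` is the population cause-specific rate).
#' @param disease_rrs Data frame `disease, sex, age_low, age_high, rr`
#'   of smoker-vs-non-smoker disease risks on broad age bands.
#' @param base_traj,scenario_traj Smoking prevalence trajectories (as
#'   returned by [simulate_prevalence()] or [apply_effects()]); the
#'   `current` column at year 0 of `base_traj` defines base-year exposure.
#' @param horizon_age Follow every cohort until this age (default 100).
#' @return List with elements `base` and `scenario`, each a list of
#'   `markov_trace` objects named `<sex>_<age_low>`, carrying `sex` and
#'   `start_age` attributes.
#' @export
run_population <- function(pyramid, lifetable, schedules, disease_rrs,
                           base_traj, scenario_traj, horizon_age = 100) {
  if (!setequal(unique(base_traj$year), unique(scenario_traj$year))) {
    stop("base and scenario trajectories cover different spans", call. = FALSE)
  }
  ages <- 15:99
  # precompute per-sex, single-year-age rate vectors so the cycle loop is
  # plain scalar arithmetic (equivalent to run_cohort + build_transitions;
  # asserted by tests)
  precomp <- list()
  for (s in unique(pyramid$sex)) {
    get_vec <- function(df, col) {
      vapply(ages, function(a) lookup_band(df, s, a, col), numeric(1))
    }
    sch_i <- schedules[schedules$disease == "IHD", ]
    sch_s <- schedules[schedules$disease == "stroke", ]
    pr_i <- get_vec(sch_i, "prevalence"); pr_s <- get_vec(sch_s, "prevalence")
    csm_i <- get_vec(sch_i, "mortality"); csm_s <- get_vec(sch_s, "mortality")
    m_all <- get_vec(lifetable, "mortality_rate")
    m_bg <- m_all - csm_i - csm_s
    if (any(m_bg < 0)) {
      warning("cause-specific mortality exceeds all-cause for sex ", s,
              "; background clipped to 0", call. = FALSE)
      m_bg <- pmax(m_bg, 0)
    }
    fat_i <- ifelse(pr_i > 0, csm_i / pr_i, 0)
    fat_s <- ifelse(pr_s > 0, csm_s / pr_s, 0)
    precomp[[s]] <- list(
      inc_i = get_vec(sch_i, "incidence"), inc_s = get_vec(sch_s, "incidence"),
      pr_i = pr_i, pr_s = pr_s,
      p14 = -expm1(-m_bg),
      p24 = -expm1(-(m_bg + fat_i)),
      p34 = -expm1(-(m_bg + fat_s)),
      rr_i = vapply(ages, function(a) disease_rr_at(disease_rrs, "IHD", s, a),
                    numeric(1)),
      rr_s = vapply(ages, function(a) disease_rr_at(disease_rrs, "stroke", s, a),
                    numeric(1)))
  }
  traj_matrix <- function(traj, s) {
    tj <- traj[traj$sex == s, ]
    tj <- tj[order(tj$year, tj$age_low), ]
    lows <- sort(unique(tj$age_low))
    nbands <- length(lows)
    ymax <- max(tj$year)
    if (nrow(tj) != nbands * (ymax + 1)) {
      stop("trajectory is not a complete band x year grid for sex ", s,
           call. = FALSE)
    }
    highs <- tj$age_high[match(lows, tj$age_low)]
    bi <- findInterval(ages, lows)
    if (any(bi == 0) || any(ages >= highs[nbands] & is.finite(highs[nbands]))) {
      stop("trajectory does not cover ages 15-99 for sex ", s, call. = FALSE)
    }
    prev <- matrix(tj$current, nrow = nbands)  # bands x years
    prev[bi, , drop = FALSE]                   # ages x years
  }
  sexes <- unique(pyramid$sex)
  base_tms <- lapply(stats::setNames(nm = sexes),
                     function(s) traj_matrix(base_traj, s))
  run_one <- function(tms) {
    traces <- list()
    for (i in seq_len(nrow(pyramid))) {
      s <- pyramid$sex[i]; a0 <- pyramid$age_low[i]
      pc <- precomp[[s]]
      tm <- tms[[s]]
      ymax <- ncol(tm) - 1
      cycles <- max(1L, as.integer(horizon_age - a0))
      t <- seq_len(cycles)
      ai <- pmin(a0 + t - 1, 99) - 15L + 1L
      p0 <- base_tms[[s]][ai, 1]
      ps <- tm[cbind(ai, pmin(t, ymax) + 1)]
      pif_i <- potential_impact_factor(p0, ps, pc$rr_i[ai])
      pif_s <- potential_impact_factor(p0, ps, pc$rr_s[ai])
      p12 <- -expm1(-pc$inc_i[ai] * (1 - pif_i))
      p13 <- -expm1(-pc$inc_s[ai] * (1 - pif_s))
      p14 <- pc$p14[ai]; p24 <- pc$p24[ai]; p34 <- pc$p34[ai]
      if (any(p12 + p13 + p14 > 1)) {
        stop("transition probabilities from S1 exceed 1 for cohort ",
             s, " ", a0, call. = FALSE)
      }
      ai0 <- a0 - 15L + 1L
      init <- initialize_cohort(pyramid$count[i], pc$pr_i[ai0], pc$pr_s[ai0])
      occ <- matrix(0, nrow = cycles + 1, ncol = 4,
                    dimnames = list(NULL, c("S1", "S2", "S3", "S4")))
      occ[1, ] <- init
      cases_ihd <- cases_stroke <- deaths <- numeric(cycles)
      s1 <- init[[1]]; s2 <- init[[2]]; s3 <- init[[3]]; s4 <- init[[4]]
      for (tt in t) {
        ci <- s1 * p12[tt]; cs <- s1 * p13[tt]
        d <- s1 * p14[tt] + s2 * p24[tt] + s3 * p34[tt]
        s1 <- s1 - ci - cs - s1 * p14[tt]
        s2 <- s2 + ci - s2 * p24[tt]
        s3 <- s3 + cs - s3 * p34[tt]
        s4 <- s4 + d
        cases_ihd[tt] <- ci; cases_stroke[tt] <- cs; deaths[tt] <- d
        occ[tt + 1, ] <- c(s1, s2, s3, s4)
      }
      tr <- structure(list(occupancy = occ, cases_ihd = cases_ihd,
                           cases_stroke = cases_stroke, deaths = deaths),
                      class = "markov_trace")
      attr(tr, "sex") <- s
      attr(tr, "start_age") <- a0
      traces[[paste0(s, "_", a0)]] <- tr
    }
    traces
  }
  scen_tms <- lapply(stats::setNames(nm = sexes),
                     function(s) traj_matrix(scenario_traj, s))
  list(base = run_one(base_tms), scenario = run_one(scen_tms))
}
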