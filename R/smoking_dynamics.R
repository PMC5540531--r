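#' Decompose population mortality by smoking status
#'
#' Splits an all-cause population mortality rate into never/current/former
#' smoker rates using smoking prevalence and mortality relative risks:
#' `m_never = m_pop / (rr_c * prev_c + rr_f * prev_f + prev_n)`,
#' `m_current = rr_c * m_never`, `m_former = rr_f * m_never`.
#' The prevalence-weighted mean of the three status rates equals `m_pop`
#' exactly (conservation).
#'
#' @param m_pop All-cause mortality rate(s), per person-year.
#' @param prev_current,prev_former Smoking prevalence proportions; together
#'   with never they must lie on the simplex.
#' @param rr_current,rr_former Mortality relative risks vs never smokers.
#' @return A list with components `m_never`, `m_current`, `m_former`
#'   (vectorised over the inputs).
#' @export
decompose_mortality <- function(m_pop, prev_current, prev_former,
                                rr_current, rr_former) {
  if (any(m_pop < 0) || any(!is.finite(m_pop))) {
    stop("m_pop must be finite and nonnegative", call. = FALSE)
  }
  prev_never <- 1 - prev_current - prev_former
  if (any(prev_current < -1e-9) || any(prev_former < -1e-9) ||
      any(prev_never < -1e-9)) {
    stop("prevalences must lie on the simplex", call. = FALSE)
  }
  if (any(rr_current < 1 | rr_former < 1)) {
    warning("mortality relative risk below 1 supplied", call. = FALSE)
  }
  denom <- rr_current * prev_current + rr_former * prev_former + prev_never
  if (any(denom <= 0)) stop("nonpositive denominator in decomposition", call. = FALSE)
  m_never <- m_pop / denom
  list(m_never = m_never,
       m_current = rr_current * m_never,
       m_former = rr_former * m_never)
}

#' Signed flow parameters
#'
#' The prevalence model carries one signed flow parameter per age-sex
#' stratum: a negative value is an annual initiation rate (its magnitude is
#' the proportion of never smokers starting per year), a positive value an
#' annual cessation rate (proportion of current smokers quitting per year).
#' Exactly one of the two flows is nonzero per stratum.
#'
#' @param signed Numeric vector of signed parameters in `[-1, 1]`.
#' @return A list with `initiation` and `cessation` vectors.
#' @export
flows_from_signed <- function(signed) {
  if (any(abs(signed) > 1)) stop("signed parameters must lie in [-1, 1]", call. = FALSE)
  list(initiation = pmax(-signed, 0), cessation = pmax(signed, 0))
}

#' One annual update of smoker counts in a single stratum
#'
#' Applies status-specific survival first (probabilities
#' `rate_to_prob(m_status)`), then moves survivors never->current at the
#' initiation rate and current->former at the cessation rate. Both flows are
#' computed from the post-survival, pre-flow stocks; never smokers cannot
#' reach the former state in one step.
#'
#' @param counts Named numeric vector or list with `never, current, former`.
#' @param initiation,cessation Annual flow proportions in `[0, 1]`.
#' @param m_never,m_current,m_former Status-specific mortality rates.
#' @return Numeric vector `c(never, current, former)` after one year.
#' @export
step_cohort <- function(counts, initiation, cessation,
                        m_never, m_current, m_former) {
  n <- counts[["never"]] * (1 - rate_to_prob(m_never))
  c_ <- counts[["current"]] * (1 - rate_to_prob(m_current))
  f <- counts[["former"]] * (1 - rate_to_prob(m_former))
  starters <- n * initiation
  quitters <- c_ * cessation
  c(never = n - starters, current = c_ + starters - quitters,
    former = f + quitters)
}

# internal single-sex engine: counts_mat is bands x 3 (never, current, former);
# returns an array [bands, 3, years + 1]. Flows, mortality and aging are
# applied in that order each year; `entrants` (never smokers) enter band 1.
sim_counts_engine <- function(counts_mat, initiation, cessation, m_pop,
                              rr_current, rr_former, width, years,
                              entrants = 0) {
  if (!is.matrix(counts_mat)) counts_mat <- matrix(counts_mat, ncol = 3L)
  nb <- nrow(counts_mat)
  out <- array(0, dim = c(nb, 3L, years + 1L))
  out[, , 1L] <- counts_mat
  out_frac <- ifelse(is.finite(width), 1 / width, 0)
  for (t in seq_len(years)) {
    cur <- matrix(out[, , t], ncol = 3L)
    tot <- rowSums(cur)
    pc <- ifelse(tot > 0, cur[, 2] / tot, 0)
    pf <- ifelse(tot > 0, cur[, 3] / tot, 0)
    dm <- decompose_mortality(m_pop, pc, pf, rr_current, rr_former)
    n <- cur[, 1] * exp(-dm$m_never)
    c_ <- cur[, 2] * exp(-dm$m_current)
    f <- cur[, 3] * exp(-dm$m_former)
    starters <- n * initiation
    quitters <- c_ * cessation
    n <- n - starters
    c_ <- c_ + starters - quitters
    f <- f + quitters
    post <- cbind(n, c_, f)
    moved <- post * out_frac
    post <- post - moved
    if (nb > 1) post[-1, ] <- post[-1, ] + moved[-nb, ]
    post[nb, ] <- post[nb, ] + moved[nb, ]  # open-ended tail keeps its outflow
    post[1, 1] <- post[1, 1] + entrants
    out[, , t + 1L] <- post
  }
  out
}

#' Forward simulation of smoking prevalence
#'
#' Runs the three-state smoking model forward: annual status-specific
#' survival (from the population mortality rate decomposed via the mortality
#' relative risks), initiation/cessation flows among survivors, aging of a
#' fraction `1 / band_width` across bands, and new never-smoking entrants
#' into the youngest band.
#'
#' @param initial Data frame `sex, age_low, age_high, never, current, former`
#'   giving starting counts per stratum.
#' @param flows Data frame `sex, age_low, age_high, signed_parameter` (see
#'   [flows_from_signed()]).
#' @param lifetable Life table covering the same strata.
#' @param rrs Data frame `sex, age_low, age_high, rr_current, rr_former`
#'   of mortality relative risks.
#' @param demo Optional demographic rates (as in [project_population()]);
#'   `NULL` for a closed population with no new entrants.
#' @param years Number of annual cycles (>= 1).
#' @return Data frame with columns `sex, age_low, age_high, year` (0-based
#'   cycle), counts `n_never, n_current, n_former` and prevalences
#'   `never, current, former`.
#' @export
simulate_prevalence <- function(initial, flows, lifetable, rrs, demo = NULL,
                                years) {
  stopifnot(years >= 1)
  res <- list()
  for (s in unique(initial$sex)) {
    ini <- initial[initial$sex == s, , drop = FALSE]
    ini <- ini[order(ini$age_low), , drop = FALSE]
    key <- paste(s, ini$age_low, sep = ":")
    fl <- flows[flows$sex == s, , drop = FALSE]
    signed <- fl$signed_parameter[match(key, paste(s, fl$age_low, sep = ":"))]
    if (any(is.na(signed))) stop("flows do not cover all strata", call. = FALSE)
    m <- lifetable$mortality_rate[match(key, stratum_key(lifetable))]
    if (any(is.na(m))) stop("life table does not cover all strata", call. = FALSE)
    rk <- match(key, stratum_key(rrs))
    if (any(is.na(rk))) stop("mortality RRs do not cover all strata", call. = FALSE)
    fls <- flows_from_signed(signed)
    entrants <- 0
    if (!is.null(demo)) {
      fem <- initial[initial$sex == "female", , drop = FALSE]
      fk <- match(paste("female", fem$age_low, sep = ":"),
                  stratum_key(demo$fertility))
      fert <- ifelse(is.na(fk), 0, demo$fertility$fertility[fk])
      births <- sum(fert * (fem$never + fem$current + fem$former))
      entrants <- if (s == "male") births * demo$sex_ratio / (1 + demo$sex_ratio)
                  else births / (1 + demo$sex_ratio)
    }
    arr <- sim_counts_engine(
      as.matrix(ini[, c("never", "current", "former")]),
      fls$initiation, fls$cessation, m,
      rrs$rr_current[rk], rrs$rr_former[rk],
      ini$age_high - ini$age_low, years, entrants)
    nb <- nrow(ini)
    long <- data.frame(
      sex = s,
      age_low = rep(ini$age_low, times = years + 1),
      age_high = rep(ini$age_high, times = years + 1),
      year = rep(0:years, each = nb),
      n_never = as.vector(arr[, 1, ]),
      n_current = as.vector(arr[, 2, ]),
      n_former = as.vector(arr[, 3, ]))
    tot <- long$n_never + long$n_current + long$n_former
    long$never <- ifelse(tot > 0, long$n_never / tot, NA_real_)
    long$current <- ifelse(tot > 0, long$n_current / tot, NA_real_)
    long$former <- ifelse(tot > 0, long$n_former / tot, NA_real_)
    res[[s]] <- long
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# internal: per-sex weighted least squares objective for calibration
calibration_objective <- function(signed, ini_mat, obs, weights, m_pop,
                                  rr_c, rr_f, width, years, obs_year_idx,
                                  entrants = 0) {
  fls <- flows_from_signed(signed)
  arr <- sim_counts_engine(ini_mat, fls$initiation, fls$cessation, m_pop,
                           rr_c, rr_f, width, years, entrants)
  resid <- numeric(0)
  for (j in seq_along(obs_year_idx)) {
    slice <- arr[, , obs_year_idx[j]]
    tot <- rowSums(slice)
    sim_c <- slice[, 2] / tot
    sim_f <- slice[, 3] / tot
    resid <- c(resid, sim_c - obs[[j]]$current, sim_f - obs[[j]]$former)
  }
  sum(unlist(weights) * resid^2)
}

#' Calibrate initiation/cessation rates to observed survey prevalence
#'
#' Estimates one signed flow parameter per age-sex stratum (negative =
#' initiation, positive = cessation) by bounded weighted least squares: the
#' model is seeded with the earliest survey's prevalence and simulated
#' forward; the sum of weighted squared deviations between simulated and
#' observed current/former prevalence at every survey year is minimised
#' with `nlminb` under box constraints `[-1, 1]`, with seeded multi-start
#' to guard against local minima. Sexes are calibrated independently.
#'
#' Observation weights are inverse variances `n_eff / (p (1 - p))` when the
#' panel carries an `n_eff` column; otherwise equal weights are used with a
#' warning.
#'
#' @param observed Survey panel: data frame `sex, age_low, age_high, year,
#'   never, current, former` (proportions) and optionally `n_eff`. At least
#'   two survey years are required.
#' @param lifetable,rrs,demo As in [simulate_prevalence()].
#' @param pyramid Optional starting counts (`sex, age_low, age_high, count`);
#'   defaults to 1000 persons per stratum (the fit depends on counts only
#'   through aging weights).
#' @param n_starts Number of optimisation starts (first at zero, remainder
#'   uniform in `[-0.2, 0.2]`).
#' @param seed Seed for the random starts.
#' @return An object of class `tobacco_calibration`: list with `flows`
#'   (data frame incl. `signed_parameter`, `initiation`, `cessation`),
#'   `objective`, `convergence` (per-sex codes; 0 = converged),
#'   `residuals`, and `n_starts`.
#' @export
calibrate_rates <- function(observed, lifetable, rrs, demo = NULL,
                            pyramid = NULL, n_starts = 5, seed = 1) {
  yrs <- sort(unique(observed$year))
  if (length(yrs) < 2) stop("need surveys from at least two years", call. = FALSE)
  use_neff <- "n_eff" %in% names(observed)
  if (!use_neff) {
    warning("no effective sample sizes supplied; using equal weights",
            call. = FALSE)
  }
  year0 <- yrs[1]
  span <- max(yrs) - year0
  births <- 0
  if (!is.null(demo)) {
    fem_key <- stratum_key(demo$fertility)
    fem <- observed[observed$sex == "female" & observed$year == year0, ,
                    drop = FALSE]
    fcnt <- if (is.null(pyramid)) rep(1000, nrow(fem)) else
      pyramid$count[match(stratum_key(fem), stratum_key(pyramid))]
    fk <- match(stratum_key(fem), fem_key)
    fert <- ifelse(is.na(fk), 0, demo$fertility$fertility[fk])
    births <- sum(fert * fcnt)
  }
  flows_out <- list(); conv <- c(); objs <- c(); resid_out <- list()
  for (s in unique(observed$sex)) {
    obs_s <- observed[observed$sex == s, , drop = FALSE]
    base <- obs_s[obs_s$year == year0, , drop = FALSE]
    base <- base[order(base$age_low), , drop = FALSE]
    nb <- nrow(base)
    key <- paste(s, base$age_low, sep = ":")
    cnt <- if (is.null(pyramid)) rep(1000, nb) else
      pyramid$count[match(key, stratum_key(pyramid))]
    ini_mat <- cnt * as.matrix(base[, c("never", "current", "former")])
    m <- lifetable$mortality_rate[match(key, stratum_key(lifetable))]
    rk <- match(key, stratum_key(rrs))
    if (any(is.na(m)) || any(is.na(rk))) {
      stop("inputs do not cover the survey strata", call. = FALSE)
    }
    obs_by_year <- list(); w_by_year <- list()
    for (j in seq_along(yrs)) {
      oy <- obs_s[obs_s$year == yrs[j], , drop = FALSE]
      oy <- oy[match(base$age_low, oy$age_low), , drop = FALSE]
      obs_by_year[[j]] <- list(current = oy$current, former = oy$former)
      if (use_neff) {
        pclamp <- function(p) pmin(pmax(p, 1e-4), 1 - 1e-4)
        wc <- oy$n_eff / (pclamp(oy$current) * (1 - pclamp(oy$current)))
        wf <- oy$n_eff / (pclamp(oy$former) * (1 - pclamp(oy$former)))
      } else {
        wc <- rep(1, nb); wf <- rep(1, nb)
      }
      w_by_year[[j]] <- c(wc, wf)
    }
    entrants <- if (is.null(demo)) 0 else {
      if (s == "male") births * demo$sex_ratio / (1 + demo$sex_ratio)
      else births / (1 + demo$sex_ratio)
    }
    obj_fn <- function(p) calibration_objective(
      p, ini_mat, obs_by_year, w_by_year, m,
      rrs$rr_current[rk], rrs$rr_former[rk],
      base$age_high - base$age_low, span, obs_year_idx = yrs - year0 + 1L,
      entrants = entrants)
    best <- NULL
    for (k in seq_len(n_starts)) {
      start <- if (k == 1) rep(0, nb) else {
        set.seed(seed + 1000L * k + match(s, unique(observed$sex)))
        stats::runif(nb, -0.2, 0.2)
      }
      fit <- stats::nlminb(start, obj_fn, lower = -1, upper = 1,
                           control = list(rel.tol = 1e-12, eval.max = 2000,
                                          iter.max = 1000))
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    if (best$convergence != 0) {
      warning("calibration for sex '", s, "' did not report convergence: ",
              best$message, call. = FALSE)
    }
    fls <- flows_from_signed(best$par)
    flows_out[[s]] <- data.frame(
      sex = s, age_low = base$age_low, age_high = base$age_high,
      signed_parameter = best$par,
      initiation = fls$initiation, cessation = fls$cessation)
    conv[s] <- best$convergence
    objs[s] <- best$objective
    resid_out[[s]] <- best$objective
  }
  out <- list(flows = do.call(rbind, c(flows_out, make.row.names = FALSE)),
              objective = sum(objs), objective_by_sex = objs,
              convergence = conv, n_starts = n_starts)
  class(out) <- "tobacco_calibration"
  out
}

#' @export
print.tobacco_calibration <- function(x, ...) {
  cat("Smoking initiation/cessation calibration\n")
  cat("  objective (weighted SSE):", format(x$objective, digits = 6), "\n")
  cat("  convergence codes:", paste(names(x$convergence), x$convergence,
                                    sep = "=", collapse = ", "), "\n")
  print(x$flows, digits = 4)
  invisible(x)
}

#' Bootstrap uncertainty for calibrated flow rates
#'
#' Monte Carlo resampling of the calibration inputs: survey prevalence
#' triples are redrawn from Dirichlet distributions (concentrations
#' `proportion * n_eff`), mortality relative risks from lognormal
#' distributions fitted to their confidence intervals (when `lci`/`hci`
#' columns are present), and the calibration is re-run for each draw
#' starting from the base-case optimum.
#'
#' @inheritParams calibrate_rates
#' @param n_iter Number of bootstrap iterations.
#' @param seed Root seed; results are reproducible given the seed.
#' @param default_n_eff Effective sample size used when the panel has none.
#' @return List with `mean` and `sd` data frames of signed parameters,
#'   the draw matrix `draws` (iterations x strata), and `n_failed`.
#' @export
bootstrap_rates <- function(observed, lifetable, rrs, demo = NULL,
                            pyramid = NULL, n_iter = 100, seed = 1,
                            default_n_eff = 1000) {
  stopifnot(n_iter >= 1)
  if (!"n_eff" %in% names(observed)) {
    warning("no effective sample sizes; Dirichlet resampling uses n_eff = ",
            default_n_eff, call. = FALSE)
    observed$n_eff <- default_n_eff
  }
  base_fit <- suppressWarnings(
    calibrate_rates(observed, lifetable, rrs, demo, pyramid,
                    n_starts = 3, seed = seed))
  strata <- base_fit$flows[, c("sex", "age_low", "age_high")]
  draws <- matrix(NA_real_, nrow = n_iter, ncol = nrow(strata))
  has_rr_ci <- all(c("rr_current_lci", "rr_current_hci") %in% names(rrs))
  set.seed(seed)
  n_failed <- 0L
  for (it in seq_len(n_iter)) {
    obs_it <- observed
    for (i in seq_len(nrow(obs_it))) {
      p <- pmax(as.numeric(obs_it[i, c("never", "current", "former")]), 1e-6)
      alpha <- p / sum(p) * obs_it$n_eff[i]
      g <- stats::rgamma(3, shape = alpha, rate = 1)
      if (all(is.finite(g)) && sum(g) > 0) {
        d <- g / sum(g)
        obs_it[i, c("never", "current", "former")] <- as.list(d)
      }
    }
    rrs_it <- rrs
    if (has_rr_ci) {
      for (i in seq_len(nrow(rrs_it))) {
        dc <- lognormal_from_ci(rrs$rr_current[i], rrs$rr_current_lci[i],
                                rrs$rr_current_hci[i])
        df_ <- lognormal_from_ci(rrs$rr_former[i], rrs$rr_former_lci[i],
                                 rrs$rr_former_hci[i])
        rrs_it$rr_current[i] <- draw(dc, 1)
        rrs_it$rr_former[i] <- draw(df_, 1)
      }
    }
    fit <- try(suppressWarnings(
      calibrate_rates(obs_it, lifetable, rrs_it, demo, pyramid,
                      n_starts = 1, seed = seed + it)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      n_failed <- n_failed + 1L
      next
    }
    key <- stratum_key(strata)
    draws[it, ] <- fit$flows$signed_parameter[
      match(key, stratum_key(fit$flows))]
  }
  ok <- stats::complete.cases(draws)
  mean_df <- cbind(strata, signed_parameter = colMeans(draws[ok, , drop = FALSE]))
  sd_df <- cbind(strata, sd = apply(draws[ok, , drop = FALSE], 2, stats::sd))
  list(mean = mean_df, sd = sd_df, draws = draws,
       base = base_fit, n_failed = n_failed)
}
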