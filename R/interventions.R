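#' Convert an odds ratio to a relative risk
#'
#' Exact 2x2-table conversion given the baseline (unexposed) risk:
#' `RR = OR / (1 - p0 + p0 * OR)`. Approaches the OR as the outcome
#' becomes rare.
#'
#' @param odds_ratio Positive odds ratio.
#' @param baseline_risk Baseline outcome risk in `(0, 1)`.
#' @return Relative risk.
#' @examples
#' or_to_rr(2, 0.2)  # 1.6667
#' @export
or_to_rr <- function(odds_ratio, baseline_risk) {
  stopifnot(all(odds_ratio > 0))
  if (any(baseline_risk <= 0 | baseline_risk >= 1)) {
    stop("baseline_risk must be in (0, 1)", call. = FALSE)
  }
  odds_ratio / (1 - baseline_risk + baseline_risk * odds_ratio)
}

#' Relative retail price change from an excise tax change
#'
#' With full pass-through and excise expressed as a share of retail price,
#' raising the excise share from `t0` to `t1` changes the retail price by
#' `(t1 - t0) / (1 - t1)` (from the identity `p1 = p0 (1 - t0) / (1 - t1)`).
#' A pass-through factor below 1 scales the change proportionally.
#'
#' @param current_share,target_share Excise shares of retail price in
#'   `[0, 1)`.
#' @param pass_through Fraction of the tax change passed into price
#'   (default 1).
#' @return Relative price change (proportion; 0.6 means +60%).
#' @examples
#' price_change_from_tax(0.20, 0.50)  # 0.6
#' @export
price_change_from_tax <- function(current_share, target_share,
                                  pass_through = 1) {
  stopifnot(current_share >= 0, target_share >= 0)
  if (target_share >= 1) stop("excise share must be below 1", call. = FALSE)
  pass_through * (target_share - current_share) / (1 - target_share)
}

# internal: effect multipliers on initiation/cessation for one sex from an
# effects table (rows: target, measure, value, sex) and a price change
effect_multipliers <- function(effects, sex, price_change) {
  sel <- effects$sex %in% c("all", sex)
  eff <- effects[sel, , drop = FALSE]
  mult_init <- 1; mult_cess <- 1; prev_reduction <- 0
  for (i in seq_len(nrow(eff))) {
    tgt <- eff$target[i]; msr <- eff$measure[i]; val <- eff$value[i]
    if (msr == "relative_risk") {
      if (tgt == "initiation") mult_init <- mult_init * val
      if (tgt == "cessation") mult_cess <- mult_cess * val
    } else if (msr == "price_elasticity") {
      if (is.null(price_change)) {
        stop("price elasticity effect requires a price change", call. = FALSE)
      }
      if (tgt == "initiation") {
        mult_init <- mult_init * max(0, 1 + val * price_change)
      }
      if (tgt == "cessation") {
        mult_cess <- mult_cess * max(0, 1 + val * price_change)
      }
      if (tgt == "prevalence") {
        prev_reduction <- prev_reduction + min(1, max(0, -val * price_change))
      }
    } else if (msr == "relative_reduction") {
      if (tgt == "prevalence") prev_reduction <- prev_reduction + val
    } else {
      stop("unknown effect measure: ", msr, call. = FALSE)
    }
  }
  list(init = mult_init, cess = mult_cess,
       prev_reduction = min(prev_reduction, 1))
}

#' Apply intervention effects to the smoking model
#'
#' Builds the intervention-scenario smoking prevalence trajectory. During
#' the effect horizon, initiation/cessation relative risks multiply the
#' baseline flow rates and price elasticities scale them by
#' `1 + elasticity * price_change` (floored at zero); after the horizon the
#' flows revert to baseline while accrued prevalence changes persist.
#' Effects on prevalence itself (absolute relative reductions, or the
#' prevalence price elasticity) move the stated fraction of current
#' smokers into the former-smoker state at the start of year 1 - quitting,
#' since adults cannot re-enter the never state. Scaled flow rates outside
#' `[0, 1]` are clipped with a warning.
#'
#' @param initial,base_flows,lifetable,rrs,demo As in
#'   [simulate_prevalence()].
#' @param effects Data frame of effect rows: `target`
#'   (initiation/cessation/prevalence), `measure` (relative_risk,
#'   relative_reduction, price_elasticity), `value`, `sex`
#'   (male/female/all). An empty data frame reproduces the base scenario.
#' @param price_change Relative retail price change (required when any
#'   effect is an elasticity), e.g. from [price_change_from_tax()].
#' @param horizon Effect horizon in years (default 10).
#' @param years Total simulated years (>= horizon).
#' @return Trajectory data frame in the format of [simulate_prevalence()].
#' @export
apply_effects <- function(initial, base_flows, lifetable, rrs, demo = NULL,
                          effects, price_change = NULL, horizon = 10,
                          years = horizon) {
  stopifnot(years >= 1)
  out <- NULL
  for (s in unique(initial$sex)) {
    ini <- initial[initial$sex == s, , drop = FALSE]
    ini <- ini[order(ini$age_low), , drop = FALSE]
    key <- paste(s, ini$age_low, sep = ":")
    fl <- base_flows[base_flows$sex == s, , drop = FALSE]
    signed <- fl$signed_parameter[match(key, paste(s, fl$age_low, sep = ":"))]
    base <- flows_from_signed(signed)
    m <- lifetable$mortality_rate[match(key, stratum_key(lifetable))]
    rk <- match(key, stratum_key(rrs))
    mult <- effect_multipliers(effects, s, price_change)
    counts <- as.matrix(ini[, c("never", "current", "former")])
    if (mult$prev_reduction > 0) {
      quit <- counts[, 2] * mult$prev_reduction
      counts[, 2] <- counts[, 2] - quit
      counts[, 3] <- counts[, 3] + quit
    }
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
    width <- ini$age_high - ini$age_low
    nb <- nrow(ini)
    arr <- array(0, dim = c(nb, 3, years + 1))
    arr[, , 1] <- counts
    for (t in seq_len(years)) {
      if (t <= horizon) {
        init_t <- base$initiation * mult$init
        cess_t <- base$cessation * mult$cess
      } else {
        init_t <- base$initiation
        cess_t <- base$cessation
      }
      clipped <- init_t > 1 | cess_t > 1
      if (any(clipped)) {
        warning("scaled flow rate above 1 clipped", call. = FALSE)
        init_t <- pmin(init_t, 1); cess_t <- pmin(cess_t, 1)
      }
      step <- sim_counts_engine(arr[, , t], init_t, cess_t, m,
                                rrs$rr_current[rk], rrs$rr_former[rk],
                                width, 1, entrants)
      arr[, , t + 1] <- step[, , 2]
    }
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
    out <- rbind(out, long)
  }
  rownames(out) <- NULL
  out
}
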