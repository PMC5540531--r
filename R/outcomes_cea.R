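#' Discounted DALYs from a Markov trace
#'
#' Years lived with disability (YLD) accrue in the disease-history states,
#' weighted by the disability weight and discounted at `(1 + r)^-t`;
#' years of life lost (YLL) accrue at death as the discounted annuity of
#' the residual life expectancy at the age of death:
#' `YLL(t) = deaths(t) * (1 - (1 + r)^-LE) / r * (1 + r)^-t`
#' (and `deaths * LE` at `r = 0`). DALY = YLL + YLD.
#'
#' @param trace A [run_cohort()] `markov_trace` carrying `sex` and
#'   `start_age` attributes (or supply them explicitly).
#' @param weights List with disability weights `ihd` and `stroke`, each in
#'   `[0, 1]`.
#' @param lifetable Life table with a `life_expectancy` column on strata
#'   covering the cohort's ages.
#' @param discount_rate Annual discount rate (default 0.03).
#' @param sex,start_age Override the trace attributes.
#' @return List with `yld`, `yll` and `daly` (scalars).
#' @export
compute_dalys <- function(trace, weights, lifetable, discount_rate = 0.03,
                          sex = attr(trace, "sex"),
                          start_age = attr(trace, "start_age")) {
  stopifnot(inherits(trace, "markov_trace"), discount_rate >= 0)
  if (is.null(weights$ihd) || is.null(weights$stroke)) {
    stop("disability weights for ihd and stroke are required", call. = FALSE)
  }
  occ <- trace$occupancy
  cycles <- nrow(occ) - 1
  t <- seq_len(cycles)
  df <- (1 + discount_rate)^(-t)
  yld <- sum((occ[t + 1, 2] * weights$ihd +
                occ[t + 1, 3] * weights$stroke) * df)
  le <- vapply(t, function(tt) {
    age <- min(start_age + tt - 1, 99)
    v <- lookup_band(lifetable, sex, age, "life_expectancy")
    if (is.na(v)) stop("life table has no life expectancy at age ", age,
                       call. = FALSE)
    v
  }, numeric(1))
  annuity <- if (discount_rate == 0) le else
    (1 - (1 + discount_rate)^(-le)) / discount_rate
  yll <- sum(trace$deaths * annuity * df)
  list(yld = yld, yll = yll, daly = yld + yll)
}

#' DALYs averted by an intervention, by sex
#'
#' Sums discounted DALYs over all cohort traces of a paired
#' [run_population()] run and differences base minus scenario.
#'
#' @param paired List with `base` and `scenario` trace lists (matching
#'   names).
#' @param weights,lifetable,discount_rate As in [compute_dalys()].
#' @return List with `male`, `female` and `total` DALYs averted and the
#'   per-scenario totals `base_dalys`, `scenario_dalys`.
#' @export
dalys_averted <- function(paired, weights, lifetable, discount_rate = 0.03) {
  if (!setequal(names(paired$base), names(paired$scenario))) {
    stop("base and scenario runs have mismatched cohorts", call. = FALSE)
  }
  tally <- function(traces) {
    out <- c(male = 0, female = 0)
    for (tr in traces) {
      s <- attr(tr, "sex")
      out[s] <- out[s] + compute_dalys(tr, weights, lifetable,
                                       discount_rate)$daly
    }
    out
  }
  b <- tally(paired$base); sc <- tally(paired$scenario)
  av <- b - sc
  list(male = unname(av["male"]), female = unname(av["female"]),
       total = sum(av), base_dalys = b, scenario_dalys = sc)
}

#' Average cost-effectiveness ratio
#'
#' Cost per DALY averted versus doing nothing, reported to the integer
#' USD (round half away from zero) as in standard CEA result tables. A
#' non-positive effect is flagged as not computable (`NA` with a
#' `dominated` attribute) rather than returning a misleading ratio.
#'
#' @param cost Discounted intervention cost (USD).
#' @param dalys DALYs averted.
#' @param rounded Round to integer USD (default TRUE).
#' @return Cost per DALY averted.
#' @examples
#' acer(1547355, 287832)  # 5
#' acer(3381652, 12666)   # 267
#' @export
acer <- function(cost, dalys, rounded = TRUE) {
  if (cost == 0 && dalys == 0) return(0)
  if (dalys <= 0) {
    return(structure(NA_real_, dominated = TRUE))
  }
  r <- cost / dalys
  if (rounded) sign(r) * floor(abs(r) + 0.5) else r
}

#' Incremental cost-effectiveness frontier with dominance
#'
#' Orders options by effect (against an implicit zero-cost, zero-effect
#' comparator), flags simple dominance (an option is dominated when some
#' other option, or the comparator, has lower-or-equal cost and
#' greater-or-equal effect, strictly better in at least one), optionally
#' applies extended dominance, and computes ICERs along the efficient
#' frontier. Exact ties are broken deterministically by name order (the
#' later name is flagged dominated).
#'
#' @param results Data frame with columns `intervention`, `cost`, `effect`.
#' @param extended Also flag extended dominance (default FALSE).
#' @param comparator_name Name for the do-nothing comparator row.
#' @return Data frame sorted by effect with columns `intervention`,
#'   `cost`, `effect`, `dominated`, `icer` (NA for dominated options; the
#'   comparator has ICER 0).
#' @export
icer_frontier <- function(results, extended = FALSE,
                          comparator_name = "no_intervention") {
  stopifnot(nrow(results) >= 1)
  df <- results[, c("intervention", "cost", "effect")]
  if (!comparator_name %in% df$intervention) {
    df <- rbind(data.frame(intervention = comparator_name, cost = 0,
                           effect = 0), df)
  }
  df <- df[order(df$effect, df$cost, df$intervention), ]
  n <- nrow(df)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i]
      strict <- df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i]
      tie <- df$cost[j] == df$cost[i] && df$effect[j] == df$effect[i] &&
        df$intervention[j] < df$intervention[i]
      if ((better && strict) || tie) {
        dominated[i] <- TRUE
        break
      }
    }
  }
  if (extended) {
    repeat {
      idx <- which(!dominated)
      fr <- df[idx, ]
      changed <- FALSE
      if (nrow(fr) >= 3) {
        ic <- c(NA, diff(fr$cost) / diff(fr$effect))
        for (k in 2:(length(ic) - 1)) {
          if (!is.na(ic[k]) && !is.na(ic[k + 1]) && ic[k] > ic[k + 1]) {
            dominated[idx[k]] <- TRUE
            changed <- TRUE
            break
          }
        }
      }
      if (!changed) break
    }
  }
  df$dominated <- dominated
  df$icer <- NA_real_
  idx <- which(!dominated)
  if (length(idx) > 0) {
    df$icer[idx[1]] <- if (df$effect[idx[1]] > 0)
      df$cost[idx[1]] / df$effect[idx[1]] else 0
    if (length(idx) > 1) {
      df$icer[idx[-1]] <- diff(df$cost[idx]) / diff(df$effect[idx])
    }
  }
  rownames(df) <- NULL
  df
}

#' WHO willingness-to-pay classification
#'
#' An intervention with a cost-effectiveness ratio strictly below one GDP
#' per capita per DALY averted is very cost-effective; between one and
#' three times, cost-effective; above three times, not cost-effective.
#' Boundaries go to the upper class (the criterion is strictly "below").
#'
#' @param acer Cost per DALY averted (USD).
#' @param gdp_per_capita GDP per capita (USD; default 910, Tanzania 2013).
#' @return One of `"very cost-effective"`, `"cost-effective"`,
#'   `"not cost-effective"`.
#' @export
classify_wtp <- function(acer, gdp_per_capita = 910) {
  stopifnot(gdp_per_capita > 0)
  ifelse(acer < gdp_per_capita, "very cost-effective",
         ifelse(acer <= 3 * gdp_per_capita, "cost-effective",
                "not cost-effective"))
}
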