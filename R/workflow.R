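#' Evaluate one intervention end to end
#'
#' Runs the full pipeline for a single intervention against the
#' no-intervention base case: simulate the base smoking-prevalence
#' trajectory, apply the intervention's effects to get the scenario
#' trajectory, run the paired Markov population, compute discounted DALYs
#' averted by sex, and discount the program cost.
#'
#' @param initial Starting smoker counts on the survey scheme
#'   (`sex, age_low, age_high, never, current, former`).
#' @param flows Calibrated signed flow rates (see [calibrate_rates()]).
#' @param bundle Model inputs: list with `lifetable_survey`,
#'   `mortality_rrs`, `demo`, `pyramid_markov`, `lifetable_markov`,
#'   `schedules`, `disease_rrs`, `disability_weights` (e.g. a
#'   [make_truth()] bundle).
#' @param effects Effect rows for this intervention (see
#'   [apply_effects()]).
#' @param annual_cost Annual program cost in base-year USD.
#' @param config A [default_config()] list.
#' @param price_change Relative price change for elasticity effects.
#' @return List with `cost` (discounted), `annual_cost`, `dalys_male`,
#'   `dalys_female`, `dalys_total`, `acer` and `wtp_class`.
#' @export
evaluate_intervention <- function(initial, flows, bundle, effects,
                                  annual_cost, config = default_config(),
                                  price_change = NULL) {
  years <- config$trajectory_years
  base_traj <- simulate_prevalence(initial, flows, bundle$lifetable_survey,
                                   bundle$mortality_rrs, bundle$demo, years)
  scen_traj <- apply_effects(initial, flows, bundle$lifetable_survey,
                             bundle$mortality_rrs, bundle$demo, effects,
                             price_change,
                             horizon = config$effect_horizon_years,
                             years = years)
  paired <- run_population(bundle$pyramid_markov, bundle$lifetable_markov,
                           bundle$schedules, bundle$disease_rrs,
                           base_traj, scen_traj,
                           horizon_age = config$horizon_age)
  av <- dalys_averted(paired, bundle$disability_weights,
                      bundle$lifetable_markov, config$discount_rate)
  cost <- discounted_program_cost(annual_cost, config$cost_horizon_years,
                                  config$discount_rate)
  a <- acer(cost, av$total)
  list(cost = cost, annual_cost = annual_cost,
       dalys_male = av$male, dalys_female = av$female,
       dalys_total = av$total, acer = a,
       wtp_class = if (is.na(a)) NA_character_ else
         classify_wtp(a, config$wtp_gdp_per_capita))
}

#' Evaluate a set of interventions and build the results table
#'
#' Evaluates each intervention independently against no intervention
#' (interventions are modelled one at a time, not as bundles), then adds
#' dominance flags and frontier ICERs. The comparator row has zero cost
#' and effect.
#'
#' @inheritParams evaluate_intervention
#' @param effects_table Effect rows for all interventions (column
#'   `intervention` selects rows; format of [tz_intervention_effects()]).
#' @param annual_costs Named vector of annual program costs (USD) keyed by
#'   intervention.
#' @param price_changes Optional named vector of relative price changes
#'   (required for interventions with elasticity effects).
#' @return Data frame with one row per intervention plus the comparator:
#'   `intervention, cost, dalys_male, dalys_female, dalys_total, acer,
#'   dominated, icer, wtp_class`.
#' @export
cea_evaluate <- function(initial, flows, bundle, effects_table, annual_costs,
                         config = default_config(), price_changes = NULL) {
  ivs <- names(annual_costs)
  rows <- list()
  for (iv in ivs) {
    eff <- effects_table[effects_table$intervention == iv, , drop = FALSE]
    pc <- if (!is.null(price_changes) && iv %in% names(price_changes))
      price_changes[[iv]] else NULL
    ev <- evaluate_intervention(initial, flows, bundle, eff,
                                annual_costs[[iv]], config, pc)
    rows[[iv]] <- data.frame(intervention = iv, cost = ev$cost,
                             dalys_male = ev$dalys_male,
                             dalys_female = ev$dalys_female,
                             dalys_total = ev$dalys_total,
                             acer = as.numeric(ev$acer),
                             wtp_class = ev$wtp_class)
  }
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res <- rbind(data.frame(intervention = "no_intervention", cost = 0,
                          dalys_male = 0, dalys_female = 0, dalys_total = 0,
                          acer = 0, wtp_class = NA_character_), res)
  fr <- icer_frontier(data.frame(intervention = res$intervention,
                                 cost = res$cost, effect = res$dalys_total))
  i <- match(res$intervention, fr$intervention)
  res$dominated <- fr$dominated[i]
  res$icer <- fr$icer[i]
  res
}

#' Calibration workflow over a survey panel
#'
#' Thin wrapper: calibrates signed initiation/cessation rates from a
#' survey panel and, optionally, bootstraps their uncertainty.
#'
#' @param observed Survey panel (see [calibrate_rates()]).
#' @param bundle Model inputs providing `lifetable_survey`,
#'   `mortality_rrs`, `demo` and `pyramid_survey`.
#' @param n_boot Bootstrap iterations (0 to skip).
#' @param seed Seed.
#' @return List with `fit` (a `tobacco_calibration`) and, when requested,
#'   `bootstrap`.
#' @export
cea_calibrate <- function(observed, bundle, n_boot = 0, seed = 1) {
  fit <- calibrate_rates(observed, bundle$lifetable_survey,
                         bundle$mortality_rrs, bundle$demo,
                         bundle$pyramid_survey, seed = seed)
  out <- list(fit = fit)
  if (n_boot > 0) {
    out$bootstrap <- bootstrap_rates(observed, bundle$lifetable_survey,
                                     bundle$mortality_rrs, bundle$demo,
                                     bundle$pyramid_survey, n_iter = n_boot,
                                     seed = seed)
  }
  out
}

# internal: distributions for one intervention's PSA parameters
psa_distributions <- function(effects_table, annual_costs, cost_spread = 0.2) {
  dists <- list()
  for (iv in names(annual_costs)) {
    dists[[paste0("cost_", iv)]] <- pert_dist(annual_costs[[iv]], cost_spread)
  }
  for (i in seq_len(nrow(effects_table))) {
    e <- effects_table[i, ]
    nm <- paste("effect", e$intervention, e$target, e$sex, sep = "_")
    d <- NULL
    if (identical(e$distribution, "lognormal")) {
      ok <- !is.na(e$lci) && !is.na(e$hci) && e$value > 0 &&
        e$lci <= e$value && e$value <= e$hci
      if (ok) {
        d <- lognormal_from_ci(e$value, e$lci, e$hci)
      } else {
        warning("effect ", nm, ": interval does not bracket the estimate; ",
                "falling back to PERT +/-20%", call. = FALSE)
        d <- pert_dist(e$value, 0.2)
      }
    } else if (identical(e$distribution, "pert")) {
      d <- pert_dist(e$value, ifelse(is.na(e$spread), 0.2, e$spread))
    } else {
      d <- point_dist(e$value)
    }
    dists[[nm]] <- d
  }
  dists
}

#' Probabilistic sensitivity analysis over the full pipeline
#'
#' Per iteration, samples every uncertain parameter from its distribution
#' - annual costs (PERT, +/-20% around the base value), intervention
#' effect sizes (lognormal fitted to their CIs, or PERT as specified) and
#' disease relative risks (lognormal) - and re-runs the evaluation
#' pipeline for each intervention, collecting (cost, DALYs averted)
#' pairs. Each parameter draws from its own substream derived from the
#' root seed, so results are reproducible and insensitive to adding
#' parameters. Iteration failures are recorded; more than 5% aborts.
#'
#' @inheritParams cea_evaluate
#' @param n_iter Number of Monte Carlo iterations.
#' @param seed Root seed.
#' @param cost_spread PERT half-width as a fraction of the annual cost
#'   (default 0.2, the +/-20% convention used for PERT-distributed
#'   parameters; 0 makes costs degenerate).
#' @param sample_disease_rrs Also sample the disease RRs (default TRUE).
#' @return List of class `psa_output`: `draws` (data frame `iteration,
#'   intervention, cost, dalys_averted`), `summary` (per-intervention
#'   means and 95% intervals), `n_iter`, `seed`, `n_failed`.
#' @export
run_psa <- function(initial, flows, bundle, effects_table, annual_costs,
                    config = default_config(), n_iter = 200, seed = 1,
                    price_changes = NULL, cost_spread = 0.2,
                    sample_disease_rrs = TRUE) {
  stopifnot(n_iter >= 1)
  dists <- psa_distributions(effects_table, annual_costs, cost_spread)
  if (sample_disease_rrs) {
    for (i in seq_len(nrow(bundle$disease_rrs))) {
      r <- bundle$disease_rrs[i, ]
      dists[[paste("rr", r$disease, r$sex, r$age_low, sep = "_")]] <-
        lognormal_from_ci(r$rr, r$lci, r$hci)
    }
  }
  draws <- draw_substreams(dists, n_iter, seed)
  out <- list(); n_failed <- 0L
  for (it in seq_len(n_iter)) {
    eff_it <- effects_table
    for (i in seq_len(nrow(eff_it))) {
      e <- eff_it[i, ]
      nm <- paste("effect", e$intervention, e$target, e$sex, sep = "_")
      eff_it$value[i] <- draws[[nm]][it]
    }
    rrs_it <- bundle$disease_rrs
    if (sample_disease_rrs) {
      for (i in seq_len(nrow(rrs_it))) {
        r <- rrs_it[i, ]
        rrs_it$rr[i] <- draws[[paste("rr", r$disease, r$sex, r$age_low,
                                     sep = "_")]][it]
      }
    }
    bundle_it <- bundle
    bundle_it$disease_rrs <- rrs_it
    res_it <- try({
      rows <- list()
      for (iv in names(annual_costs)) {
        eff <- eff_it[eff_it$intervention == iv, , drop = FALSE]
        pc <- if (!is.null(price_changes) && iv %in% names(price_changes))
          price_changes[[iv]] else NULL
        ac <- draws[[paste0("cost_", iv)]][it]
        ev <- evaluate_intervention(initial, flows, bundle_it, eff, ac,
                                    config, pc)
        rows[[iv]] <- data.frame(iteration = it, intervention = iv,
                                 cost = ev$cost,
                                 dalys_averted = ev$dalys_total)
      }
      do.call(rbind, c(rows, make.row.names = FALSE))
    }, silent = TRUE)
    if (inherits(res_it, "try-error")) {
      n_failed <- n_failed + 1L
      if (n_failed > 0.05 * n_iter) {
        stop("more than 5% of PSA iterations failed; last error: ",
             attr(res_it, "condition")$message, call. = FALSE)
      }
      next
    }
    out[[it]] <- res_it
  }
  draws_df <- do.call(rbind, c(out, make.row.names = FALSE))
  agg <- do.call(rbind, lapply(split(draws_df, draws_df$intervention),
                               function(d) data.frame(
    intervention = d$intervention[1],
    mean_cost = mean(d$cost),
    mean_dalys_averted = mean(d$dalys_averted),
    dalys_lo = stats::quantile(d$dalys_averted, 0.025, names = FALSE),
    dalys_hi = stats::quantile(d$dalys_averted, 0.975, names = FALSE))))
  rownames(agg) <- NULL
  structure(list(draws = draws_df, summary = agg, n_iter = n_iter,
                 seed = seed, n_failed = n_failed),
            class = "psa_output")
}

#' @export
print.psa_output <- function(x, ...) {
  cat("Probabilistic sensitivity analysis:", x$n_iter, "iterations, seed",
      x$seed, "\n")
  if (x$n_failed > 0) cat("  failed iterations:", x$n_failed, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}
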