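#!/usr/bin/env Rscript
# Stage 1: assemble the model inputs.
#
# The observed Tanzanian inputs that are published (survey smoking
# prevalence, disease relative risks, intervention effect sizes, the
# annual cost table) ship with the package as CSV fixtures. Everything
# that came from external sources (life tables, population counts,
# disease schedules, mortality RRs by smoking status) is generated here
# as an internally consistent synthetic bundle with known ground truth,
# so the downstream stages are fully reproducible offline. Survey panels
# with multinomial sampling noise are drawn from the bundle's true
# prevalence trajectory.

suppressPackageStartupMessages(library(tobaccoCEA))

seed <- 1
dir.create("results", showWarnings = FALSE)

truth <- make_truth(seed = seed)
surveys <- make_surveys(truth, n_per_stratum = 2000, seed = seed)

saveRDS(truth, file.path("results", "truth_bundle.rds"))
write.csv(surveys, file.path("results", "synthetic_surveys.csv"),
          row.names = FALSE)
write.csv(truth$flows, file.path("results", "true_signed_rates.csv"),
          row.names = FALSE)
write.csv(truth$lifetable_markov, file.path("results", "lifetable.csv"),
          row.names = FALSE)

cat("Synthetic bundle (seed", seed, "):\n")
cat("  strata:", nrow(truth$scheme_survey), "survey /",
    nrow(truth$scheme_markov), "Markov\n")
cat("  population:", format(sum(truth$pyramid_markov$count), big.mark = ","),
    "persons aged 15+\n")
cat("  male 15-24 current smoking (truth, year 0):",
    round(truth$initial_prev$current[truth$initial_prev$sex == "male" &
                                       truth$initial_prev$age_low == 15], 3),
    "\n")
cat("  survey panels:", length(unique(surveys$year)), "waves x",
    nrow(truth$scheme_survey), "strata, n = 2000 per stratum\n")
cat("Published fixtures available via tz_*():",
    nrow(tz_survey_prevalence()), "prevalence rows,",
    nrow(tz_intervention_effects()), "effect rows,",
    nrow(tz_intervention_costs()), "cost-center rows\n")
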