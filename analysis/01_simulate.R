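#!/usr/bin/env Rscript
# Step 1 — generate the synthetic claims population.
#
# The real study population (a national health-insurance claims database)
# is not public, so the whole workflow runs on the "estonia-like" preset:
# 20,000 insured persons aged 50+, Gompertz baseline mortality, Charlson
# comorbidity claims with realistic in/outpatient repeat patterns, and
# incident hip fractures whose effect on the death hazard decays from a
# large early excess to a persistent plateau.

library(fracexcess)

SEED <- 20260925L
params <- sim_params(n_persons = 20000L)
sim <- simulate_cohort(params, seed = SEED)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
simulate_to_dir(sim, "scratch/sim")
data.table::fwrite(sim$truth, "scratch/sim/truth.csv")

n_frac <- sum(!is.na(sim$truth$frac_time_years))
n_dead <- sum(!is.na(sim$persons$death_date))
cat(sprintf("simulated %d persons, %d claims\n",
            nrow(sim$persons), nrow(sim$claims)))
cat(sprintf("  %d first hip fractures, %d deaths before study closure\n",
            n_frac, n_dead))

dir.create("results", showWarnings = FALSE)
summary_tab <- data.frame(
  quantity = c("persons", "claims", "fractures", "deaths"),
  value = c(nrow(sim$persons), nrow(sim$claims), n_frac, n_dead))
write.csv(summary_tab, "results/01_population_summary.csv", row.names = FALSE)
cat("wrote scratch/sim/{persons,claims,truth}.csv and results/01_population_summary.csv\n")
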