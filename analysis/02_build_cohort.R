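#!/usr/bin/env Rscript
# Step 2 — ascertain incident hip-fracture cases, match references 1:4 on
# sex and birth year, score pre-index Charlson comorbidity, and lay out
# follow-up to death or study closure (2016-05-04).

library(fracexcess)

SEED <- 20260925L
persons <- read_persons("scratch/sim/persons.csv")
claims <- read_claims("scratch/sim/claims.csv")
link <- validate_linkage(persons, claims)
cat(sprintf("linkage: %d claims checked, %d flagged\n",
            link$rows_read, link$rows_rejected))

cohort <- build_cohort(persons, claims, ratio = 4L, min_age = 50L,
                       seed = SEED + 1L)
data.table::fwrite(cohort, "scratch/cohort.csv")

by_arm <- aggregate(cbind(age_at_index, cci_score) ~ arm, cohort, mean)
deaths <- table(cohort$arm[cohort$event == "death"])
cat(sprintf("cohort: %d cases, %d references\n",
            sum(cohort$arm == "case"), sum(cohort$arm == "reference")))
print(by_arm)
cat(sprintf("deaths during follow-up: %d cases, %d references\n",
            deaths[["case"]], deaths[["reference"]]))

write.csv(data.frame(
  arm = by_arm$arm, n = as.vector(table(cohort$arm)[by_arm$arm]),
  mean_age = by_arm$age_at_index, mean_cci = by_arm$cci_score,
  deaths = as.vector(deaths[by_arm$arm])),
  "results/02_cohort_descriptives.csv", row.names = FALSE)
cat("wrote scratch/cohort.csv and results/02_cohort_descriptives.csv\n")
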