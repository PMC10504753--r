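#!/usr/bin/env Rscript
# Stage 2: CTQ-SF screening. Scores the five trauma subscales, flags
# them against the clinical cut-offs (sexual abuse >= 8, etc.), computes
# CSA prevalence with its Wald interval over the full cohort, and keeps
# the pure-CSA analysis sample (comorbid forms of abuse excluded).

library(symptomnet)

cohort <- read.csv("results/cohort.csv", stringsAsFactors = FALSE)
scr <- screen_cohort(cohort)
print(scr)

analysis <- cohort[scr$analysis_flag, ]
write.csv(analysis, "results/analysis_cohort.csv", row.names = FALSE)
jsonlite::write_json(
  list(n_total = scr$n_total, n_csa = scr$n_csa,
       n_analysis = scr$n_analysis,
       prevalence_pct = scr$prevalence_pct,
       ci_low_pct = scr$ci_low_pct, ci_high_pct = scr$ci_high_pct),
  "results/screen.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/analysis_cohort.csv and results/screen.json\n")
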