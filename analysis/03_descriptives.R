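#!/usr/bin/env Rscript
# Stage 3: Table-1 style descriptives on the CSA analysis sample --
# counts (percent) by sex with uncorrected chi-square tests, mean (SD)
# with pooled t-tests for age and scale totals, and Cronbach's alpha
# reliability for each instrument.

library(symptomnet)

analysis <- read.csv("results/analysis_cohort.csv",
                     stringsAsFactors = FALSE)
t1 <- build_table_one(analysis)
print(t1)
write.table(t1$formatted, "results/table1.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

alphas <- c(
  ctq = cronbach_alpha(analysis[, sprintf("CTQ%02d", 1:28)]),
  gad7 = cronbach_alpha(analysis[, sprintf("GAD%02d", 1:7)]),
  phq9 = cronbach_alpha(analysis[, sprintf("PHQ%02d", 1:9)]))
cat(sprintf("Cronbach alpha: CTQ-SF %.3f, GAD-7 %.3f, PHQ-9 %.3f\n",
            alphas["ctq"], alphas["gad7"], alphas["phq9"]))
jsonlite::write_json(as.list(alphas), "results/reliability.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
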