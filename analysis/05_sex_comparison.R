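#!/usr/bin/env Rscript
# Stage 5: male vs female network comparison by permutation -- global
# strength invariance, maximum edge difference, and per-edge tests with
# Holm correction over the 120 edges.

library(symptomnet)

analysis <- read.csv("results/analysis_cohort.csv",
                     stringsAsFactors = FALSE)
items <- symptom_items(analysis)
male <- items[analysis$sex == "male", ]
female <- items[analysis$sex == "female", ]
cat(sprintf("groups: %d male, %d female\n", nrow(male), nrow(female)))

nct <- network_comparison_test(male, female, permutations = 1000,
                               seed = 20211005L)
print(nct)

diffs <- edge_difference_table(nct$net1, nct$net2)
diffs <- diffs[order(-abs(diffs$diff)), ]
cat("largest male-minus-female edge differences:\n")
print(head(diffs, 5), row.names = FALSE)

out <- list(global_strength = as.list(nct$global_strength),
            strength_diff = nct$strength_diff_observed,
            strength_p = nct$strength_p,
            M = nct$M_observed, M_p = nct$M_p,
            permutations = nct$permutations, edges = nct$edges)
jsonlite::write_json(out, "results/nct.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
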