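#!/usr/bin/env Rscript
# Stage 6: accuracy and stability diagnostics -- nonparametric bootstrap
# CIs for every edge (with pairwise bootstrapped difference tests) and
# the case-dropping correlation-stability coefficient for expected
# influence and bridge expected influence.

library(symptomnet)

analysis <- read.csv("results/analysis_cohort.csv",
                     stringsAsFactors = FALSE)
items <- symptom_items(analysis)

eb <- bootstrap_edges(items, B = 500, seed = 20211007L)
cat(sprintf("edge bootstrap: %d replicates, %d failed\n", eb$B,
            eb$n_failed))
covered <- mean(eb$edges$ci_low <= eb$edges$estimate &
                  eb$edges$estimate <= eb$edges$ci_high)
cat(sprintf("CIs covering the sample estimate: %.0f%%\n", 100 * covered))

cs_ei <- case_drop_cs(items, "expected_influence", B = 50,
                      seed = 20211011L)
cs_bei <- case_drop_cs(items, "bridge_expected_influence", B = 50,
                       seed = 20211013L)
print(cs_ei)
print(cs_bei)

jsonlite::write_json(
  list(edge_ci = eb$edges, B = eb$B,
       cs_expected_influence = cs_ei$cs_coefficient,
       cs_expected_influence_label = cs_ei$label,
       cs_bridge = cs_bei$cs_coefficient,
       cs_bridge_label = cs_bei$label,
       cs_curve_ei = cs_ei$cs_curve, cs_curve_bei = cs_bei$cs_curve),
  "results/stability.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/stability.json\n")
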