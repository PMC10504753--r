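# symptomnet

Symptom-network analysis of comorbid anxiety and depression among
survivors of childhood sexual abuse (CSA), as a tested, reusable R
pipeline driven by a synthetic cohort with known ground truth.

## The problem and who this is for

Large survey studies screen students with the CTQ-SF (28 trauma items),
then analyze anxiety (GAD-7, 7 items) and depression (PHQ-9, 9 items)
in the CSA-positive subsample as a *network*: nodes are symptoms, edges
are regularized partial correlations, and the interesting quantities
are central symptoms, bridge symptoms linking the two disorders,
sex differences in structure, and the stability of all of the above.
The raw data behind such studies are typically unavailable, which makes
the analysis chain hard to scrutinize. This package is for
epidemiologists and methodologists who want that entire chain —
screening rules, descriptive tests, estimator, permutation comparison,
bootstraps — as auditable code whose statistical behavior is verified
against planted truth.

## What is inside

* **Synthetic cohorts** (`synthetic_spec()`, `generate_cohort()`):
  latent Gaussian copula over the 16 GAD/PHQ items with a planted
  partial-correlation network (chain backbone plus four strong edges,
  including the cross-instrument GAD5–PHQ8 bridge), CTQ-SF items with
  per-subscale severity calibrated to a ~3.6% CSA screen rate, and
  demographics with realistic sex imbalances.
* **Screening** (`screen_cohort()`, `prevalence_ci()`): subscale sums,
  clinical cut-offs (sexual abuse >= 8, emotional abuse >= 13, physical
  abuse >= 10, physical neglect >= 10, emotional neglect >= 15), the
  comorbid-abuse exclusion, and Wald/Wilson prevalence intervals.
* **Descriptives** (`build_table_one()`, `chi_square()`,
  `pooled_t_test()`, `cronbach_alpha()`): Table-1 style sex
  comparisons with uncorrected Pearson chi-squares and pooled t-tests.
* **Network estimation** (`estimate_network()`, `graphical_lasso()`,
  `select_network()`): Spearman / Pearson / polychoric correlation
  input, graphical lasso (compiled coordinate descent) over a
  100-point penalty path, EBIC selection (gamma = 0.5) with
  pattern-constrained refits, partial-correlation conversion, and
  covariate-adjusted re-estimation with edge-wise comparison.
* **Centrality** (`centrality_table()`): expected influence, bridge
  expected influence across the anxiety/depression communities, and
  nodewise predictability (R-squared from the other 15 items).
* **Sex comparison** (`network_comparison_test()`): permutation test of
  global strength, maximum edge difference, and all 120 individual
  edges with Holm correction, re-running the full estimator inside
  every permutation.
* **Stability** (`bootstrap_edges()`, `case_drop_cs()`): percentile
  bootstrap CIs and pairwise edge-difference tests; case-dropping
  bootstrap with the CS-coefficient (max drop proportion keeping 95% of
  subsample centrality correlations >= 0.7).
* **Orchestration** (`run_config()`, `run_pipeline()`): one seeded
  configuration runs simulate → screen → describe → estimate →
  centrality → compare → stability and writes per-stage artifacts plus
  a hashed manifest. The numbered scripts under `analysis/` run the
  same stages as a narrative workflow writing under `results/`.

The model at the core: with correlation matrix S of the 16 items, the
graphical lasso maximizes `log det(Theta) - tr(S Theta) - lambda *
sum_{i!=j} |Theta_ij|`; the penalty is chosen by
`EBIC = -2 logL + E log n + 4 gamma E log p`, and edge weights are the
partial correlations `-Theta_ij / sqrt(Theta_ii Theta_jj)`. Centrality
uses the one-step signed sums `EI(i) = sum_j w_ij` and its
cross-community restriction bEI.

## Worked example

```r
library(symptomnet)

# a survey-scale cohort with planted truth, screened down to CSA cases
cohort <- generate_cohort(synthetic_spec(n = 96218, seed = 20211001))
scr <- screen_cohort(cohort)
scr
#> CSA screening: 3404 / 96218 positive (3.54%, 95% CI 3.42-3.65%); 3066 in analysis sample after comorbid-abuse exclusion

analysis <- cohort[scr$analysis_flag, ]
items <- symptom_items(analysis)
net <- estimate_network(items)
net
#> EBIC-glasso network: 16 nodes, 16 edges (lambda=0.0741, gamma=0.5, n=3066, spearman)

ct <- centrality_table(net, items)
head(ct[order(-ct$bei), c("node", "bei", "ei", "predictability")], 2)
#>  node       bei        ei predictability
#>  PHQ8 0.1273463 0.2779861     0.08993199
#>  GAD5 0.1273463 0.1370603     0.06231906
```

The screening line says 3.54% of the simulated cohort exceed the
sexual-abuse cut-off (the generator is calibrated to ~3.6%) and that
338 participants flagged for a second form of abuse were excluded. The
network line reports the EBIC-selected penalty and edge count — the 16
surviving edges are exactly the planted backbone-plus-bridges
structure, led by GAD2–GAD3 (0.186), PHQ3–PHQ4 (0.178), PHQ1–PHQ2
(0.159) and the cross-instrument bridge GAD5–PHQ8 (0.127). The
centrality rows show that same bridge dominating bridge expected
influence from both of its endpoints.

The full narrative analysis — descriptive Table 1, the
covariate-adjusted comparison, the male/female permutation test, and
the stability diagnostics — is the numbered scripts:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_screen.R
Rscript analysis/03_descriptives.R
Rscript analysis/04_network.R
Rscript analysis/05_sex_comparison.R
Rscript analysis/06_stability.R
```

Each prints what it found and writes tables under `results/`.

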