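---
title: "Methods: regularized symptom networks for comorbid anxiety and depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The scientific problem

Anxiety and depression co-occur at high rates among survivors of
childhood sexual abuse (CSA). The network approach to psychopathology
treats the two disorders not as latent diseases but as systems of
mutually reinforcing symptoms: each of the 7 GAD-7 anxiety items and 9
PHQ-9 depression items is a node, and an edge is the partial
correlation between two symptoms after conditioning on all other
symptoms. Symptoms that are strongly connected overall ("central") or
that connect the two instruments ("bridge" symptoms) are candidate
intervention targets.

This package re-implements that analysis pipeline end to end —
screening, descriptive comparison, regularized network estimation,
centrality, sex-stratified permutation comparison, and bootstrap
stability — and pairs it with a synthetic-cohort generator with known
ground truth, so that every estimator in the chain can be validated by
parameter-recovery experiments rather than by eyeballing plots.

## The generative model behind the simulator

The generator uses a latent Gaussian copula. Each participant has a
16-dimensional latent normal vector whose precision matrix encodes the
*planted* partial-correlation network; observed Likert responses arise
by cutting each latent score at fixed per-item thresholds. This is the
standard model under which rank-based and polychoric correlation
estimates of the latent structure are consistent, which is exactly what
makes recovery tests meaningful: the estimand is well-defined and known.

Concretely, for a planted partial-correlation matrix $P$ the latent
correlation matrix is $\Sigma = \mathrm{cov2cor}\left((I-P)^{-1}\right)$
(`partial_to_latent_correlation()`), which exists whenever $I-P$ is
positive definite; the default network is diagonally dominant by
construction, and any user-supplied matrix is checked at build time with
the offending eigenvalue reported.

Default study conditions, chosen once:

* **Planted network.** A chain backbone along the instrument ordering
  with weights spread over 0.10–0.20, plus four strong edges: GAD2–GAD3
  (0.30), PHQ1–PHQ2 (0.28), PHQ3–PHQ4 (0.26) within-instrument, and
  GAD5–PHQ8 (0.25) across instruments. The heterogeneous chain weights
  make rank-correlation recovery a discriminating check (a constant
  chain would leave the true ranking degenerate); the four strong edges
  mirror the kind of structure reported for this population.
* **Item thresholds.** For each GAD/PHQ item, category probabilities
  follow a geometric decay whose mean matches the published item means
  (e.g. 0.29 for the suicidal-ideation item, 1.01 for fatigue), mapped
  to latent cut-points through the inverse normal CDF. Item-level
  marginals for the source population are otherwise unpublished, so
  this is an approximate, not exact, calibration — the implied SDs come
  out close to the printed ones without being targeted.
* **CTQ-SF trauma items.** Generated independently of the GAD/PHQ latent
  structure (the network analyses run within the screened subsample
  only), with one shared factor per subscale (loading 0.6) so that
  abuse experiences are item-correlated within a subscale, plus a
  per-subscale severity shift. The sexual-abuse severity default
  (−0.68 on the latent scale) was calibrated by simulation so that
  roughly 3.6% of participants exceed the SA cut-off, matching the
  screening rate of the target population; other subscales sit at
  realistic 1.7–3.2% positive rates, which leaves ≈89% of SA-positive
  participants in the analysis sample after the comorbid-abuse
  exclusion.
* **Demographics.** Category probabilities per sex are taken from the
  published counts (e.g. only-child status: 56.8% of males vs 41.2% of
  females), so Table-1 style chi-squares on simulated data have
  realistic effect sizes. Female participants receive a +0.15 latent
  mean shift on all symptom items, reproducing the direction of the
  published sex difference in scale totals without altering the latent
  correlation structure.

What the generator does **not** emulate: item-level response styles
(acquiescence, careless responding), differential item functioning by
sex beyond a mean shift, longitudinal dynamics, missingness (an
injector exists but is off by default, since the target analysis
reports no missing-data handling), and — deliberately — the strong
general factor of real questionnaires. A sparse chain-plus-bridges
truth implies far lower inter-item correlations, total-score SDs and
Cronbach alphas than the ≈0.85–0.91 of real scales (simulated GAD-7
alpha comes out near 0.2, and the screened CTQ subsample can even show
negative alphas through selection effects); planting a dense general
factor would make it impossible to test sparse-structure recovery, so
the reliability functions are validated against closed-form fixtures
(parallel items, equicorrelated items) rather than against the
simulator. Passing recovery tests therefore
demonstrate estimator correctness under the copula model, not
robustness to every artifact of real survey data.

## Screening and descriptives

CTQ-SF subscale scores are plain item sums; the clinical cut-offs are
sexual abuse ≥ 8, emotional abuse ≥ 13, physical abuse ≥ 10, physical
neglect ≥ 10, emotional neglect ≥ 15. A participant enters the analysis
sample when flagged for sexual abuse and for *no other* subscale.
Prevalence is reported over all retained participants with every
SA-flagged participant in the numerator, before the comorbid-abuse
exclusion — the convention under which the published 3.62%
(95% CI 3.50–3.73%) reproduces exactly. The Wald interval is the
default because it reproduces those printed bounds to the last digit;
the Wilson interval (which differs in the upper bound by 0.01) is
available behind an argument. Reverse-keyed CTQ items are assumed
already keyed; the keying is the caller's responsibility and the scale
definition is configurable.

Group comparisons use the uncorrected Pearson chi-square — with the
Yates correction none of the five published statistics reproduce — and
the pooled-variance (not Welch) two-sample t. Cronbach's alpha uses the
classical variance-ratio formula.

## Network estimation

The estimator is the EBIC-selected graphical lasso on a correlation
input:

1. **Correlation input.** Spearman by default: the source analysis does
   not state its correlation input, and rank correlations are robust
   and fast for 4-category Likert items inside permutation loops. A
   two-step maximum-likelihood polychoric estimator (thresholds from
   marginal proportions, then per-pair likelihood maximization over the
   latent correlation) is available via the estimator config for users
   who want the latent-scale estimand; it is consistent under the same
   copula the simulator uses but roughly two orders of magnitude
   slower.
2. **Graphical lasso.** Block coordinate descent on the covariance
   estimate with an elementwise penalty matrix (compiled code). Only
   off-diagonal precision entries are penalized, so an identity input
   returns an identity precision matrix exactly. Convergence is
   declared when the average absolute change per sweep falls below
   `tol` times the mean absolute off-diagonal of the input (default
   `1e-4`, cap 1000 sweeps); stationarity conditions
   ($|S_{ij}-W_{ij}| \le \lambda$ on excluded edges, equality on active
   ones) are asserted in the test suite.
3. **Penalty selection.** 100 log-spaced penalties from
   $\lambda_{\max} = \max_{i\ne j}|S_{ij}|$ down to
   $0.01\,\lambda_{\max}$, scored by
   $\mathrm{EBIC} = -2\log L + E\log n + 4\gamma E\log p$ with
   $\gamma = 0.5$, the conventional default. The log-likelihood of each
   candidate is recomputed from an unpenalized maximum-likelihood fit
   constrained to the candidate's sparsity pattern (implemented as a
   glasso solve with a prohibitive penalty on the excluded entries), so
   that shrinkage does not bias model-size comparison; the *returned*
   network is the penalized estimate, converted to partial correlations
   via $w_{ij} = -\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. Ties in
   EBIC break toward the larger penalty, i.e. the sparser model. Edges
   are counted as nonzero above $10^{-10}$.

**Covariate adjustment.** The adjusted network replaces each item by
its least-squares residual on an indicator expansion of the covariates
(sex, family type, income band, only-child status) and re-estimates.
One subtlety is documented rather than hidden: residualization turns
integer items into continuous values, which breaks rank ties, so even
covariates orthogonal to all items perturb a *Spearman* network
slightly; under a Pearson input the adjusted network is identical to
the original in that case, and the equivalence test in the suite runs
under Pearson for exactly that reason. The original-vs-adjusted
comparison reports the Spearman rank correlation over the 120 edge
weights and a two-sample t-test (the independent-samples form, matching
how the comparison is conventionally reported; a paired variant is
available).

## Centrality and predictability

Expected influence is the one-step signed incident sum
$EI(i)=\sum_j w_{ij}$ — the definitional sentence in this literature
describes the sum of connected edge weights, and signed sums are the
appropriate index when negative edges exist. Bridge expected influence
restricts the sum to edges crossing the anxiety/depression community
boundary, so $EI = bEI + EI_{\text{within}}$ holds exactly; that
decomposition is fuzz-tested over 1000 random networks. Predictability
is the nodewise $R^2$ of each item regressed on the other 15 — a
transparent linear approximation of how much of a symptom its
neighbors account for (mixed-model variants used elsewhere in the
literature are not reproducible without the original data, and the
linear version is the testable one). On sparse planted-network cohorts
the mean predictability comes out low — around 6% at survey scale —
far below the ≈50% reported for real samples, for the same reason the
simulated alphas are low: a sparse truth carries much less shared
variance than real symptom data. Predictability is therefore validated
against its bivariate closed form (R² of a planted pair equals the
squared correlation) rather than against the published average.

## Sex comparison (permutation test)

Male and female networks are estimated with the same estimator config;
the test statistics are (a) the absolute difference in global strength
(sum of absolute edge weights), (b) the maximum absolute edge
difference $M$, and (c) every individual signed edge difference
(male − female). Null distributions come from re-estimating both
networks after permuting group labels across the pooled rows — the full
estimator, correlation input plus EBIC-glasso, runs inside every
permutation rather than any shortcut. P-values use the add-one
estimator $(1+\#\{\text{perm} \ge \text{obs}\})/(1+B)$, so they are
never exactly zero; under label exchangeability the test is exact. The
per-edge family is Holm-corrected across all 120 edges (every edge
weight is compared); a config flag restricts the family to edges
present in at least one group for users who prefer the narrower
family. The production default is 1000 permutations; calibration and
power experiments in the tests run at 100–200 permutations with a
10-point penalty grid, which leaves the type-I error of the global
strength test in the nominal range and detects a planted 0.25
edge-weight difference at n = 1000 per group.

## Stability diagnostics

Edge accuracy uses the nonparametric bootstrap: resample rows with
replacement, re-estimate, and report percentile 95% intervals per edge
plus a bootstrapped difference test for every pair of edges. Percentile
(not BCa) intervals are used, matching the plain bootstrap CIs the
methodology prescribes. One property worth knowing: for an
L1-sparsified estimator the bootstrap *mean* of an edge can fall
outside its own percentile interval (an edge that is zero in nearly
all replicates but occasionally large), so the suite asserts that the
bootstrap median sits inside the interval and that the intervals cover
the full-sample estimates for ≥90% of edges.

Centrality stability uses the case-dropping bootstrap: for each drop
proportion $q$ in 0.05–0.75 (step 0.05), correlate the full-sample
centrality ranking with the ranking in subsamples retaining a
$(1-q)$ fraction of cases (Spearman, matching "ranking correlation").
The CS-coefficient is the largest $q$ — required to hold for the whole
prefix of the grid — such that at least 95% of subsample correlations
stay at or above 0.7; 0.25 and 0.5 are applied purely as interpretive
labels ("unstable" / "acceptable" / "good"). Replicates that fail to
estimate are dropped and counted; grid points leaving fewer than
$p+2$ rows are skipped with a warning.

## Numerical choices and degenerate inputs

* Constant item columns abort correlation estimation naming the item;
  an item residualized to (numerical) zero by a covariate it equals is
  caught the same way downstream.
* Rank-deficient covariate designs drop aliased columns with a warning;
  singular predictability designs fall back to a tiny ridge.
* Zero-variance t-tests return $t=0, p=1$ when means agree and abort as
  degenerate otherwise; zero-margin contingency tables abort.
* All stochastic stages (generator, permutations, bootstraps) take
  explicit seeds and scope them with `withr::with_seed`, so pipeline
  runs are byte-reproducible and never disturb the caller's RNG state.
* The pipeline orchestrator derives fixed sub-seed offsets from the
  master seed and records them, with row counts after every filter and
  md5 hashes of every artifact, in `manifest.json`.

## Problem sizes used in the validation suite

Recovery experiments run at n = 2000–5000 (rank correlation ≥ 0.8
between true and estimated weights on the truly-nonzero edges; all four
strong edges recovered with the correct sign at n = 5000). Comparison
calibration uses 200 replications at 200 permutations with 400 rows per
group; power uses 25 seeds at 1000 rows per group. Stability
monotonicity compares CS at n = 5000 vs n = 500 over 10 paired seeds
with 50 subsamples per grid point on a 0.1–0.7 grid. These sizes were
chosen as the smallest at which the corresponding properties are
comfortably identified.

## Known limitations

* Spearman partial correlations on 4-category items are attenuated
  relative to the latent weights (the suite demonstrates this
  attenuation directly), so estimated edge weights are comparable
  across groups and samples but are not unbiased estimates of the
  latent partial correlations; the polychoric input removes most of
  the attenuation at substantial cost.
* The penalty, EBIC hyperparameter, and correlation input of the
  original analysis are unpublished, so its figures cannot be matched
  numerically; validation is by planted-truth recovery instead.
* Predictability is linear nodewise $R^2$, an upper-level proxy rather
  than the mixed-model estimator some published tables use.
* The NCT here implements the three invariance tests that are actually
  reported for this design (global strength, structure via $M$,
  individual edges); centrality-invariance subtests are out of scope.
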