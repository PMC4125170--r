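---
title: "Methods: cluster-conditional risk assessment for type 2 diabetes"
author: "diabrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cluster-conditional risk assessment for type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diabrisk)
```

## The model

`diabrisk` builds a four-tier risk assessment for type 2 diabetes from
cross-sectional cohort data. The construction has five stages.

**1. Variable selection.** Candidate variables are screened twice. Unpruned
C4.5 decision trees (binary gain-ratio splits, thresholds at midpoints of
sorted distinct values) are grown on five overlapping training sets — the
whole cohort, each sex, and the two age strata (< 50 and >= 50 years) — with
ten trees per set, one per cross-validation training fold. A variable is
tree-selected when it appears more than four times as a split variable
within the first eight tree levels, summed over all fifty trees. In
parallel, a multivariate logistic regression of the diabetes label on the
full pool retains variables with Wald p < 0.05. The final risk set is the
intersection of the two, plus declared expert overrides (HDL, a
well-established protective factor, is kept even when its p-value is above
the cutoff). Fasting glucose is deliberately excluded from the final set
however strong its evidence: its tree split thresholds are instead pooled,
binned to 0.05 mmol/L, and their modal value becomes the *absolute glycemia
criterion* (5.85 mmol/L when no glycemia split exists). The shipped default
risk set is the nine variables age, sex, BMI, waist, CHOL, TG, HDL, DBP and
family history (PSH).

**2. Partition.** The cohort is standardized on the risk variables (sample
SD, n − 1 denominator) and partitioned by k-means (Lloyd iteration,
k-means++ seeding with five restarts, deterministic given the seed).
Candidate cluster counts 2–7 are compared by the between-cluster R² and
Sarle's cubic clustering criterion (CCC); the selection rule admits k with
CCC ≥ 10 and takes the smallest admitted k with the largest R² increment.
Because CCC compares the observed R² with its expectation under a uniform
null over the principal-component hyperbox, it is systematically negative
for strongly correlated elliptical data, so on realistic cohorts no k may
be admitted; the rule then falls back to the k with maximal CCC and warns.
The shipped pipeline default is therefore a fixed k = 3, which is also the
count the selection rule produced on the original study population.
Clusters are relabelled by decreasing size, so cluster 1 is always the
largest ("general") group. New subjects are assigned to the nearest
centroid in standardized space.

**3. Cluster-conditional probabilities.** One maximum-likelihood logistic
regression of prevalent diabetes on the nine risk variables is fitted per
cluster (IRLS via `glm`), with Hosmer–Lemeshow calibration statistics
(decile-of-risk groups, dof = groups − 2) attached. A variable that is
constant inside a cluster — typically a binary variable the partition
separated on — carries no information there and is dropped from that
cluster's fit with coefficient zero.

**4. Relative risk and its cutoff.** Non-diabetic subjects are divided,
within each cluster, into 24 groups: twelve half-open five-year age bins
[20, 25), ..., [70, 75), [75, Inf) crossed with sex. The cluster's logistic
model evaluated at the group's *mean covariate vector* gives the group's
average onset probability P~0~ (the logit-at-means convention — not the
mean of individual probabilities; the two differ by the Jensen gap). A
subject's relative risk is RR = P~k~ / P~0~, with P~k~ their own modelled
probability and P~0~ that of their cluster–sex–age cell (empty cells fall
back to the nearest populated bin of the same cluster and sex, ties toward
younger). The RR cutoff is chosen from the ROC curve of RR against
prevalent diabetes as the operating point closest to the ideal corner
(0, 1); for pre-trained assessment runs it is a configuration constant
defaulting to the published 2.2.

**5. Four-tier stratification (CCRA).** Each subject passes a three-step
cascade: glycemia above the absolute criterion → **high** risk; otherwise
RR at or below the cutoff → **non** risk; otherwise the subject's degree —
the number of cluster-specific threshold criteria satisfied (for the first
cluster: BMI > 26.8 kg/m², CHOL > 5.18 mmol/L, TG > 1.7 mmol/L, all strict
comparators) — maps 3 → high, 2 → medium, 1 → low. The criteria of the
other clusters are unpublished; they are reconstructed as the cluster's
75th percentiles of BMI, CHOL and TG among non-diabetic members, shipped in
the model file tagged `derived`, and fully overridable. A degree of 0 with
elevated RR maps to low risk: the RR criterion alone already signals
elevated risk, and the alternative (non risk) would contradict the RR
cascade. Prevalent diabetics are flagged, scored, and excluded from
category counts.

## Validation instruments

**Jackknife.** Every subject is assessed by a model trained on the other
n − 1 subjects and scored against the category the full-data model assigns,
after collapsing tiers to three classes (non-risk; different-risk = low,
medium or high; diabetes for prevalent diabetics). The default refit mode
(`"logits"`) freezes the cluster partition and rule thresholds and refits
the per-cluster logistic models and the reference grid per fold — these are
the dominant source of leave-one-out variation; `"full"` mode retrains the
entire pipeline and is used in the small-cohort oracle tests. Failed folds
count as incorrect. A seeded subsample of folds (each still trained on
n − 1) estimates the same accuracy at reduced cost.

**Follow-up incidence.** Incidence by baseline category is cases per 1000
person-years with person-years = persons × years (complete follow-up: the
published rates are exactly cases/(n × 6) × 1000, which fixes this
convention). Confidence intervals are exact Poisson (Garwood) intervals on
the case count scaled to person-years; the source's own interval method is
unstated and matches no standard method we tested, so the Garwood choice is
documented rather than compared.

## The synthetic cohort generator

No public accession of the original 16,246-person cohort exists, so the
package ships a generator whose defaults are the study conditions:

* Per-sex means and SDs of age, BMI, waist, SBP, DBP, GLU, CHOL, TG and
  HDL as published for the model population; male fraction 8624/15237;
  PSH prevalence 13.73 % (men) / 17.8 % (women); baseline diabetes
  prevalence 1009/16246. Two values required judgement: LDL moments are
  not published (we assume 2.95 ± 0.85 / 3.05 ± 0.90 mmol/L), and the
  published per-sex GLU SDs (1.27/1.20) are inconsistent with the total
  column (0.62) and with the follow-up subset (0.62/0.61) of the same
  table — a per-sex SD twice the pooled SD is impossible — so the
  generator uses 0.62/0.61.
* Covariates are drawn per sex from a multivariate normal with an assumed
  correlation matrix (BMI–waist 0.8, SBP–DBP 0.7, TG–HDL −0.4,
  CHOL–LDL 0.85, the rest modest, |r| ≤ 0.35); the source publishes only
  marginal moments, so this structure is a declared assumption, editable
  through `cohort_spec()`.
* Three latent subpopulations (mixing 0.55/0.25/0.20) displace the means:
  cluster 2 is older with higher blood pressure and glucose, cluster 3
  carries elevated adiposity and lipid values. Displacements are re-centred
  so marginal means are preserved.
* Values below physiologic floors (age 20 y, GLU 2.5 mmol/L, BMI 13, ...)
  are resampled from the left-truncated normal by inverse CDF, and the
  underlying location of each (variable, component) is pre-adjusted so the
  truncated mean still matches the target. Resampled entries lose their
  correlation with the other coordinates — a deliberate trade: exact
  marginal moments at slight correlation attenuation for the few affected
  coordinates (mainly TG).
* Prevalent diabetes combines the diagnostic rule (GLU > 7.0 mmol/L) with
  a Bernoulli draw from a logistic risk process on standardized
  covariates; its intercept is recalibrated by root finding so the
  marginal prevalence matches the target. The six-year incident process
  reuses the same coefficients with its own intercept calibrated to 4.5
  cases per 1000 person-years.
* One integer seed drives everything; stage sub-streams are derived by
  fixed offsets, so cohorts are byte-identical across runs.

What the generator does **not** emulate: skewed or heavy-tailed lipid
distributions (real TG is approximately log-normal), nonlinear
age–risk profiles, measurement error, missing data, loss to follow-up, and
the strong higher-order dependence between impaired fasting glucose and
adiposity seen in real populations (see below). Passing tests on this
cohort therefore demonstrate correctness of the procedures, not clinical
performance; the published headline numbers (AUC 0.808, sensitivity 0.794,
specificity 0.679, jackknife 90.99 %, the exact category distribution)
are properties of the unavailable cohort and are not reproduction targets.

## Numerical choices

* Gain-ratio ties are broken by variable name order, then smaller
  threshold; leaf-label ties go to the non-diabetic class. Splits need
  positive information gain, at least 25 records per child (configurable)
  and depth ≤ 12 (root = 1): unpruned trees on continuous data are
  otherwise unbounded.
* The age boundary "under / above 50" is the half-open partition
  age < 50 / age ≥ 50; age 50 itself belongs to the older stratum.
* The two printed tree-frequency thresholds ("higher than five" in the
  methods, "higher than four" in the results) disagree; the default is 4,
  configurable.
* Logistic fits converge on a deviance tolerance of 1e-8; quasi-separated
  fits (separation warning plus |beta| > 15) raise an error naming the
  offending variable.
* k-means uses five k-means++ restarts (best within-SS kept); empty
  clusters are re-seeded from the farthest point. During k-range scans
  the nested refinement of the previous solution is also tried and kept
  when it explains more variance, which makes R² provably non-decreasing
  in k.
* CCC follows the SAS Technical Report A-108 formulation: eigenvalues of
  the covariance supply the hyperbox edges, p* is the largest dimension
  whose scaled edge is at least 1, and the variance-stabilized log ratio
  of (1 − E(R²)) to (1 − R²) is scaled by sqrt(n p*/2)/(0.001 + E(R²))^1.2.
* Hosmer–Lemeshow strata with zero expected events (or zero expected
  non-events) are merged upward with a message.
* RR is computed and stored as an exact ratio; it is invariant under
  affine recoding of any covariate with correspondingly transformed
  coefficients (a tested property).
* ROC ties are grouped into a single threshold step; the cutoff ties
  break toward higher specificity.

## Design choices on genuinely open points

* Whether the "10-fold cross validation without pruning" yields ten trees
  per sub-cohort (frequency counting over all fifty trees) or one tree
  with CV only for error estimation is ambiguous; the default is the
  ten-tree reading, which is the only one that makes the printed
  frequencies (> 4 over the first eight levels) attainable.
* Diabetics are included when fitting the per-cluster logits and when
  clustering (both described over the full cohort), but excluded from the
  reference grid (described over the 15,237 non-diabetics). The mixture is
  unusual but both statements are honoured as written.
* The CHOL-by-sex product variable appears in the selection narrative but
  not in the printed nine-variable model; it ships as an expert override
  of the selection report only, and is excluded from the default model
  variables.
* Person-years ignore attrition, as the published rate arithmetic does.

## Problem sizes used by the tests and the acceptance script

The test suite works at n = 30–2,500 subjects for pipeline-level checks and
n = 20,000–50,000 for distributional recovery checks of the generator. The
acceptance script builds one 8,000-subject cohort, runs selection (50
trees), trains the model, and evaluates 400 seeded leave-one-out folds,
each trained on the other 7,999 subjects. These sizes are the package's
default demonstration scale; every stage accepts arbitrary cohort sizes.

## Known limitations

* The stratification reproduces the published *procedure*; cohort-specific
  numbers depend on the data. On the synthetic default cohort the mean
  GLU rises strictly across the four tiers, but BMI, waist and TG can
  invert between the medium and high tiers: the high tier is dominated by
  the absolute glycemia override, and with modest Gaussian glucose–
  adiposity correlations (0.2–0.3) glycemia-flagged subjects carry only
  moderately elevated BMI/TG, while the medium tier is selected directly
  on BMI/CHOL/TG exceedances. The fully monotone published pattern implies
  an effective glucose–adiposity dependence near 0.5 in the real cohort —
  a higher-order association the Gaussian copula deliberately does not
  impose.
* CCC ≥ 10 is rarely attainable on correlated data (see above); treat the
  selection rule's fallback warning as expected on realistic cohorts.
* The jackknife on the synthetic cohort is near-perfect (fold models
  barely differ from the full model at these sizes); it validates the
  bookkeeping and stability, not the published 90.99 %.
* Derived cluster rules are reconstructions, clearly tagged; replace them
  with clinically chosen thresholds for any real application.

## A worked example

```{r example, eval = FALSE}
spec <- cohort_spec(n_subjects = 6000, seed = 42)
cohort <- generate_cohort(spec)
model <- train_risk_model(cohort, pipeline_config(seed = 42))
model
strat <- stratify_cohort(cohort, model)
strat$counts

followup <- generate_followup(cohort, spec)
a <- strat$assessments
keep <- !a$prevalent_diabetes
incidence_table(data.frame(id = a$id[keep], category = a$category[keep]),
                followup[followup$id %in% a$id[keep], ])
```
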