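---
title: "From EHR cohort to comorbidity communities: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From EHR cohort to comorbidity communities: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electronic-health-record (EHR) extracts for a chronic disease such as
type 2 diabetes arrive as a wide patient-by-variable matrix: thousands
of records, hundreds of mostly dichotomous diagnosis and medication
indicators, a handful of demographics, and a binary disease label. Two
things make such matrices awkward for direct modelling: heavy
redundancy/collinearity among the indicators, and the fact that a flat
list of "predictive variables" hides how those variables co-occur
within patients. `ehrnet` implements a pipeline that (i) prunes the
matrix to a complete binary analysis matrix, (ii) selects predictive
variables by two independent arms, (iii) scores the survivors in one
joint logistic regression, and (iv) replaces the flat list by a
mutual-information (MI) network over the diseased subpopulation whose
modularity communities group comorbidities and risk factors.

## Synthetic cohorts and what they do (and do not) emulate

The kind of patient matrix this pipeline targets is typically not
redistributable, so the package ships a seeded generator
(`cohort_spec()` / `generate_cohort()`) producing cohorts with the
statistical structure the downstream stages assume, plus ground truth
for recovery testing:

* **Correlated blocks.** Each block (a comorbidity or risk-factor
  cluster) is driven by a shared latent Bernoulli factor; every feature
  equals the factor flipped with probability $\varepsilon$. Given a
  target marginal prevalence $p$ the latent prevalence is
  $\pi = (p - \varepsilon)/(1 - 2\varepsilon)$, and the within-block
  pairwise odds ratio is a monotone function of $\varepsilon$ ranging
  from $\infty$ (no noise) to 1 (pure noise), so a bracketed root
  search sets $\varepsilon$ to hit any requested odds ratio $\ge 1$.
  This is the simplest mechanism giving tunable pairwise association
  among binary features.
* **Outcome model.** A logistic model
  $\operatorname{logit} p_i = \beta_0 + \sum_j \beta_j x_{ij}$ over any
  named features; the nonzero-$\beta$ set is the planted predictive set.
* **Demographics.** Age uniform on 18–76 (integer), sex Bernoulli(0.5)
  with 1 = male, BMI lognormal around 27 (sd of log 0.18, rounded to
  one decimal as a real EHR would store it) so that all four weight
  categories are populated.
* **Nuisance structure.** Independent noise features with prevalences
  drawn on (0.02, 0.30), near-duplicate columns (2% flip noise) mimicking
  redundant variables, and completely-at-random missingness.

Not emulated: ICD code semantics, longitudinal visit structure,
informative missingness, and real-world confounding between
demographics and diagnoses. Passing recovery tests on these cohorts
therefore demonstrates that the machinery works when its assumptions
hold; it does not certify performance on any particular hospital's
data.

One caveat worth knowing when designing recovery experiments: because
the network stage conditions on the diseased subpopulation, any two
variable groups that both influence the outcome become associated
*within cases* (collider conditioning), so weak between-block edges in
a case-only network are a property of the model, not a bug.

`study_cohort_spec()` fixes a reference configuration whose curated
matrix is 8,482 records by 286 binary variables at roughly 20% outcome
prevalence — the scale of a mid-size single-centre extract — used by
the end-to-end smoke test and the `analysis/` scripts.

## Curation

`apply_curation()` executes a fixed drop order: records with excluded
outcome labels (e.g. type 1 diabetes in a type 2 study); records aged
at or below `min_age` (default 18); explicitly excluded variables;
variables whose missing fraction — computed after the record drops —
exceeds `max_missing_fraction` (default 0.5, the regime in which a
smoking-style variable missing in over half the records is excluded);
then declared dichotomisations and the BMI expansion; finally
complete-case record removal. Every drop is written to a ledger
(kind, id, reason) so that records-in equals records-out plus ledger
drops. Complete-case handling closes a gap the upstream rules leave
open — both selection arms need complete predictors — and is the one
genuinely discretionary step; the ledger makes its cost visible.

BMI categories are half-open intervals $[0, 18.5)$, $[18.5, 25)$,
$[25, 30)$, $[30, \infty)$ (underweight, normal, overweight, obese).
Published range notations for these categories usually leave slivers
such as 24.99–25 undefined; half-open intervals make the map total
while agreeing with the conventional labels everywhere else.

## Feature selection

**Random-forest arm.** Two forests (default 500 trees, $\sqrt p$
candidate variables per split, no depth limit — standard defaults)
produce per-variable mean decrease accuracy (MDA: the average rise in
out-of-bag misclassification error after permuting the variable) and
total Gini-impurity decrease. Both importance distributions are cut by
the boxplot-notch rule: a variable is selected when its importance
exceeds

$$\mathrm{median} + 1.58 \cdot \mathrm{IQR}/\sqrt{n},$$

the upper bound of the boxplot notch (an approximate 95% confidence
bound for the median), with $n$ the number of values. By default a
variable survives if it passes on *either* measure (union rule;
intersection is available). Two properties of this rule matter in
practice: it is scale-equivariant, and it is **liberal** — the
threshold sits only $1.58/\sqrt n$ IQRs above the median, so with
hundreds of variables a substantial fraction of null importances
exceeds it. It reliably retains true signal but does not control false
selections; treat the RF-selected set as a recall-oriented screen whose
purification happens at the node-scoring stage.

**Lasso arm.** L1-penalised logistic regression (the binary-outcome
form of the least-squares-plus-L1 objective; the squared-error form is
available behind `family = "gaussian"`), penalty chosen to minimise
10-fold cross-validated deviance on the training fraction, intercept
unpenalised. Selected variables are the nonzero coefficients at that
penalty. The deviance-minimising penalty likewise trades some false
inclusions for recall; a stricter penalty can be forced via the
`lambda` argument.

Both arms fit on a seeded 70% training split and report accuracy,
precision, recall (probability threshold 0.5, ties to class 0) and
midrank ROC AUC on the held-out 30%.

The misclassification loss is implemented as the overall misclassified
fraction; region-indexed weightings of the same quantity reduce to this
aggregate for the metrics reported here.

## Node scoring

All variables selected by an arm enter **one** multivariable logistic
regression (IRLS, relative deviance tolerance $10^{-10}$, max 100
iterations); each node's score is the Wald $z$ = coefficient / SE and
nodes with two-sided $p < 0.05$ (configurable) enter the network, node
size $\propto |z|$. A joint rather than marginal fit is used because
the variables were selected together and their mutual adjustment is
the point of the step. Perfect separation and aliasing are *flagged*
(scores reported missing, with a warning) rather than silently
regularised; constant columns are dropped with a warning. No
post-selection-inference correction is applied — the $z$-scores are
descriptive node weights, and their null calibration is verified only
in the no-selection setting.

## The MI network

Over the case (outcome-positive) records only — configurable — every
pair of nodes is scored by the plug-in mutual information of its
empirical 2×2 table (natural log; zero-probability cells contribute 0;
bits behind a flag). Edge significance is Monte-Carlo: `B` uniform
permutations of one variable (default 999), add-one estimator
$p = (1 + \#\{MI_{perm} \ge MI_{obs} - 10^{-12}\})/(B+1)$, so $p$ is
never zero and ties count conservatively. Because only the 1/1 cell of
the table varies under permutation, the null MI values are taken from
a precomputed lookup over that cell's attainable range, making the
$\binom{p}{2}$ edge tests cheap. The per-edge p-values are adjusted by
Benjamini–Hochberg across all tested pairs (the multiplicity over
$\sim p^2/2$ tests is real even though each test is exact;
Bonferroni/none are available), and an edge is retained only if the
adjusted $p$ beats `alpha` **and** at least `min_patients` (default 15)
patients are positive for both endpoints — the patient floor keeps
edges interpretable as actually-shared morbidity. Nodes carry the male
fraction among node-positive patients for sex-prevalence display.

The conservative tie handling means reported p-values are uniform only
on each pair's attainable grid; the calibration test accounts for this
with the randomized ("fuzzy") p-value transform.

## Communities

`fast_greedy()` is an agglomerative Clauset–Newman–Moore-style
maximiser of Newman modularity
$Q = \sum_c (e_{cc} - a_c^2)$: start from singletons, repeatedly merge
the connected community pair with maximal $\Delta Q = 2(e_{ij} - a_i
a_j)$, and cut the recorded dendrogram at the modularity maximum.
Exact ties in $\Delta Q$ (within $10^{-12}$) are broken by the
lexicographically smallest community-id pair, making runs fully
deterministic where the textbook algorithm leaves ties open.
MI-weighted modularity is the pipeline default — the edge weights carry
the association strength — with unweighted counts behind a flag;
disconnected graphs agglomerate per component under one global cut.
`brute_force_best_partition()` enumerates all set partitions (Bell
numbers; refused above 10 nodes) as an independent optimality oracle:
greedy $Q$ can never exceed it, and on separable fixtures (clique
pairs, clique rings) it attains it exactly. On dense unstructured
graphs the greedy optimum may fall short of the exhaustive one — the
known behaviour of greedy modularity search.

## Orchestration and reproducibility

`run_pipeline()` chains the stages from a single `run_config()`. One
master seed deterministically derives per-stage seeds (stage-name
salted, so adding a stage never perturbs earlier ones); all tabular
outputs are CSV with doubles at 6 significant digits, networks are
GraphML, and a JSON manifest records stages, parameters, seeds and the
md5 of every artifact. Two runs of the same configuration are
byte-identical, which the test suite asserts at full study scale.

## Problem sizes used by the tests

The suite exercises: generator calibration at 4,000–10,000 records;
permutation-null calibration with 500 independent pairs ($n = 300$,
$B = 200$); community recovery on ten seeded cohorts (two 8-feature
blocks at within-block odds ratio 8, 50 noise features, $\ge 500$
cases, $B = 999$); selection recovery on ten cohorts of 5,000 records
with 15 planted predictors among 200 features (forests of 200 trees
here; importance rankings stabilise well below the 500-tree default);
node-score null calibration with 200 replicates at $n = 10{,}000$; and
one full pipeline run, twice, at the 8,482 × 286 reference scale with
$B = 199$ edge permutations. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities at the sizes
recorded in its output.

## Known limitations

* The boxplot-notch selector controls recall, not false selections;
  with many variables its false-selection fraction is high by
  construction (see above), and the same holds more mildly for the
  CV-deviance lasso penalty. The significance filter at the
  node-scoring stage is what prunes the network's vertex set.
* Plug-in MI is biased upward at small case counts; the permutation
  test, not the MI magnitude, carries the inferential weight.
* Case-only conditioning induces associations between independently
  generated predictive groups (collider effect); interpret
  between-community edges accordingly.
* Greedy modularity is a local optimiser and the resolution limit of
  modularity applies; the brute-force oracle guards correctness only
  at toy scale.
* The generator's missingness is completely at random; informative
  missingness would require a different curation strategy than
  complete-case analysis.
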