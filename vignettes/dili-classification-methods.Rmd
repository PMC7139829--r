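---
title: "Modeling drug-induced liver injury from molecular descriptors: methods and design choices"
author: "diliqsar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug-induced liver injury from molecular descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diliqsar)
```

## The problem

Drug-induced liver injury (DILI) is a leading cause of drug withdrawals and
boxed warnings, and it is poorly predicted by cell-culture or animal models.
QSAR (quantitative structure-activity relationship) classifiers attempt to
predict DILI concern directly from the chemical structure, encoded as a table
of numeric molecular descriptors (mean atomic polarizability, hydrogen
percentage, autocorrelation indices, logP, and so on). The reference
annotation for this task is the FDA's DILIrank list, which assigns each of
1036 drugs one of four concern categories: *Most*, *Less*, *No* and
*Ambiguous* DILI concern.

`diliqsar` implements the full modeling pipeline around such data: label
collapsing, descriptor preprocessing, chemical-diversity assessment, filter
feature selection, nested cross-validation over a grid of learners, model
selection by balanced accuracy and positive predictive value,
y-randomization, ensemble stacking (majority vote, pooled probabilities,
meta-models), virtual screening of external libraries, and outlier /
applicability-domain diagnostics.

Descriptor computation itself is out of scope: descriptor tables (typically
produced by commercial software from 2-D structures) are consumed as CSV
inputs. So that every stage of the pipeline is testable without such
software, the package ships a synthetic-data generator that emulates the
statistical structure of a real descriptor table.

## Data model

The central container, `DescriptorSet`, extends `SummarizedExperiment`:
descriptors are rows, compounds are columns, the per-descriptor kind
(continuous or binary) lives in `rowData`, and compound metadata — name,
concern category, the collapsed binary label, maximum daily dose, treatment
duration, exclusion flags — lives in `colData`. `descriptorMatrix()` exposes
the compounds-by-descriptor orientation that learners expect. Preprocessing
reports and fitted normalization parameters accumulate in `metadata()`, so a
single object carries everything needed to transform a screening library
consistently with its training set.

Labels collapse as the annotation intends: *Most* and *Less* concern form the
positive class (label 1), *No* concern the negative class, and *Ambiguous*
compounds — an expression of annotation uncertainty, not an outcome — are
excluded. Exclusions of biologics, mixtures and simple inorganics are
case-by-case judgment calls, so `readDilirank()` takes them as a
user-supplied list rather than hard-coding them.

## Preprocessing

Three cleanup rules are applied, in order, before any modeling:

1. **Quasi-constant filter.** A descriptor is dropped when fewer than 1% of
   its values differ from its statistical mode. For continuous data the mode
   is defined as the most frequent exact value, ties broken by the smallest
   value — real-valued descriptor tables contain many repeated exact values
   (counts, indicator-like descriptors), which makes this well defined.
2. **Auto-correlation filter.** Scanning columns in table order, each
   retained column removes every later column with `|Pearson r| > 0.9`
   (pairwise-complete observations). Keeping the *earlier* column makes the
   result deterministic; which member of a correlated pair survives is
   otherwise arbitrary, and only the kept-column count is order-invariant.
3. **Normalize and cap.** Continuous descriptors are z-scored and clipped to
   ±2 SD; binary descriptors pass through. The fitted means and SDs are
   retained, and external tables are transformed with the *training*
   statistics. Capping at transform time deliberately bounds every external
   compound into the training cube — this is the mechanism that keeps the
   applicability domain broad for screening, at the cost of compressing
   genuinely extreme chemistry onto the boundary.

Missing descriptor values are imputed with the column median (binary: mode)
after filtering; correlations are computed on pairwise-complete observations.
A caveat worth stating: these filters are fit once, globally, before
cross-validation, which mirrors common practice but is mildly optimistic;
feature *selection*, by contrast, runs strictly inside the outer training
sets (below).

## Chemical diversity

Diversity of a modeling set is summarized with the rescaled Gower
dissimilarity, appropriate for mixed continuous/binary descriptors:
per-column contributions are `|xi - xj| / range` for continuous columns
(range over the whole table) and simple mismatch for binary columns,
averaged over jointly observed columns, then divided by the observed maximum
so distances span exactly [0, 1]. Binary columns use symmetric simple
matching (not Jaccard), since absence of a fragment is as informative as
presence for toxicity. Two properties are worth noting: the rescaled Gower
dissimilarity need not satisfy the triangle inequality, and a pair with no
jointly observed columns is an error rather than a silent zero.

## Feature selection

`scoreFeatures()` exposes thirteen filter methods under one contract (named
scores, higher is better, deterministic name-broken ranking): ANOVA F, rank
AUC, Kruskal-Wallis, variance, chi-squared, information gain, gain ratio,
symmetrical uncertainty, OneR, ReliefF, random-forest permutation and
impurity importance, and a univariate resampled tree score. Choices the
underlying literature leaves open were fixed as follows:

* Entropy/contingency scorers discretize continuous descriptors into 5
  equal-frequency bins — the scale-free choice, and the one that keeps these
  filters invariant to monotone descriptor transforms at the bin boundaries.
* Relief is the ReliefF variant: 10 neighbors, all instances,
  range-normalized differences, prior-weighted misses.
* The several forest-based importance variants found in practice are
  collapsed into one permutation-importance and one impurity-importance
  entry over a 200-tree forest; the registry is the extension point if a
  one-to-one census is wanted.
* `variance` is unsupervised; it is the one registered filter for which "a
  perfect separator ranks first" cannot hold, and tests treat it
  accordingly.

`topFeatureFrequency()` reproduces the standard "how often does a descriptor
make a method's top 5" table, reporting by default only descriptors that
occur at least twice. Sign of a descriptor's contribution can be read from
the difference of class means of the selected descriptor.

## Nested cross-validation

Generalization is estimated with nested (double) cross-validation: 10
stratified outer folds estimate performance, 5 inner folds tune. For each
outer fold, feature selection to `nFeatures` (default 50) descriptors and a
bounded random hyperparameter search (default 20 draws, maximizing inner
balanced accuracy) run on the outer-training compounds only; the winner is
refit on the full outer-training set and predicts the held-out fold. Folds
are stratified by label — with a 64/36 class split this stabilizes
fold-level PPV. Both pooled and fold-averaged metrics are reported; they
agree only under equal fold composition, and a test pins a counterexample.

Learners are pluggable third-party implementations behind one
`fit`/`predict`/`sample` interface: logistic regression, elastic net, CART,
random forest, SVM (linear/radial/sigmoid), kNN (k tuned over 1-30), naive
Bayes and a single-layer neural network. The kNN entry converts the winning
vote fraction into a positive-class probability; all others emit calibrated
or raw probabilities directly. A learner failing on a fold is recorded and
skipped; more than two failed folds mark the model invalid.

Model selection is deliberately strict: a model enters the ensemble only if
pooled out-of-fold BA **and** PPV both exceed 0.70 ("higher than", so exact
boundaries fail).

**y-randomization.** Labels are permuted uniformly (preserving class
counts), the whole pipeline is rerun, and the exercise repeats (default 10
times) cycling through the supplied model specifications. Genuine models
must beat every scrambled run, whose BA should hover near 0.5.

## Ensemble stacking

Three schemes combine the selected models' out-of-fold predictions:

* **Majority vote.** Toxic iff at least half of the models vote toxic. The
  exact-tie convention (tie → toxic), like the `>= threshold` convention for
  pooled probabilities, is precautionary: the costlier mistake is labeling a
  hepatotoxic compound innocuous.
* **Pooled probabilities.** Mean or median across models, thresholded at 0.5
  (or 0.67 — raising the threshold trades sensitivity for specificity
  monotonically, and never increases the toxic count).
* **Meta-models.** A second-level learner (random forest by default; SVM,
  kNN, naive Bayes and CART are the usual alternatives) trained on the base
  models' out-of-fold prediction columns, optionally augmented with log dose
  and treatment duration. Columns are chosen by the same filter registry
  applied to the prediction matrix. Because the feature matrix contains only
  out-of-fold predictions, the meta-model inherits the leakage guarantee.
  Its performance is estimated by a fresh stratified 10-fold CV, repeated
  over seeds and reported as mean ± SD — the evaluation protocol here is a
  design choice, since stacking literature leaves it open.

For screening, `freezeEnsemble()` refits each selected specification once on
the full training set (selection rerun globally, hyperparameters tuned by a
single stratified inner CV), and `screenLibrary()` transforms the external
library with the training normalizer, pools per-model probabilities (both
mean and median are always reported) and ranks compounds by ascending pooled
probability — the head of the ranking is the candidates most confidently
predicted free of liver toxicity.

## Outliers and applicability domain

Training-set outliers are scored with an isolation forest (100 trees,
subsample 256, the standard `2^(-E[h]/c(psi))` score) and with subspace
outlier detection (SOD: shared-nearest-neighbor reference sets of size 10,
variance-selection factor 0.8, flagging the top 5% of scores). Outliers are
reported, never removed: a compound misclassified by most models is not
thereby an outlier, and `misclassifiedAudit()` makes exactly that
distinction inspectable.

The applicability domain of screening compounds is assessed three ways, all
on Euclidean distances over the normalized-capped table:

* **kNN thresholds** (three-stage): each training compound gets a local
  threshold (mean distance to its k nearest neighbors, k defaulting to
  `ceiling(sqrt(n))` for cheap deterministic behavior); a test compound is
  in-domain iff it is within at least one training compound's threshold.
* **INFLO**: density ratio between a compound and its influence space (kNN
  plus reverse-kNN).
* **COF**: chaining-distance ratio, separating "isolated" from merely
  "sparse but connected".

INFLO/COF in/out cutoffs are not standardized; the default is 1.2, the raw
scores are always reported, and the cutoff is a parameter. One subtlety the
package documents explicitly: deleting a training compound and *refitting*
the kNN thresholds can enlarge the in-domain set (the survivors' k-th
neighbors move outward, inflating their local thresholds). The intuitive
"deletion only shrinks the domain" monotonicity holds when thresholds are
held fixed, which `adKnnThreshold(thresholds = ...)` supports and the test
suite asserts in that form.

## The synthetic-data generator

`generateDescriptors()` draws a labeled descriptor table with the features
the pipeline's assumptions care about: informative columns as Gaussians with
a class-mean shift of `effectSize` SD units; pure-noise columns (every third
one log-normal, so the ±2 SD capping is exercised by heavy tails);
quasi-constant columns (0.5% of values off the mode — strictly inside the 1%
rule); redundant columns constructed to have sample correlation *exactly*
`rho` (default 0.95) with a source column; Bernoulli binary descriptors; a
log-normal dose with an additive class effect on the log scale (toxic
compounds get higher doses, reflecting the dose-dependence of intrinsic
DILI); and optional label noise. The default positive fraction, 0.64,
mirrors the 447/694 concern/no-concern composition of the curated DILIrank
modeling set. Since no generative model for real descriptor tables exists,
any structure satisfying these invariants is acceptable; Gaussian shifts are
the transparent choice.

What passing on synthetic data does **not** show: real descriptor blocks are
highly structured (thousands of correlated descriptors in families),
class-conditional distributions are not Gaussian, and effect sizes are far
from uniform across descriptors. Synthetic results validate the machinery —
leakage safety, calibration of the null, monotonicities, bookkeeping — not
the attainable accuracy on real drugs.

`syntheticDilirank()` similarly builds a stand-in for the DILIrank download
(1036 rows, the published 192/287/312/254 census, invented names and
placeholder SMILES) so the parser and label collapsing are testable offline;
its compounds are not real drugs.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline at
n = 600-694 compounds and p ≈ 200 descriptors with three fast learners
(logistic, kNN, CART), 10 × 5 nested folds, and 5-10 y-randomization
repeats — sizes chosen so the whole exercise reproduces in minutes on one
core while keeping the Monte-Carlo bands of the null (BA within [0.44, 0.56]
at n = 600) meaningful. Ties are broken deterministically everywhere
(descriptor name in rankings, column order in the correlation filter, index
order in neighbor sets); all stochastic steps derive their streams from a
single seed; distances use a 1e-12 floor where a zero k-distance would
otherwise divide by zero. Degenerate inputs (empty classes, all-constant
tables, compounds with no jointly observed descriptors, zero available
probabilities) raise errors with the offending names rather than propagating
silent zeros.

## Worked example

```{r example, eval = FALSE}
library(diliqsar)

x <- preprocessDescriptors(generateDescriptors(synthConfig(
  nCompounds = 300, nInformative = 12, nNoise = 60, effectSize = 1.5,
  seed = 1)))
plan <- makeFoldPlan(compoundLabels(x), outer = 10, inner = 5, seed = 2)
specs <- list(modelSpec("logistic", "anova_f", nFeatures = 30, seed = 3),
              modelSpec("knn", "kruskal_wallis", nFeatures = 30,
                        nSearchDraws = 10, seed = 4))
res <- runModelGrid(x, specs, plan)
stackModels(res, "pooled_prob", stat = "median")$summary
yRandomization(x, specs, repeats = 3, seed = 5,
               genuine = lapply(res, `[[`, "pooled"))
```

## Known limitations

* Real descriptor software (and hence real DILIrank performance) is outside
  the package; reported numbers on synthetic data characterize the pipeline,
  not hepatotoxicity prediction accuracy.
* The quasi-constant/auto-correlation filters are global (not per-fold), a
  mild optimism shared with common practice.
* The learner registry covers the standard families available in the
  environment; boosted trees, Bayesian additive trees and rotation forests
  are natural extensions behind the same interface.
* AD thresholds for INFLO/COF are conventions, not calibrated quantities;
  treat the raw scores as the primary output.
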