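---
title: "Phylogenetically blocked prediction of binary genomic features from trait tables"
author: "phyloTraitML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetically blocked prediction of binary genomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloTraitML)
```

## The problem

Comparative questions of the form *"which lifestyle traits predict whether a
microbial genome carries feature X?"* (here, prototypically, the CRISPR
adaptive immune system) face two obstacles at once. First, large trait
databases are text-mined: each species × trait cell carries a *pair* of
confidences — that the species does (`c+`) and does not (`c-`) have the trait
— rather than a clean 0/1 call, and many cells are missing outright. Second,
species are not independent observations: close relatives share both traits
and genomic features through common descent, so a naive cross-validation or a
random train/test split systematically overstates predictive ability.

phyloTraitML packages one coherent answer: derive a single score per cell,
impute the gaps, and then make every model-fitting and model-assessment step
*phylogenetically blocked*, so that errors are estimated across deep
evolutionary splits rather than between cousins.

## From confidence pairs to an analysis-ready matrix

The score combines the relative confidence with the overall confidence:

$$p = \frac{1}{2} + \left(\frac{c_+}{c_+ + c_-} - \frac{1}{2}\right)\,
\max(c_+, c_-).$$

It is 1 when presence is certain, 0 when absence is certain, and it shrinks
toward 0.5 — "no information" — as the larger of the two confidences shrinks.
The pair (0, 0) is formally 0/0; we define it as 0.5, consistent with that
limit. `deriveScore()` implements the formula, `scoreTable()` applies it to a
`ConfidenceTable`, preserving missing cells.

Missing scores are imputed by `imputeMissing()` with an iterative
random-forest scheme: initialise missing cells at column means, sweep columns
in order of increasing missingness, regress each incomplete column on all the
others with a regression forest (100 trees), overwrite its missing cells with
predictions, and stop at the first sweep where the normalised squared change
of the imputed cells increases (or after `maxIter = 10` sweeps), returning
the pre-increase state. Scores are treated as continuous throughout —
imputation happens before any thresholding — and observed cells are never
altered. The forest size is a quality/runtime compromise; imputation accuracy
on held-out cells, not any particular hyperparameter, is the contract, and the
test suite checks that the scheme beats column-mean imputation on
phylogenetically structured traits.

`dropTraits()` removes trait families by literal name substring (the typical
use being removal of machine-derived summary traits and growth-substrate
traits for interpretability), after imputation so that dropped columns still
inform the fill-in of retained ones.

## Blocked folds from the tree

`makeBlockedFolds()` clusters the patristic distance matrix (path-length
distance between tips, `patristicMatrix()`) with k-medoids into `k = 5` folds
by default. The PAM implementation (`pamCluster()`) is the classic BUILD +
SWAP algorithm made fully deterministic: every tie — in BUILD gains, SWAP
improvements, and nearest-medoid assignment — is broken by smallest index.
We prefer bit-reproducible folds over fidelity to any particular randomised
BUILD; on small instances the result is verified against exhaustive medoid
search — BUILD+SWAP occasionally terminates in a swap-local optimum, which the
tests verify explicitly when it happens — and on larger ones its objective is
checked against the reference `cluster::pam`. Distances are used raw (no square-root or other transform):
"distance between tips" on a branch-length tree is read as patristic.

Folds double as the phylogenetically independent holdout: `holdoutSplit()`
accepts either a fold index (a clade-like block becomes the test set,
mirroring a taxon-level holdout such as an entire phylum) or an explicit
species list. The pipeline refits blocked folds on the training species only,
so no CV fold ever leaks test information.

## Models

**Forward-selection logistic regression.** `forwardPath()` grows nested
predictor sets greedily, scoring each candidate by `cvError()` — the mean
squared error of held-out predicted probabilities (the Brier score; a 0/1
misclassification criterion is available via `criterion = "zeroone"`, but the
probabilistic reading of "mean squared error" is the default). Exact ties go
to the alphabetically first trait. `selectByBIC()` then picks the size
minimising BIC of a full-training-data refit, with the parameter count
including the intercept and ties resolved toward the smaller model. The
logistic fitter is IRLS with a tiny ridge (1e-6) on the coefficients, which
keeps forward steps finite under the complete separation that binary trait
data readily produce; separated fits are flagged, not rejected.

**κ-weighted blocked random-forest ensemble.** `fitBlockedEnsemble()` fits
one forest per blocked fold, each with that fold excluded (500 trees by
default — enough for stable importances at desk scale; the variables tried
per split are `floor(sqrt(p))`). Each forest is then weighted by its Cohen's
κ on the excluded fold. Negative κ values are floored at zero before
renormalisation — a forest that does worse than chance on its own held-out
clade should abstain, not anti-vote — and if every κ is ≤ 0 the weights fall
back to uniform. `predictEnsemble()` lets each forest cast a hard majority
label and returns the class with the greater total weight; an exact tie
returns the training-set majority class. Hard labels (not averaged
probabilities) keep the vote rule interpretable and match the
greatest-total-weight formulation. `ensembleImportance()` aggregates both
forest importance measures (out-of-bag permutation mean decrease in accuracy,
and mean decrease in Gini impurity) as a weighted mean using the same κ
weights — the one consistent choice once the forests themselves are
κ-weighted. For rare outcomes, `stratified = TRUE` gives every tree a
balanced bootstrap (minority-class count drawn from each class, with
replacement).

**Evaluation.** `evaluatePredictions()` reports confusion counts, accuracy,
Cohen's κ and the true positive rate. κ is the headline metric: it corrects
for the inflated accuracy a constant majority-class predictor earns under
class imbalance (such a predictor scores exactly κ = 0).

## Ordination and association reports

`runPCA()` is centred (not scaled) PCA by SVD, the standard default for an
all-`[0, 1]` score matrix; a scaling flag exists. Scaling would equalise the
leverage of near-constant traits, which is usually undesirable here. Labels
are never part of the ordination input — `exportEmbedding()` joins them to
the coordinates only afterwards, for plotting incidence overlays, and accepts
externally computed nonlinear embeddings (e.g. t-SNE coordinates) unchanged.

`incidenceByCategory()` summarises incidence per metadata category with exact
(Clopper–Pearson) binomial intervals at the 99% level, omitting categories
below 10 species; `chiSquare()` applies the same small-category exclusion to
the row totals of a contingency table before a plain Pearson test (no
continuity correction by default — a flag exists). Exact intervals are the
conservative reading of "binomial confidence intervals" when non-overlap is
used as evidence. `phiCorrelation()` and `stratifiedAssociation()` cover
binary–binary associations and their stratum-wise breakdown (the
factor-within-stratum analysis used for interaction claims such as a DNA
repair marker × aerobicity effect on immune-system incidence).

## The synthetic study generator

`generateDataset()` emulates the statistical structure the pipeline assumes,
so everything is testable without any database download:

* **Tree** — a pure-birth (Yule) tree rescaled to unit depth
  (`simulateTree()`). Yule is the simplest generator with realistic
  imbalance; absolute depth is a free scale, so fixing it to 1 makes rates
  and Brownian variances directly interpretable.
* **Traits** — binary characters evolved by a symmetric two-state Mk model
  (exact per-branch transition probability \((1 - e^{-2rt})/2\)) from a
  Bernoulli(0.5) root; a `signalFraction` of 0.8 by default, the remainder
  i.i.d. noise traits.
* **Confidences** — for a true-1 cell, `c+ ~ Beta(s, 1)` and
  `c- ~ Beta(1, s)` (reversed for true-0), with `s = confidenceStrength = 8`:
  informative but noisy, the regime of text-mining confidences. The Beta
  family is a modelling choice — the real noise distribution of such scores
  is uncharacterised — chosen because a single parameter moves it smoothly
  from uninformative (s = 1) to near-deterministic. Cells are masked missing
  independently at rate 0.18, the missingness level of the motivating trait
  database.
* **Outcome** — a liability threshold model:
  \(L_i = \sum_j \beta_j x_{ij} + B_i + \epsilon_i\) with Brownian \(B\)
  (variance `phyloLiabilitySd`² at unit depth) injecting phylogenetically
  correlated residual, and labels set by the empirical liability quantile
  closest to `targetPrevalence` (exact prevalence control, no intercept
  root-finding). Defaults: three driver traits with log-odds effects of 2,
  liability sd 1, prevalence 0.45 — strong enough signal to be recoverable at
  n = 300, weak enough that recovery is not trivial.

Stage sub-seeds are derived by hashing the stage name into the master seed,
so changing one stage's draw count never perturbs another stage, and a given
`SimulationConfig` always yields a byte-identical bundle.

What the generator does *not* emulate: correlated trait families and
multicollinearity as strong as real text-mined tables, systematic (non-random)
missingness, heterogeneous per-trait confidence quality, or gain/loss dynamics
of the outcome feature along the tree (the liability residual is Brownian,
not a two-state process). Passing tests therefore show the machinery is
correct and well-calibrated under its own assumptions, not that any
particular real-data effect size will be reproduced.

## Numerical choices and degenerate inputs

* Logistic IRLS: convergence at score norm < 1e-6, 100-iteration cap, linear
  predictor clamped at ±30; single-class outcomes are an error; folds whose
  training complement is single-class contribute a class-frequency forecast
  with a warning.
* PAM: improvement threshold 1e-12 (exact-tie stability), swap cap 200.
* Imputation: stopping at the first increase of
  \(\Delta = \sum(\text{new} - \text{old})^2 / \sum \text{new}^2\) over
  imputed cells; output clipped to [0, 1]; an entirely missing column is an
  error naming the column.
* κ with chance agreement 1 (both vectors constant and equal) is 0 by
  convention; ensemble vote ties at exactly equal weight go to the training
  majority class.
* Ultrametricity, fold non-emptiness, weight normalisation (±1e-9) and score
  ranges are enforced by S4 validity methods.

## Problem sizes

The reference synthetic study used throughout the tests and examples is 300
species × 30 traits with five blocked folds and 500-tree forests, and the
property-style checks run 10 replicate seeds (with 8/10 success thresholds
for the stochastic recovery and honesty properties, and 18/20 for the
driver–label association check). These sizes give stable statistical
behaviour for a desk-scale study; all of them are configurable upward.

## Known limitations

* Blocked folds assume the blocks are evolutionarily independent; on shallow
  trees (or a star phylogeny) PAM still returns a partition, but it no longer
  carries that meaning.
* The forward-selection path is greedy and inherits the usual instability
  under strong multicollinearity; the ensemble model is the more robust
  choice there.
* No parametric phylogenetic regression is included; the blocking approach is
  deliberately non-parametric (no explicit evolution model for the traits).
* The imputation forest treats columns as exchangeable predictors; it does
  not use the tree, so purely phylogenetic signal in missing cells is
  recovered only insofar as correlated columns carry it.

## A minimal run

```{r example, eval = FALSE}
bundle <- generateDataset(SimulationConfig(nSpecies = 120, nTraits = 12,
                                           seed = 1))
cfg <- runConfig(bundle$confidences, bundle$tree, bundle$labels,
                 k = 5, testGroup = 1, nTrees = 500, maxSize = 6, seed = 1)
res <- runPipeline(cfg, outDir = "run1")
res$evaluations$blockedEnsemble
```

The run directory contains the config copy, a timestamped log with input
hashes, fold files, the selection path, ensemble weights and importances, the
evaluation reports (computed once, on the held-out group only), and the
ordination tables.
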