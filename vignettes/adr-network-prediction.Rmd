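---
title: "Predicting an adverse-reaction class from drug targets, interaction networks and GO annotations"
author: "adrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting an adverse-reaction class from drug targets, interaction networks and GO annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrnet)
```

## The problem and the model

Most marketed drugs bind proteins beyond their intended target, and some of
those off-target interactions surface clinically as adverse drug reactions
(ADRs). `adrnet` asks a concrete question: given only which proteins a drug
docks, can we predict whether it carries a particular ADR *class* — the
reference case being cardiotoxicity, defined as any reaction whose ICD-10
code falls in the circulatory-system chapter I00–I99?

The data model is a pair of fact matrices over a common drug universe
$D_1 \dots D_N$:

* $DS_{nj} \in \{0,1\}$ — drug $n$ is reported with adverse reaction $S_j$;
* $DT_{nk}$ — the association weight between drug $n$ and protein feature
  $T_k$.

Reactions are collapsed into a single response: $DS_{nH} = 1$ iff any
reaction of drug $n$ maps into the class code range (for cardiotoxicity,
the 3-character ICD-10 category between I00 and I99; decimal sub-codes are
ignored and a range entry such as I30–I52 is represented by its lower
bound). The prediction task is then a binary classification of drugs with
$DT$ columns as features.

Raw drug–target facts are sparse and binary. The package enriches them in
two independent ways:

1. **Network expansion.** Given a protein–protein interaction (PPI) network
   whose edges carry integer confidence stars 1–5 (5 = high-confidence
   physical interaction), the drug's target set is expanded one level: the
   expansion "tree" roots at the drug, branches to each direct target and
   leafs at every network neighbor of each direct target. The new
   $DT_{nk}$ is the *multiplicity* of protein $k$ in that tree — a protein
   that is a direct target and also the neighbor of another direct target
   counts twice. Expansion is preceded by star filtering ("N Stars UP":
   keep edges with at least N stars), making confidence a tunable
   dimension of the experiment grid.
2. **GO annotation.** Each target's Gene Ontology biological-process
   annotations replace (or augment) protein identity. Terms live at a
   *level*: the root ("biological process") is level 1 and every other
   term sits at 1 + the length of its shortest `is_a` path to the root.
   Two constructions are available: *threshold* features (keep direct
   annotations at level ≥ N, cell = number of the drug's targets carrying
   the term) and *rollup* features (replace terms deeper than N by all
   their ancestors at exactly level N, deduplicated per target).

Downstream, every experimental condition runs through the same machinery:
per-feature association screening (Fisher's exact test for binary columns,
Wilcoxon rank-sum for integer weights, keep p < 0.05), majority-class
partition balancing, a probability-output classifier (RBF-kernel SVM or
logistic regression), and stratified 10-fold cross-validation repeated
three times with median reporting of AUC, accuracy, sensitivity and
specificity at the 0.5 probability threshold.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `minStars` | — | Confidence floor for PPI edges (1–5, dimensionless). Sweeping it trades network coverage against noise. |
| `minLevel` / `rollLevel` | — | GO depth threshold / rollup level. Shallow levels are uninformative ("biological process"), very deep levels fragment the signal. |
| `alpha` | 0.05 | Feature-screen threshold on raw p-values. No multiple-testing correction: the screen is a pre-filter for the classifier, not an inference procedure. |
| `folds`, `repeats` | 10, 3 | Cross-validation geometry; medians over repeats damp fold-assignment luck. |
| `cost`, `gamma` | 1, 1/#features | SVM hyperparameters, the `e1071` defaults; the package deliberately does no tuning. |
| `tau` | 0.5 | Decision threshold for ACC/SEN/SPE; both model families emit fitted probabilities, so 0.5 is the natural calibration-free cut. |

## The synthetic-data generator

Because the real inputs (DrugBank, SIDER, HAPPI, GO) are licensed,
large and mutable, the package ships a generator
(`synthConfig()` / `generateDataset()`) that emulates their *shapes* with a
planted mechanism, so every stage of the pipeline is exercisable and
testable offline.

The generative model: 300 proteins fall into 12 equal modules; within a
module any pair interacts with probability 0.3 (stars drawn from a
high-skewed distribution: 0.05/0.10/0.15/0.30/0.40 over 1..5), between
modules with probability 0.01 (stars low-skewed, mirrored). Two modules
are *toxic*. Each of 200 drugs samples 1–5 targets uniformly. A drug is
toxic pre-noise iff a target lies in a toxic module **or** is one
interaction hop from a toxic-module protein; labels are then flipped with
probability 0.05. Toxic drugs receive a simulated reaction name mapped to
ICD-10 I99 (inside the circulatory range), everyone shares a benign R42
reaction, so the label must be reconstructed through the same ADR→ICD-10
join the real pipeline uses. The ontology has depth 7: three shared
level-2 branches and one module-specific chain per module from level 3
down, with each protein annotated by its module's deepest term.

Design intent behind the defaults:

* toxicity propagates exactly **one** hop because the pipeline expands
  exactly one level — the planted signal is recoverable in principle by
  the implemented method, while drugs whose only route to a toxic module
  is that hop are invisible to the raw target matrix ("No Net");
* stars correlate with module co-membership, so sweeping `minStars`
  changes how much of the module structure (and hence signal) survives;
* module-specific deep GO terms make module membership — a strong
  correlate of the planted label — visible to the GO feature route;
* 5% label noise keeps perfect separation out of reach without burying
  the signal; sizes (200 drugs, 300 proteins) keep a full experiment grid
  runnable in seconds.

What the generator does **not** emulate: scale-free degree distributions,
correlated target portfolios of drug families, annotation depth
heterogeneity, reporting bias in ADR data, or realistic prevalences of
specific reactions. Passing tests on synthetic data therefore demonstrate
that the machinery recovers a network-mediated signal when one exists —
not that any particular performance level transfers to real databases,
whose headline numbers require the full licensed dumps.

## Numerical and procedural choices

* **GO level = shortest path.** A DAG gives a term many depths; the
  minimum is deterministic and anchors the root at level 1. Whether the
  original convention was shortest or longest path is not decidable from
  published descriptions; shortest is this package's fixed choice.
* **Rollup maps to *all* level-N ancestors.** Choosing one ancestor would
  be arbitrary in a DAG. The ancestor closure follows every parent link —
  a level-N ancestor may be reachable only through an intermediate term
  that itself sits *shallower* than N, so no pruning by intermediate
  level is allowed (the test suite checks this against a breadth-first
  closure oracle). Per-target deduplication keeps a cell interpretable as
  "number of supporting targets".
* **GO cells are counts, not binary.** Consistent with the expanded
  network's integer weights, and it routes GO features through the
  rank-sum branch of the screen. Whether the original design used counts
  is unknown; this is a package choice, not a claim.
* **Fisher two-sided p** sums hypergeometric point masses ≤ the observed
  one with relative tolerance 1e-7 (the standard 2×2 convention); a zero
  margin (constant column) is degenerate and yields p = 1 rather than an
  error, so constant features simply fail the screen.
* **Rank-sum** uses an exact midrank permutation distribution up to total
  n = 12 and the tie-corrected, continuity-corrected normal approximation
  beyond; the approximation is vectorized by hand because the screen is
  the pipeline's hot path.
* **Screening happens inside each training fold.** Selecting features on
  the full matrix before cross-validation leaks the validation labels and
  inflates performance; a `selectGlobally` flag reproduces the leaky
  variant for comparison. If no feature clears `alpha` in a fold, the
  single smallest-p feature is used so a model can always be fitted.
* **Balancing** deals the shuffled majority class into
  `max(1, round(|major| / |minor|))` parts (sizes differing by ≤ 1); one
  model per part ∪ minority; the ensemble probability is the arithmetic
  mean. Note that when the class ratio is below 1.5 the single resulting
  part can exceed the minority size by more than one — the rounding rule,
  not a fixed size cap, is the contract. Validation folds stay
  imbalanced so reported performance reflects deployment conditions.
* **Stratified folds** preserve class proportions per fold; with heavy
  imbalance, plain random folds can produce single-class validation sets
  and undefined AUCs.
* **Per-repeat pooled metrics.** One ROC from all out-of-fold predictions
  of a repeat (stable with small minority classes), then the median over
  repeats; an even repeat count takes the mean of the middle pair.
* **Network randomization = node-label permutation.** It preserves the
  abstract graph exactly (degree and star multisets, joint structure) and
  is deterministic under a seed, giving the cleanest "same topology,
  scrambled identities" control; degree-preserving rewiring is weaker on
  both counts.
* **Determinism.** Every stochastic entry point takes a seed and restores
  the caller's RNG state (`withr`); the SVM probability model in `e1071`
  draws from R's RNG and is covered by the same discipline.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full grid on the default
generator conditions (200 drugs, 300 proteins), with exhaustive oracles at
small scale chosen for completeness rather than speed: all 2×2 tables with
N ≤ 40 against an independent enumeration oracle, all rank-sum partitions
with n ≤ 10 against full permutation enumeration, 200 random expansion
instances against a literal tree-counting oracle, and 500-instance
property sweeps for balancing and AUC identities.

## Known limitations

* One expansion level only; multi-hop diffusion is out of scope.
* One binary ADR class per run; no multi-class or multi-label support.
* No hyperparameter tuning, calibration, or additional classifier
  families; the two families are compared at fixed defaults.
* The ADR-name → ICD-10 join is by curated name map (the packaged
  cardiotoxicity table covers the reference class); unmapped reaction
  names silently contribute nothing to the label.
* p-values from condition contrasts use per-repeat AUCs as the unit of
  replication, which understates variability relative to fold-level or
  bootstrap units; the report labels its unit explicitly.

## A minimal worked run

```{r example, eval = FALSE}
g  <- generateDataset(synthConfig(seed = 1))
dt <- buildTargetFacts(g$targets, g$truth$drug_id)
y  <- buildAdrClassLabels(g$adrs, g$icd, c("I00", "I99"), g$truth$drug_id)

noNet <- summarizeCV(crossValidate(dt, y, modelSpec("svm_rbf"), seed = 1))

ex <- expandOneLevel(dt, filterByStars(g$net, 2))
net <- summarizeCV(crossValidate(ex, y, modelSpec("svm_rbf"), seed = 1))

rbind(no_net = noNet, stars2_up = net)
```
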