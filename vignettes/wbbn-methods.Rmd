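---
title: "Weighted Bayesian belief networks: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted Bayesian belief networks: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbbn)
```

## The problem

Clinical screening tables — the discretized Wisconsin breast-cancer data
being the canonical shape — record a handful of categorical measurements
per patient plus a binary outcome. Classical association rule mining treats
every attribute–value pair as equally important; in a diagnostic setting
that is wrong on its face: a high bare-nuclei score carries far more
malignancy evidence than a low mitosis count. `wbbn` implements an
associative classifier in which the *pairs themselves are weighted by their
positive-class evidence*, rules are mined and filtered under those weights,
and the surviving strong rules decide which attributes enter a Bayesian
network classifier and which edges it may use.

## Data model

A dataset is a set of records, each holding exactly one integer *item* per
attribute (one item per discretized bin; contiguous ID blocks per
attribute) plus one class item. The default schema is the 9-attribute
breast-cancer layout: items 1–18 for the attribute bins, 19/20 for
benign/malignant. The `.num` reader accepts the LUCS-KDD item-number
dialect; the CSV reader discretizes raw 1–10 cytology scores through
user-supplied bins (default: 1–5 low, 6–10 high). The published sources for
this layout never state the exact bin boundaries behind the item pairs, so
the schema is deliberately user-supplied configuration (YAML), with the
default above as the shipped convention. Records with missing cells (`?`,
empty, or an absent item) are flagged at read time and removed by
`drop_missing()`, which reports the count.

## Pair weights

For each attribute item we count co-occurrence with each class label and
rank all (item, label) pairs jointly — dense ranks, largest count first,
ties shared. Weights are then defined for the positive class only. Two
schemes are provided because the choice is genuinely open in the method's
published description (the printed weight tables are consistent in
magnitude with a joint relative frequency but follow no stated formula):

* **joint** (default): `w(i) = count(i ∧ yes) / n = P(i ∧ yes)`. Weights of
  one attribute's items sum to `P(yes)`, and weights are anti-monotone with
  the yes-label ranks — two properties the shipped tests assert.
* **posterior**: `w(i) = P(yes | i)`, the Bayes-theorem posterior of
  malignancy given the pair.

A record's ("tuple") weight is the **mean** of its attribute items' weights
(a `sum` scheme is available). The mean keeps record weights on the item
weight scale regardless of attribute count and makes the uniform-weight
case collapse exactly to classical support — the reduction the test suite
checks against an independent plain-counting Apriori.

## Weighted rule mining and strong rules

Weighted support is a ratio of record-weight sums, weighted confidence the
support ratio of rule over antecedent. One support function serves all
three mining modes (two-attribute, multi-attribute, class-label); only the
itemset shape differs. Because every record's weight is fixed before
mining, weighted support is anti-monotone under itemset growth, so
levelwise Apriori pruning is exact — the suite verifies the miner against
brute-force enumeration over all itemset pairs on random weighted datasets.
Itemsets never take two items of one attribute (their support is
structurally zero).

Weighted Bayes confidence (WBC) of `A → B` is `P(B|A)` computed from
weighted supports — numerically the weighted confidence; the alternative
reading, estimating `P(B|A)` from a learned network, is circular here
because no network exists before strong rules are selected. Weighted Bayes
lift is `WBC / WS(B)`, taking the consequent's weighted marginal as
`P(B)` — the only consequent marginal the weighted framework defines. A
rule is **strong** when `WBC ≥ min_confidence` and `WBL > min_lift`; the
lift threshold defaults to 1 (strict positive association) since no
published threshold exists. Rules whose consequent has zero support are
dropped with a warning (their lift is undefined). Output ordering is fully
deterministic: descending (WBL, WBC), then lexicographic itemset order.

Default thresholds are minimum support 0.36 and minimum confidence 0.70,
the operating point reported for this method's breast-cancer experiments;
`threshold_config()` exposes them, along with `max_antecedent_size`
(default 3 — published strong-rule counts of 5–12 imply short rules).

## Network construction

* **Node set.** Only attributes occurring in strong rules, plus the class
  node. An `unrestricted_k2` flag lifts both this and the edge restriction.
* **Order.** K2 needs a total order; none is published. Nodes are ordered
  by descending total pair weight (heavier, more disease-informative
  attributes become potential ancestors), class last, ties alphabetical.
  Totals are rounded to 12 decimals before ranking so that mathematically
  equal totals cannot be split by floating-point summation order.
* **Search.** Greedy K2 under the Cooper–Herskovits marginal likelihood
  (uniform Dirichlet prior), adding the best earlier-ordered candidate
  parent while the score improves, up to `max_parents` (default 3: the
  datasets are small and CPT size grows exponentially in parents).
  Candidate parents are restricted to attribute pairs co-occurring in some
  strong rule. A score improvement must exceed 1e-12 to count, so exact
  ties never add an edge.
* **Parameters.** `P(v | pa) = (N(v,pa) + α) / (N(pa) + αk)` with per-cell
  pseudo-count α = 0.5 (the published parametric-learning setting, read as
  the standard Dirichlet/Laplace-style semantics). Never-observed parent
  configurations therefore yield the uniform `1/k`, and no CPT entry is
  ever zero — which in turn keeps every full assignment's joint probability
  strictly positive and classification total.
* **Inference.** Exact enumeration over hidden nodes. The networks here
  have at most ten-odd binary nodes, so approximation would only add error.
  Exact posterior ties (possible only through symmetric CPTs) go to the
  majority training class.

## Evaluation protocol

Splits are stratified by class and seeded; `train_frac = 1` reproduces the
resubstitution (100 %/100 %) protocol of published threshold tables. Two
deliberate departures from the published setup, both behind flags: weights
are computed on the *training partition only* by default (`paper_mode =
TRUE` computes them on the full dataset, as the published weight table
appears to), and splits are stratified (`stratified = FALSE` gives plain
random splits). With zero strong rules the pipeline reports the
majority-class baseline with a warning rather than failing — a defined
prediction is required for sweep tables. `threshold_sweep()` crosses the
four published threshold pairs with split ratios 100/100, 80/20, 70/30,
60/40 by default.

## The synthetic generator

`generator_spec()` plants a Bayesian network over binary attributes plus a
binary class (default shape: 9 attributes, positive-class prior 0.35,
~683 records — the scale and shape of the discretized breast-cancer table)
and samples records ancestrally. Presets:

* `spec_independent()` — no edges; every lift converges to 1.
* `spec_separable()` — three attributes with `P(high|malignant) = 0.95`,
  `P(high|benign) = 0.05`; the Bayes error is below 0.02, so a sound
  pipeline must classify held-out records almost perfectly.
* `spec_chain()` — `A1 → A2 → class` with 0.9/0.1 conditionals; structure
  recovery ground truth.
* `spec_wbc_like()` — five class-linked attributes of varying strength
  plus one attribute–attribute edge, emulating correlated cytology
  measurements.

`expected_strong_rules()` computes supports, confidences and lifts
*analytically* from the planted joint (enumerable up to 12 binary nodes)
under uniform weights — the limit the data-driven miner approaches, used
as the convergence oracle in the tests.

What the generator does **not** emulate: ordinal bins wider than two,
attribute-specific missingness mechanisms (missing cells are injected
uniformly at random), measurement noise correlated across attributes
beyond the planted edges, and any real biological effect sizes. Passing
tests on generated data therefore demonstrate *algorithmic correctness*
(the implementation computes the method's quantities exactly and recovers
planted structure), not clinical performance on real cytology data.

## Numerical choices and degenerate inputs

* Support/confidence are ratios of double sums; equality checks against
  oracles are at 1e-12. Threshold comparisons are `≥` on the computed
  double; tests that compare the weighted route against plain counting pick
  thresholds off the attainable `k/n` lattice so knife-edge rounding cannot
  flip borderline rules between two correct implementations.
* Empty dataset: counting and accuracy raise errors; reading an empty file
  returns an empty dataset.
* Zero total record weight (all pair weights zero) raises an
  undefined-support error rather than returning NaN.
* An all-missing dataset after `drop_missing()` is an empty dataset, not an
  error.
* CPT columns are asserted to sum to 1 within 1e-9 by the test suite.

## Problem sizes in the shipped checks

The test suite and acceptance script use sizes chosen to make each property
sharp yet quick on a laptop: 25 random datasets of 3–6 attributes and
40–200 records for exact miner/oracle equivalence; 10 × 10 000 records for
the lift-independence band [0.9, 1.1]; 10 × 5 000 ancestral samples for CPT
recovery within 0.05 max-abs error; 10 × 2 000 for chain-structure
recovery; 100 random evidence patterns over ≤ 8-node networks for
inference-oracle agreement at 1e-10; and 10 seeds of the 683-record
separable benchmark for end-to-end accuracy ≥ 0.95.

## Known limitations

* Binary bins per attribute are the tested path; the code accepts more bins
  per attribute, but the shipped schemas and generator presets are binary.
* The published weight table for this method is not exactly reproducible
  from any stated formula; the joint scheme matches its scale and ordering
  properties only, and is treated as a diagnostic reference.
* Greedy K2 is order-dependent by design; with a misleading node order it
  can orient edges against the data-generating direction (it still finds an
  equivalent-skeleton model on the chain benchmark).
* Holdout accuracy is the only built-in metric, matching the method's
  published evaluation; ROC/F1 are out of scope.
* No continuous attributes, negative rules, closed-itemset compression, or
  approximate inference.
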