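# wbbn — Weighted Bayesian Belief Networks for discretized clinical data

`wbbn` builds an associative Bayesian-network classifier for discretized
categorical clinical tables, of the kind used in breast-cancer risk
prediction: every attribute–value pair is weighted by its evidence for the
positive (malignant) class, weighted association rules are mined from those
weights, the strongest rules select and wire the network, and new records
are classified by exact posterior inference.

## The method

Records are sets of integer **items**, one per discretized attribute bin,
plus a class item (benign / malignant). The pipeline is:

1. **Pair weighting.** For each item *i*, count its co-occurrence with each
   class label, rank all (item, label) pairs jointly by count (dense ranks),
   and weight the pair from the Bayes-theorem quantities of its contingency:
   the default *joint* scheme uses `w(i) = P(i ∧ class=yes)`, the alternative
   *posterior* scheme `w(i) = P(yes | i)`. A record's (tuple) weight `W_r`
   is the mean of its items' weights.
2. **Weighted association rule mining (WARM).** The weighted support of an
   itemset X is `WS(X) = Σ_{r ⊇ X} W_r / Σ_r W_r`, and the weighted
   confidence of a rule A→B is `WC = WS(A ∪ B)/WS(A)`. Rules are mined in
   three modes — two-attribute, multi-attribute, and class-label — by
   levelwise Apriori (exact, since `WS` is anti-monotone in the itemset).
3. **Strong-rule selection.** Weighted Bayes confidence `WBC(A→B) = P(B|A)`
   from weighted supports, and weighted Bayes lift `WBL = WBC / WS(B)`.
   A rule is *strong* when `WBC ≥ min_confidence` and `WBL > 1`.
4. **Network construction.** K2 structure search (Cooper–Herskovits score)
   over the attributes appearing in strong rules plus the class node, in
   descending total-pair-weight order with the class last; conditional
   probability tables smoothed with a Dirichlet pseudo-count α = 0.5:
   `P(v|pa) = (N(v,pa) + α)/(N(pa) + αk)`.
5. **Classification.** `P(class | evidence)` by exact enumeration over the
   factored joint `P(x1,…,xn) = Π P(xi | Pa(xi))`; the argmax class is
   returned with its posterior.

The package also ships readers for the LUCS-KDD `.num` item format and for
raw CSV + discretization schema, a synthetic-data generator with planted
network structure (so every stage can be tested against analytic ground
truth), an evaluation harness (stratified holdout, threshold sweeps), and a
command-line front-end (`inst/cli/wbbn`).

## Worked example

```r
library(wbbn)

ds <- generate(spec_separable(n_records = 683, seed = 7))  # 9 binary attributes
wt <- compute_weights(ds)
head(as.data.frame(wt), 4)
#>   item attribute count_yes count_no rank_yes rank_no     weight
#> 1    1        A1        13      432       29       1 0.01903367
#> 2    2        A1       221       17       11      27 0.32357247
#> 3    3        A2        11      424       30       3 0.01610542
#> 4    4        A2       223       25       10      25 0.32650073

cfg    <- threshold_config(min_support = 0.36, min_confidence = 0.70)
rules  <- mine_rules(ds, wt, cfg, mode = "class_label")
strong <- score_strong(rules, ds, wt, cfg)
head(as.data.frame(strong)[, c("antecedent","consequent","ws","wbc","wbl","strong")], 3)
#>   antecedent consequent        ws       wbc      wbl strong
#> 1      2,4,6         20 0.4028068 1.0000000 2.111423   TRUE
#> 2        4,6         20 0.4257494 0.9959797 2.102934   TRUE
#> 3        2,6         20 0.4221969 0.9958604 2.102683   TRUE

res <- run_pipeline(ds, cfg, train_frac = 0.7, seed = 7)
res[, c("n_rules", "n_strong_rules", "accuracy")]
#>   n_rules n_strong_rules  accuracy
#> 1      32             32 0.9902439
attr(res, "model")
#> bayes_net: 4 nodes, 6 edges (alpha = 0.5)
#>   A2 <- {A1}
#>   A3 <- {A1, A2}
#>   class <- {A1, A2, A3}
```

The weight table ranks each attribute bin by how often it co-occurs with
the malignant class (item 2 — the high bin of the informative attribute A1
— carries weight 0.32, its low bin 0.02). The three strongest class rules
say that high values of the informative attributes imply malignancy with
confidence ≈ 1 and lift ≈ 2.1 over the malignant base rate. The fitted
network classifies the 30 % held-out records with 99 % accuracy on this
separable benchmark.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/wbbn sweep --synthetic separable --n 683 --seed 7 --out sweep.csv
```

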