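# lpihn

Predicting lncRNA-binding proteins by random walk with restart on a
heterogeneous network.

## The problem

Long noncoding RNAs (lncRNAs) mostly act through the proteins they
bind, yet known lncRNA-protein interactions are sparse. `lpihn` is for
computational biologists who want to prioritize candidate binding
proteins for a query lncRNA from three common data sources: an lncRNA
expression matrix across tissues, a weighted protein-protein
interaction (PPI) network, and a table of already-known lncRNA-protein
interactions.

## The method

Three layers are fused into one heterogeneous network:

* lncRNA-lncRNA similarity `SL(i, j) = |cor(X_i, X_j)|`, the absolute
  Pearson correlation of expression profiles;
* the PPI layer normalized symmetrically,
  `SP'(i, j) = SP(i, j) / sqrt(M(i,i) M(j,j))` with `M(j, j)` the row
  sum of raw scores;
* known interactions `I(i, j) ∈ {0, 1}` as cross-layer edges.

The row-stochastic block transition matrix (proteins first)

```
W = | W_P   W_PL |
    | W_LP  W_L  |
```

keeps probability `1 - γ` within a layer and sends `γ` across for nodes
with a cross edge. A random walk with restart

```
Y_{t+1} = (1 - δ) Wᵀ Y_t + δ Y_0,   δ = 0.3, β = 0.5, γ = 0.5
```

starts from `Y_0` = (β on the query lncRNA, `1 - β` spread over its
known partner proteins) and is iterated until the L1 change drops below
1e-10. Candidate proteins -- those not already known partners -- are
ranked by their stationary probabilities.

The package also ships the full evaluation harness: leave-one-out
cross-validation (LOOCV) over known interactions, pooled ROC/AUC,
sensitivity at fixed specificity, precision/recall at rank `k`, fold
enrichment `N/(2n)`, percentile retrieval counts, a
protein-layer-only RWR comparison, a randomized-network control, and a
synthetic planted-structure generator so everything runs without
external databases.

## Worked example

```r
library(lpihn)

scn <- generate_scenario(scenario_config())   # default planted scenario
net <- lpihn_network(scn$interactions, scn$expression, scn$ppi)
net
#> Heterogeneous lncRNA-protein network: 40 proteins, 60 lncRNAs, 273 known interactions

predict_partners(net, "L01", top_k = 5) |> head(5)
#> # A tibble: 5 × 5
#>   query protein  score  rank in_top_k
#>   <chr> <chr>    <dbl> <int> <lgl>
#> 1 L01   P06     0.0302     1 TRUE
#> 2 L01   P07     0.0270     2 TRUE
#> 3 L01   P08     0.0262     3 TRUE
#> 4 L01   P10     0.0241     4 TRUE
#> 5 L01   P04     0.0180     5 TRUE

trials <- run_loocv(scn$interactions, scn$expression, scn$ppi)
glance(trials)
#> # A tibble: 1 × 7
#>   method n_trials n_queries n_proteins   auc mean_fold_enrichment recall_at_10
#>   <chr>     <int>     <int>      <int> <dbl>                <dbl>        <dbl>
#> 1 hetnet      272        59         40 0.877                 6.87        0.919
```

The scores are stationary visiting probabilities: `P06` is the protein
the walker most often occupies when restarting around `L01` and its
known partners, i.e. the strongest new-interaction candidate. In the
LOOCV summary, AUC 0.877 means a hidden true partner outranks a random
non-partner about 88% of the time on this synthetic scenario, and mean
fold enrichment 6.9 means held-out partners rank about 7 times better
than chance. `autoplot(trials, type = "roc")` draws the pooled ROC
curve; `tidy(trials)` returns the per-trial ranks.

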