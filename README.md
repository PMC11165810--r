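# eventlink

Link prediction on drug–target–disease graphs via **event nodes** and a
gated convolution + attention graph neural network, implemented entirely
in R.

## The problem

Most drug-repurposing models score pairwise associations — drug–disease,
drug–target — and lose the fact that a therapeutic effect is a *ternary*
relation: a drug acting through a target treats a set of diseases.
`eventlink` makes that ternary relation first-class. From three pairwise
association tables (drug–target, drug–disease, target–disease, the usual
tab-separated edge-list exports of biomedical network databases) it
derives **event nodes**

> Q = ⟨X, Y, Z⟩, where X is a drug, Y a target, and
> Z = { z : (X, z) ∈ drug–disease and (Y, z) ∈ target–disease }

— one event per drug–target pair whose disease intersection Z is
non-empty. Events and diseases form a heterogeneous bipartite graph with
an edge (Q, z) for every z ∈ Z. Predicting *missing* event–disease edges
proposes new indications for a known drug–target combination.

## The model

The encoder maps both node types into a shared d-dimensional space
(h′ = M·h, with one-hot disease-membership rows as event features, a
trainable event embedding, and random Gaussian disease features) and then
stacks L layers, each combining two branches in parallel:

* **convolution branch** (sample-and-aggregate): sample up to k
  neighbours, aggregate `Z_i = mean({h_i} ∪ h_N(i))`, update
  `c_i = ReLU(W·[h_i ‖ Z_i])`;
* **attention branch**: per-neighbour-type scores
  `e_ij = LeakyReLU(aᵀ[Wᵛh_i ‖ Wᵛh_j])`, softmax-normalised weights
  `α_ij`, semantic representation `h′_i = Σ_j α_ij Wᵛh_j`, fused as
  `t_i = U·ReLU([h_i ‖ h′_i])`.

Each branch passes through a sigmoid **gate unit**
`g(x) = x ⊙ σ(W_g x + b_g)` and the layer output is the gated sum plus a
residual: `h_i ← h_i + g_c(c_i) + g_a(t_i)`. The decoder scores an edge
by the embedding dot product (single-linear and bilinear decoders are
available for ablation), trained as binary classification against
uniformly sampled negative edges with numerically stable weighted BCE
and Adam (lr 1e-3, dropout 0.6, weight decay 1e-5, embedding dim 64 by
default). Edges are split 60/10/30 into train/validation/test;
message passing uses training positives only, and the best
validation-AUC checkpoint is returned. Evaluation reports AUC, accuracy,
F1, precision, recall and AUPR.

Because no R deep-learning backend is assumed, forward pass, analytic
backpropagation and the Adam optimizer are implemented in plain R +
Matrix; gradients are verified against central finite differences in the
test suite.

## Worked example

A planted-cluster synthetic benchmark (the package's generator assigns
drugs, targets and diseases to latent clusters; within-cluster
associations are drawn at 0.9, cross-cluster at 0.02, so held-out
event–disease links are predictable from the observed structure):

```r
library(eventlink)

tabs  <- simulate_pair_tables(n_drugs = 60, n_targets = 40, n_diseases = 120,
                              n_clusters = 4, seed = 11)
graph <- build_hetero_graph(build_events(tabs), tabs$vocab)
graph
#> <event_graph>
#>   events:   177
#>   diseases: 120 (120 linked)
#>   edges:    3851

split <- split_edges(graph, seed = 11)
fit   <- fit_event_gnn(graph, split, dim = 32, epochs = 200, seed = 11)
fit
#> <event_gnn>
#>   177 events, 120 diseases; 2310 train / 385 val / 1156 test positives
#>   dim 32, 2 layer(s), decoder 'product'
#>   best validation AUC 0.98446 at epoch 200 of 200

evaluate_edges(fit)
#> # A tibble: 1 × 6
#>     auc accuracy    f1 precision recall  aupr
#>   <dbl>    <dbl> <dbl>     <dbl>  <dbl> <dbl>
#> 1 0.974    0.960 0.961     0.934  0.990 0.958
```

The six numbers are the test-set report: the model recovers held-out
event–disease links almost perfectly (AUC 0.974) because the planted
cluster structure is exactly the kind of signal the encoder propagates.
Ranked indications for one event:

```r
predict_links(fit, event = 0, threshold = 0.9) |> head(5)
#> # A tibble: 5 × 4
#>   disease disease_id probability  rank
#>     <int> <chr>            <dbl> <int>
#> 1     105 Z106             1.000     1
#> 2       3 Z004             1.000     2
#> 3      20 Z021             1.000     3
#> 4     119 Z120             0.999     4
#> 5      97 Z098             0.999     5
```

`tidy(fit)` returns the per-epoch history, `glance(fit)` a one-row
summary, `autoplot(fit)` the loss/validation-AUC curves, and
`run_ablation()` the nine-variant ablation table (layer count, separate
convolution / attention branches, gate removal, three decoders). The
pipeline is also scriptable: `cmd_simulate()`, `cmd_build_graph()`,
`cmd_train()`, `cmd_evaluate()`, `cmd_ablate()`, `cmd_predict()` and
`export_prediction_graph()` read a YAML config and write TSV/JSON
artifacts; `inst/cli/eventlink.R` exposes them as shell subcommands.

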