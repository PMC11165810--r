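---
title: "Event–disease link prediction: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event–disease link prediction: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modelling idea

Pairwise association tables — drug–target, drug–disease, target–disease
— are the common currency of biomedical network resources, but a
therapeutic mechanism is inherently three-way: a drug, acting through a
target, treats diseases. `eventlink` reifies the ternary relation as an
*event node* Q = ⟨X, Y, Z⟩: one node per drug–target pair (X, Y), whose
disease set Z is defined as the intersection of X's diseases and Y's
diseases. Pairs with an empty intersection yield no event: an event
asserts that the combination treats at least one disease. The
intersection rule is the only derivation consistent with treating the
disease set as what the *pair* (rather than either member alone) is
associated with; it is a modelling choice, and users with curated
ternary data can bypass it by supplying their own events.

Events and diseases form a heterogeneous bipartite graph; drug and
target identity are kept as annotations on the event, not as
message-passing nodes, because both the encoder and the decoder operate
only on event and disease embeddings. Diseases absent from every event
are retained as isolated nodes so that disease indices — and therefore
the one-hot feature columns — are stable across splits and reruns. All
identifier-to-index maps are lexicographic, which makes every
downstream artifact bit-reproducible from the input tables and a seed.

Predicting missing event–disease edges is framed as binary
classification: observed edges are positives, uniformly sampled
non-edges are negatives (1:1 by default; the ratio and a positive-class
weight in the loss are exposed for imbalanced regimes).

## Features

Event features are the rows of the binary incidence matrix A (q × z):
row i one-hot-encodes the diseases of event i. A trainable event
embedding (width equal to the embedding dimension by default) is
concatenated with the one-hot row before projection, so the model can
both exploit the known associations and learn event-specific structure.
Disease features are i.i.d. standard normal vectors: diseases carry no
curated covariates here, and random features plus a learned projection
give each disease a distinguishable, trainable representation.

Note one consequence honestly: A encodes the *full* association matrix,
including edges later held out for validation and test. The edge split
governs message passing and supervision only. This mirrors how the
one-hot construction is defined for this architecture; the
permuted-label control in the acceptance suite shows the pipeline does
not trivially read test labels out of the features (control AUC ≈ 0.5),
but users comparing against other methods should be aware the feature
matrix is built before splitting.

## The encoder

After per-type projection h′ = M·h into d dimensions, each of L layers
runs two branches in parallel on the current embeddings H:

* **Convolution branch** (sample-and-aggregate): for each node, up to k
  neighbours are sampled uniformly without replacement (full
  neighbourhood if degree ≤ k); the aggregate is the elementwise mean of
  the node and its sampled neighbours; the update is
  ReLU(W·[h_i ‖ mean]). The aggregator is configurable (mean/sum/max in
  the single-node API); mean is the default because it is
  degree-robust.
* **Attention branch**: scores e_ij = LeakyReLU(aᵀ[Wᵛh_i ‖ Wᵛh_j]) with
  negative slope 0.2, softmax-normalised over the (full) neighbourhood,
  semantic representation Σ_j α_ij Wᵛh_j, then fusion
  U·ReLU([h_i ‖ h′_i]). Wᵛ is indexed by the *neighbour* type (disease
  messages into events use the disease transform and vice versa); the
  attention vector a is shared. The concatenation doubles the width, so
  the learned linear map U restores dimension d — required for the
  residual addition below.

Each branch output passes through a sigmoid gate x ⊙ σ(W_g x + b_g)
(one gate per branch per layer), and the layer output is
h_i + gate(conv) + gate(attention) — a gated sum with a residual
connection. This wiring uses each pictured architectural component
exactly once per layer; gating after fusion instead of per branch is
the main alternative and would remove the model's ability to weigh the
branches independently. Dropout (default 0.6) is applied between layers
during training only.

Two evaluation-relevant choices:

* **Evaluation uses full neighbourhoods.** Neighbour subsampling is a
  training-time stochastic regularizer; at evaluation the aggregation
  matrix includes every neighbour, making `encode()` a deterministic
  pure function of (graph, features, parameters).
* **The projection is shared** between the two branches rather than
  duplicated per branch — fewer parameters, and the branches already
  differ in their own transforms.

Activations: the convolution/fusion nonlinearity is ReLU, the attention
score nonlinearity is LeakyReLU(0.2) (the standard choice for that
mechanism), and the gate nonlinearity is the sigmoid — the only one of
the three that is forced by the gating semantics.

## Decoder, loss, optimisation

The default decoder scores an edge by the dot product of the event and
disease embeddings (sum of the elementwise product over the embedding
dimension) followed by a sigmoid. Two alternatives are registered for
the ablation harness: a single linear map on the concatenated pair
embeddings, and a bilinear form uᵀBv.

The loss is mean binary cross-entropy on logits in the numerically
stable softplus form, `w·y·softplus(−x) + (1−y)·softplus(x)`, exact for
|logits| far beyond 1e4, with an optional positive-class weight.
Optimisation is Adam (β₁ 0.9, β₂ 0.999, ε 1e-8) with L2 weight decay
added to the gradient. Defaults: learning rate 1e-3, batch size 3840
(splits smaller than that run as one full batch), embedding dimension
64, dropout 0.6, weight decay 1e-5. Forward and backward passes are
hand-written in R; the analytic gradients are verified against central
finite differences on every parameter tensor in the test suite.

Training runs 200 epochs by default. No early stopping is applied;
instead the parameters at the best validation AUC are returned
(`best_epoch` is recorded), which bounds runtime while protecting
against late-epoch overfitting. Validation metrics are computed every
epoch on the fixed validation positives and negatives.

Message passing in every epoch uses only the training positives —
validation and test edges never enter the adjacency, which the tests
assert directly on the adjacency the fit consumed. Negatives are fixed
at split time by default (so metrics across runs and variants are
comparable on identical edge sets); per-epoch resampling is available
for training via `resample_negatives = TRUE`.

## Evaluation conventions

* AUC is the Mann–Whitney statistic (ties ½, midranks); the ROC curve
  uses the standard orientations TPR = TP/(TP+FN) on the vertical axis,
  FPR = FP/(FP+TN) on the horizontal.
* AUPR is the step-wise (trapezoid-free) area under the
  precision–recall curve, with tied scores moving together.
* Confusion-based metrics threshold at 0.5 by default (≥ counts as
  positive); zero-denominator precision/recall/F1 return 0 rather than
  NaN so ablation tables never contain undefined cells.

## The synthetic generator

`simulate_pair_tables()` plants cluster structure: drugs, targets and
diseases are assigned to `n_clusters` latent clusters (balanced, then
shuffled); drug–target pairs form within a cluster with probability
`p_dt` (cross-cluster at 0.05·p_dt); the two entity–disease tables are
Bernoulli(p_within) within cluster and Bernoulli(p_between) across.
Derived events then carry cluster-coherent disease sets, so a held-out
event–disease edge is predictable from the surviving edges of the same
cluster — exactly the transferable structure a link predictor should
exploit, with known ground truth.

The benchmark configuration used throughout the acceptance suite is 60
drugs, 40 targets, 120 diseases, 4 clusters, p_within 0.9, p_between
0.02. `p_dt` is fixed at 0.3: at these sizes it yields a few hundred
events with disease sets of a few dozen, large enough for stable
metrics and small enough for desk-scale runtimes. The smaller ablation
graph (30 drugs, 20 targets, 60 diseases, 3 clusters, dimension 16, 120
epochs) and the test-suite toys (≈20 drugs) were chosen the same way:
the smallest sizes at which the studied effects are clearly visible.

What the generator does **not** emulate about real pharmacological
networks: heavy-tailed degree distributions (hubs such as promiscuous
targets), correlated annotation noise, incomplete and biased sampling
of the association tables, identifier synonymy, or realistic scale.
Passing the synthetic benchmark therefore demonstrates that the
implementation learns and generalises planted relational structure —
not that it attains any particular performance on real resources.

## Numerical and degenerate-input conventions

* Isolated nodes: the convolution aggregate degenerates to the node
  itself; the attention aggregate is the zero vector (the single-node
  `attention_coefficients()` refuses an empty neighbourhood instead,
  since a softmax over nothing is undefined).
* Softmax scores are max-shifted per neighbourhood before
  exponentiation.
* Negative sampling enumerates the exact non-edge complement for grids
  up to 10⁶ cells and falls back to guarded rejection sampling above.
* All ties (ranking, ordering of events, vocabularies) are broken by
  index, and every index is fixed lexicographically, so identical
  inputs and seeds give byte-identical artifacts.

## Known limitations

* Full-graph backpropagation in plain R is desk-scale: hundreds of
  events train in seconds per hundred epochs, but millions of edges
  would need a compiled backend and minibatched neighbourhood training,
  both out of scope.
* Multi-head attention, edge features and learning-rate schedules are
  not implemented.
* The event derivation trusts the intersection rule; noisy pairwise
  tables propagate their false positives into event disease sets.
* Feature construction precedes edge splitting (see above); rankings of
  *unobserved* pairs are unaffected, but absolute test metrics should
  be read with that in mind.
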