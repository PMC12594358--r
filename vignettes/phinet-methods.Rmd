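---
title: "Estimating integrated information with a graph-transformer network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating integrated information with a graph-transformer network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Integrated-information theories of consciousness score a stochastic system
by how much its dynamics, observed at a particular state, exceed the
dynamics of its parts: the system-level integrated information Φ. The
subsystem that maximises Φ is the *major complex* — the posited locus of
integration. Exact computation is exponential in the number of nodes, which
confines it to systems of fewer than about ten nodes. `phinet` treats the
problem as supervised learning on graphs: label many small systems exactly,
train a graph neural network to map system structure to (Φ, major-complex
membership), and use the trained network — cheaply — on systems far beyond
the reach of exact computation, where only qualitative trends can be
trusted.

## The system model

A system is an undirected weighted graph of `N` binary nodes, states
`S_i ∈ {+1, −1}`, couplings `J_ij` and one temperature `T` shared by all
nodes. Node `i` flips to state `s` at the next step with Boltzmann
probability

    p_i(s | S) = 1 / (1 + exp(−2 τ_i s / T)),   τ_i = Σ_{j∈N(i)} J_ij S_j,

conditionally independently across nodes, so the full-state transition
probability is the product over nodes. Two exact symmetries matter
downstream: the conditionals normalise (`p_i(+1|S) + p_i(−1|S) = 1`, which
the implementation enforces exactly in floating point by computing the −1
case as the complement), and the dynamics are inversion-symmetric,
`p(S*|S) = p(−S*|−S)`, so a state vector and its global flip are physically
equivalent.

The random-system generator draws each of the `C(N,2)` edges independently
with probability `p = 0.4`, couplings from a standard normal, `T` uniformly
from `[0.1, 3.0]` and the state uniformly — these are the study conditions,
not tuning knobs. Special topologies (uniform spanning trees via Prüfer
sequences; complete graphs; loop-containing graphs with `round(0.4·C(N,2))`
edges for `N ≥ 6` and `N + 1` for `N ∈ {4,5}`) and a two-block
"split-brain" generator (100 nodes, intra-block edge probabilities 0.6 and
0.4, inter-block probability `p_e`) reproduce the structured test beds.
Connectivity is deliberately *not* enforced: disconnected systems are legal
and are in fact essential to the augmentation strategy below. One root seed
feeds separate child streams for topology, weights, temperature and state,
so changing one draw never shifts the others.

The `2^N`-row transition table is stored little-endian — node 1 varies
fastest, bit 1 encodes state +1 — matching the dominant convention of
state-by-node tables in this field; the ordering is part of the documented
contract and is tested.

## Exact labels

Ground truth is produced by an exhaustive, deterministic engine. For every
subsystem `M` (|M| ≥ 2), with all nodes outside `M` frozen at the assigned
state, and for every bipartition `{A, B}` of `M`, the engine computes the
*effective information* of the cut: the sum over nodes of the KL divergence
between each node's actual next-state distribution and the distribution
obtained when that node's inputs from across the cut are marginalised
uniformly. The minimum-information bipartition is selected under the usual
size normalisation (effective information divided by the smaller part's
size — the per-capacity cost of the cut), and the subsystem's φ is the
*unnormalised* effective information at that cut, so that integration can
grow with subsystem size. The system label is `Φ = max_M φ(M)` and the
argmax is the major complex; `Φ = 0` means no complex (every node labeled
"out"). Ties are broken by deterministic enumeration order (increasing
size, then lexicographic) and flagged.

This is an integration measure in the effective-information /
minimum-information-partition family, computed exactly at the assigned
state. It deliberately does not implement mechanism-level integration,
cause-effect repertoires or earth-mover distances — the nested hierarchy of
the full theory stays out of scope — and the oracle interface is pluggable:
labels from any engine producing `{phi, major_complex}` can be supplied
through the JSON-Lines label cache, keyed by a content hash of the system
(so edge ordering is irrelevant). The measure inherits the two symmetries
tests rely on: labels are exactly invariant under global state inversion
and equivariant under node relabeling.

A frozen fixture pack of 260 labeled systems (60 with N = 3, 100 each with
N = 4 and 5; generator settings above) ships in `inst/extdata/fixtures` so
every other module is testable without recomputation; the pack is audited
for the invariants before freezing, and its labels carry an
`engine_version` stamp.

## Features

Each node gets six features, in fixed order: `max{p_i(+1|S), p_i(−1|S)}`
(equivalently `1/(1+exp(−2|τ_i|/T))`, the only state-dependent feature),
the shared temperature `T`, degree, closeness, betweenness and the local
clustering coefficient. Each directed edge carries the raw coupling `J_ij`.
The state `S_i` itself is never a feature: using the larger of the two flip
probabilities makes every feature — and therefore the whole network —
*exactly* invariant under global state inversion, which is the appropriate
equivalence for inversion-symmetric dynamics.

Centralities use unweighted hop counts. Conventions for degenerate cases
are explicit because random sparse graphs are frequently disconnected:
closeness is `(R_i/(N−1)) / mean(d over reachable nodes)` with `R_i` the
number of reachable other nodes (isolated node → 0), betweenness is
normalised by `(N−1)(N−2)/2`, and clustering of nodes with fewer than two
neighbours is 0. Node features are z-scored per column with statistics
fitted on the (expanded) training set only; the edge feature is left raw by
default (a config switch enables standardising it).

## The network

Four transformer-convolution layers with `H = 4` heads of `C = 16` channels
(hidden width 64). Per head, node vectors are projected to queries, keys
and values; the attention weight toward node `i` from neighbour `j` is a
softmax over `j` of `q_i · (k_j + W_e e_ij) / κ` with `κ = C/H`; the update
is `z_i = W_0 x_i + Σ_j α_ij (v_j + W_e e_ij)`, heads concatenated. Batch
normalisation, ReLU and dropout (rate 0.2) follow each of the first three
layers. After the fourth layer the network splits: Branch 1 applies global
max pooling over nodes, dropout, and an affine map to the scalar Φ estimate
(regressed on the untransformed scale); Branch 2 subtracts the pooled
vector from every node embedding and maps the (componentwise nonpositive)
differences through an affine layer and a two-way softmax to in/out
membership probabilities.

The max-pool subtraction is the architectural point: message passing cannot
cross components, so in a disconnected system each component's embeddings
equal their standalone values; only a comparison against a *global*
summary lets Branch 2 demote the nodes of the weaker component. Evaluation
mode uses batch-norm running statistics, which preserves this
disconnected-composition property exactly at inference and is tested.

Width, dropout rate and the attention scaling are not dictated by the
problem; the defaults (64, 0.2, `C/H`) are configuration keys chosen once
for graphs up to a few hundred nodes. Biases are used only in the two
output heads; the convolution projections are linear maps, which keeps the
layer algebra identical to its closed form in the unit tests.

The forward and backward passes are implemented directly in R as matrix
algebra with grouped reductions over the directed edge list; the backward
pass (attention softmax, batch-norm, max-pool routing included) is
hand-derived and validated against central finite differences to a relative
error below `1e-4` in the test suite.

## Training recipe

The composite loss is `MSE(Φ̂, Φ) + 5 · CE`, where the cross-entropy is
averaged over nodes with weight 1.8 on "out" terms (implemented as a
per-term weight, one of two defensible readings of a class-weighting
factor). Optimisation uses sign momentum (LION): direction
`sign(β₁ m + (1−β₁) g)` with `β₁ = 0.9`, momentum update
`m ← β₂ m + (1−β₂) g` with `β₂ = 0.99`, learning rate `1e-4`, mini-batches
of 128 graphs merged block-diagonally, decoupled weight decay off by
default.

Two dataset transforms run before splitting, in this order:

1. *Disconnected-pair augmentation* adds `round(0.05 · n)` composites, each
   the disjoint union of two distinct training graphs; the composite's Φ is
   the larger of the pair, the winner keeps its node labels and every node
   of the loser is "out". This teaches Branch 2 the global comparison it
   needs for multi-component systems.
2. *Oversampling* runs one-dimensional k-means (k = 7, 100 restarts) on Φ
   and upsamples every smaller bin to the largest bin's size; duplicates
   are perturbed by independent multiplicative factors drawn from
   `Uniform[0.95, 1.05]` applied to Φ and to every node-feature entry
   (the 5% noise law is uniform by choice; the magnitude is the stated
   condition). Perturbed copies live in feature space only — they need no
   generating system.

Then 10% of the expanded set is held out for validation (stratified by Φ
quantile bins to stabilise early stopping), the normaliser is fitted on the
expanded training portion, and training stops once the validation composite
loss has failed to improve for 50 consecutive epochs (patience 0 stops at
the first non-improving epoch); the best-validation checkpoint, including
its batch-norm running statistics, is returned. Two runs with the same seed
are bit-identical.

## Ensembles and experiments

For large systems, predictions average Φ across an ensemble of
independently seeded models, and a node joins the major complex when at
least 60% of the models vote for it (`vote_fraction ≥ 0.6`, strict
"at least"). The experiment drivers reproduce the four studies:
mixed-size train/test, extrapolation to a strictly larger size with frozen
normaliser statistics, topology scaling (tree / complete / loop-containing
over a size grid), and the split-brain sweep over inter-block edge
probability `p_e ∈ [0, 0.4]` reporting the local-integration rate (exact
equality of the predicted complex with the first block; a subset-
containment variant is also recorded), the mean membership ratio and the
mean Φ estimate. Sweeps write replicate-level records from which all
aggregates are pure functions.

## Problem sizes used by the shipped runs

The package's own test and acceptance runs are sized for a single CPU: the
scaled-down learning study trains on 90% of the 200 fixture systems with
N ∈ {4, 5} for up to 250 epochs per seed, and the reduced sweeps use a
3-model ensemble, N = 20 topologies (10 instances each) and 5 split-brain
systems per `p_e`. The full-scale protocols — 3000 labeled systems of
N ∈ {5,6,7}, 100 repetitions, 100-model ensembles, 50 systems per `p_e` —
are encoded in `experiment_plan(scale = "full")` with published reference
bands in `cluster_reference_metrics()`, and are intended for cluster-scale
reruns; nothing in the shipped tests asserts them.

## What the generator does and does not emulate

The synthetic systems cover the stated study conditions: sparse random
coupling, symmetric binary dynamics, one global temperature. They do not
emulate heterogeneous node models, directed or signed-structured
connectivity patterns of real neural systems, state-dependent noise, or
multi-valued states. Passing tests therefore demonstrate that the pipeline
learns the labeling engine's notion of integration under these conditions —
not that the trained weights transfer to empirical connectomes, and not
that the engine's effective-information measure coincides numerically with
the full hierarchical theory it stands in for. Extrapolated Φ estimates for
large systems should be read comparatively (between topologies or along a
sweep), not as absolute values; this is the same reading the scaling study
motivates.

## Numerical choices and degenerate inputs

- Probabilities are strictly inside (0, 1) for finite couplings, so KL
  terms in the labeling engine are finite; `Φ ≤ 1e-12` is treated as zero
  (no complex).
- The attention softmax subtracts the per-destination maximum before
  exponentiation; nodes without neighbours simply keep their skip term.
- Max pooling breaks ties by the first attaining node; with continuous
  embeddings ties have measure zero.
- Batch-norm variances are floored at `1e-5`; zero-variance feature columns
  get unit scale with a warning (they arise in edgeless batches).
- JSON serialisation prints floats with 17 significant digits so that
  systems, labels and content hashes round-trip exactly.
- k-means bin counts are reduced (with a warning) when there are fewer
  distinct Φ values than bins.

## Known limitations

The labeling engine is exponential and capped at N = 8 by default; larger
systems can only be predicted, not labeled. Training is pure R and sized
for hundreds of small graphs per minute, not for the 3000-graph,
100-repetition full protocol on a laptop. The Φ regression, like any
extrapolating regressor, compresses toward the training range for systems
much larger than those labeled; the ensemble vote stabilises membership but
cannot correct a shared bias.
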