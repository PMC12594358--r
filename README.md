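# phinet

Graph-transformer estimation of system-level integrated information (Φ)
and major complexes in binary Boltzmann networks.

## The problem

Integrated-information theories score a stochastic system, observed at a
state, by Φ — how much the whole system's cause-effect dynamics exceed
those of its best bipartition — and identify the **major complex**, the
node subset maximising Φ. Exact computation enumerates subsystems and
partitions and is exponential in the number of nodes `N`, which restricts
it to `N ≲ 8`. `phinet` is for researchers who want Φ-style analyses of
larger systems: it labels many small systems exactly, trains a multi-task
graph neural network to imitate the structure → (Φ, complex) mapping, and
applies trained ensembles to systems of hundreds of nodes where only
qualitative trends are meaningful (e.g. the transition from local to
global integration in split-brain-like networks).

## The model

Systems are undirected weighted graphs of `N` binary nodes (`S_i = ±1`,
couplings `J_ij ~ N(0,1)`, shared temperature `T`). Node `i` flips to
state `s` with Boltzmann probability

```
p_i(s | S) = 1 / (1 + exp(-2 τ_i s / T)),   τ_i = Σ_{j∈N(i)} J_ij S_j
```

independently across nodes. Ground truth comes from an exact
effective-information engine: each subsystem is scored by the KL
divergence across its minimum-information bipartition at the assigned
state, the maximising subsystem is the major complex, and its score is Φ.

The estimator is a four-layer transformer-convolution network with
four-head, edge-aware attention

```
α_ij = softmax_j( q_i · (k_j + W_e e_ij) / κ ),
z_i  = W_0 x_i + Σ_j α_ij (v_j + W_e e_ij)
```

over six inversion-invariant node features (max flip probability, T,
degree, closeness, betweenness, clustering) and the raw coupling as edge
feature. Branch 1 regresses Φ from a global max-pooled readout; Branch 2
classifies each node as in/out of the complex from the difference between
its embedding and the pooled vector — the comparison that keeps
disconnected subsystems honest. Training uses the composite loss
`MSE + 5·weighted-CE` (weight 1.8 on "out"), disconnected-pair
augmentation, Φ-binned oversampling, sign-momentum (LION) optimisation and
early stopping. See `vignette("phinet-methods")` for the full account.

## Worked example

Train on 180 of the shipped labeled fixture systems (N ∈ {4, 5}) and
evaluate on the remaining 20:

```r
library(phinet)
fx  <- load_fixture_pack(sizes = c(4, 5))
fit <- phinet(fx$specs[1:180], fx$labels[1:180],
              control = train_config(max_epochs = 150, seed = 1))
print(fit)
#> Multi-task transformer-convolution network
#>   4 layers, 4 heads x 16 channels (hidden 64)
#>   trained on 180 graphs; stopped at epoch 150 (best epoch 150, val loss 2.6501)

preds <- predict(fit, fx$specs[181:200])
compute_metrics(preds, fx$labels[181:200])
#> phi estimation:  MSE = 0.0996, Pearson r = 0.8063
#> major complex:   node accuracy = 0.7500, graph accuracy = 0.2500
#> (20 graphs, 100 nodes)
```

The held-out Pearson correlation of 0.81 says the network ranks systems by
integrated information reliably; node accuracy 0.75 is per-node membership
classification, and graph accuracy (the complex predicted exactly) is the
strictest metric. Individual predictions look like:

```r
preds[[17]]$phi_hat        # estimated phi for held-out system 17
#> [1] 1.150  (true value 1.242)
which(preds[[17]]$membership)
#> [1] 1 3    (true major complex {1, 3})
```

Longer training and ensembling improve all four metrics (the acceptance
run below trains 3 seeds for 250 epochs and reaches r ≈ 0.93). For large
systems, train an ensemble and predict by vote:

```r
ens <- phinet_ensemble(fx$specs, fx$labels, n_models = 10)
res <- predict(ens, generate_split_brain(p_e = 0.01, seed = 1))
res[[1]]$phi_mean; mean(res[[1]]$membership)
```

A thin command-line interface over the same functions ships in
`inst/scripts/phinet-cli.R` (subcommands `generate`, `label`, `train`,
`evaluate`, `experiment`; JSON-Lines in, JSON/CSV out).

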