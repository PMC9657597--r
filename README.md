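# bilinkgnn

Link prediction on bipartite association networks by classifying labeled
enclosing subgraphs with a graph neural network.

## The problem

Curated association tables between two entity classes — miRNAs and
diseases being the motivating case — form a sparse 0/1 matrix
`Y (n_m x n_d)` where ones are experimentally supported associations and
zeros are merely unobserved. The screening task is to rank the zeros by how
likely they are to be real. Most predictors in this space depend on
external similarity matrices whose gaps and biases propagate into the
predictions; `bilinkgnn` learns from the network topology alone.

## The method

For each candidate pair `(m, d)` the package extracts the *h-hop enclosing
subgraph* (all nodes within graph distance `h` of either center, with the
pair's own edge always removed so supervision can never leak), assigns each
node a **double-radius structural label**

```
fl(i) = 1 + min(dx, dy) + floor(d/2) * (floor(d/2) + d mod 2 - 1),   d = dx + dy
```

(`dx`, `dy` = distances to the two centers, each measured with the opposite
center deleted; centers get label 1, nodes cut off from a center get 0),
one-hot-encodes the labels, and classifies the subgraph with a GNN whose
convolution aggregates four propagation operators per layer:

```
Z[t+1] = tanh( [ A·Z[t], A²·Z[t], D̃⁻¹Ã·Z[t], D̃⁻½ÃD̃⁻½·Z[t] ] · W[t] )
```

In a bipartite graph, `A` mixes heterogeneous neighbors while `A²` reaches
homogeneous nodes (it counts common neighbors and is zero across sides), so
the spliced convolution sees both kinds of structure at once. Layer outputs
are concatenated, **sort pooling** keeps the top `k` nodes by their learned
importance channel (zero-padding smaller subgraphs), and a 1-D
convolutional head with a dense layer emits 2-class log-probabilities
trained with NLL loss and Adam. Dropping individual operators gives the
ablation variants a–d; keeping only `D̃⁻½ÃD̃⁻½` is the DGCNN-style baseline.

The training loop, with hand-derived backpropagation for this architecture,
runs in compiled code (RcppArmadillo); a pure-R dense reference
implementation of every operation is exported and the test suite holds the
two paths to within 1e-6.

## Worked example

```r
library(bilinkgnn)

am <- generate_bipartite_sbm(sbm_spec(60, 50, 3, 0.35, 0.03, seed = 7))
am
#> Bipartite association matrix: 60 x 50, 420 associations

split <- holdout_split(am, h = 2, seed = 7)          # 10% of positives + equal negatives held out
model <- train(split$train_subgraphs, model_config(seed = 7),
               train_spec(epochs = 20, seed = 7))
model
#> Subgraph GNN (A+A2+RW+SYM), conv dims [32, 32, 1], k = 63, feature width 52, h = 2
#>   trained 20 epochs, final NLL 0.5364

scores <- predict_subgraphs(model, split$test_subgraphs)
compute_metrics(scores, split$test_labels)
#> Metrics @ threshold 0.5: ACC 0.8095 | precision 0.7500 | recall 0.9286 | AUROC 0.8656 | AUPR 0.8576 | MCC 0.6374

head(rank_candidates(model, am, "d1"), 3)            # unobserved partners of disease d1
#>   rank  id     score
#> 1    1 m49 0.8250156
#> 2    2 m31 0.8117980
#> 3    3 m37 0.7944243
```

The held-out AUROC of 0.87 says the model ranks a held-out true
association above a sampled non-association 87% of the time; the ranking
lists the matrix zeros for `d1` in descending predicted probability — the
candidate-screening output a practitioner would take to validation.
`cross_validate()` runs the same protocol as leakage-safe k-fold
cross-validation, and the methods vignette (`vignettes/methods.Rmd`)
documents the model, its defaults and the benchmark's information ceiling.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bilinkgnn.R", package = "bilinkgnn"))')" \
    simulate --out data --seed 1
... crossval --data data/edges.tsv --hop 1,2 --folds 10 --seed 1 --out cv
... ablate   --data data/edges.tsv --hop 2 --seed 1 --out ablation
... predict  --data data/edges.tsv --target d1 --hop 2 --out pred
... extract  --data data/edges.tsv --hop 2 --out subgraphs
```

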