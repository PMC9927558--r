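# grank

Scoring and ranking of protein–protein docking models with a rotation-,
translation- and reflection-invariant graph neural network built from
geometric vector perceptrons (GVPs).

Computational docking produces large pools of candidate structures (decoys)
per complex, of which only a few resemble the native assembly. `grank`
builds an atom-level graph of each decoy's inter-chain interface (atoms
within 8.5 Å of the partner chain; edges between all atom pairs within
4.5 Å; one-hot element node features; Gaussian radial-basis distance and
unit-direction edge features), scores it with a GVP-GNN — five GVPConv
blocks, each a graph propagation layer

&nbsp;&nbsp;&nbsp;&nbsp;*m*(j→i) = φ(concat(h\_Vj, h\_Ej→i)), &nbsp;
h\_Vi ← LayerNorm(h\_Vi + (1/k′)·Dropout(Σ\_{j∈N(i)} m(j→i)))

followed by a point-wise feed-forward layer
h\_Vi ← LayerNorm(h\_Vi + Dropout(φ(h\_Vi))) — and regresses *f-nat*, the
fraction of native inter-chain residue contacts, with MSE loss under Adam
(batch 64, learning rate 1e-4). Decoys are ranked per complex by the
ensemble-averaged score of the cross-validation fold models.

The package also implements the full labeling machinery (f-nat, ligand RMSD,
interface RMSD via Kabsch superposition, CAPRI classes, the f-nat ≥ 0.3
near-native label), per-complex ranking assessment (ROC-AUC, PR-AUC,
hit-rate curves, success rates), and a rigid-body synthetic decoy generator
so the entire pipeline runs with no external data. The forward *and*
backward passes of the network are implemented in base R matrix algebra;
gradients are verified against finite differences in the test suite.

## Worked example

```r
library(grank)

## a miniature benchmark: 6 synthetic complexes x 10 rigid-body decoys
ds <- make_dataset(n_complexes = 6, n_decoys_per_complex = 10, seed = 1)
head(ds$labels[, c("complex_id", "model_id", "fnat", "lrmsd", "irmsd",
                   "capri_class")], 4)
#>   complex_id model_id      fnat        lrmsd        irmsd capri_class
#> 1   synth001 decoy001 1.0000000 1.830032e-15 1.372040e-15        high
#> 2   synth001 decoy002 0.2631579 1.000000e+00 4.083813e-01  acceptable
#> 3   synth001 decoy003 1.0000000 2.000000e+00 8.076815e-01        high
#> 4   synth001 decoy004 0.8421053 9.151828e-01 4.214302e-01        high

## train a small fold ensemble to regress f-nat
fit <- grank_fit(ds$graphs, ds$labels, n_folds = 2,
                 model_config = grank_config(node_dims = c(16, 2),
                                             edge_dims = c(8, 1),
                                             n_blocks = 1, seed = 1),
                 train_cfg = train_config(batch_size = 16, n_epochs = 5,
                                          learning_rate = 1e-3, seed = 1))
preds <- predict(fit, ds$graphs)

## rank and assess per complex
records <- merge(preds, ds$labels[, c("complex_id", "model_id", "is_positive")])
metrics <- evaluate_predictions(records)
summarize_metrics(metrics)$summary
#>    metric       q25    median       q75
#> 1 roc_auc 0.6900000 0.7966667 0.9083333
#> 2  pr_auc 0.8471939 0.9386905 0.9738095
```

The labels say what each decoy is worth: decoy001 is the unperturbed native
(f-nat 1, RMSDs 0 to machine precision, class "high"); decoy002's 1 angstrom
off-axis shift breaks most native contacts (f-nat 0.26, "acceptable"), while
decoy003 slid 2 angstrom along the interface and kept them all. The metric
table summarizes, across complexes, how well the small trained scorer
separates near-native decoys (f-nat ≥ 0.3) from wrong ones: a median
per-complex ROC-AUC of 0.80 after five toy epochs.

A command-line interface wrapping the same pipeline ships at
`inst/cli/grank.R`:

```sh
Rscript inst/cli/grank.R run --out-dir myrun --seed 7 --n-complexes 10
```

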